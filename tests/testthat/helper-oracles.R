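# Independent brute-force oracles used to check the fitted estimators.

# Dense grid search over (A, B, C) minimizing squared error.
grid_search_bleach <- function(time, value, A_grid, B_grid, C_grid) {
  best <- list(rss = Inf)
  for (A in A_grid) for (B in B_grid) for (C in C_grid) {
    rss <- sum((value - (A * exp(-time / B) + C))^2)
    if (rss < best$rss) best <- list(A = A, B = B, C = C, rss = rss)
  }
  best
}

# Dense grid search over (Rmax, EC50, h) minimizing squared error.
grid_search_logistic <- function(c, response, Rmax_grid, EC50_grid, h_grid) {
  best <- list(rss = Inf)
  for (Rmax in Rmax_grid) for (EC50 in EC50_grid) for (h in h_grid) {
    rss <- sum((response - Rmax / (1 + exp(-h * (c - EC50))))^2)
    if (rss < best$rss) {
      best <- list(Rmax = Rmax, EC50 = EC50, h = h, rss = rss)
    }
  }
  best
}

# A minimal noiseless GC-coupled trial: flat bleach (A = 0), one excitatory
# substance, unit gain. Used where examples require dF/F peak == amplitude.
flat_bleach_acq <- function(noise_sd = 0, seed = NULL, ...) {
  acquisition_spec("gc_coupled", bleach = c(A = 0, B = 180, C = 1000),
                   noise_sd = noise_sd, fid_noise_sd = 0, seed = seed, ...)
}

ea_sample <- function(dilution = 1e-4) {
  sample_spec(substance_library()$ethyl_acetate, dilution)
}

in_windows_for_test <- function(time, start, end) {
  time >= start & time <= end
}
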