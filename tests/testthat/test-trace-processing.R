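test_that("dF/F follows its defining formula", {
  const <- new_trace(0:19, rep(100, 20))
  expect_equal(delta_f_over_f(const, response_window(0, 9))$value,
               rep(0, 20))
  step <- new_trace(0:19, c(rep(100, 10), rep(110, 10)))
  d <- delta_f_over_f(step, response_window(0, 9))
  expect_equal(d$value[15], 0.1, tolerance = 1e-12)
  expect_equal(mean(d$value[1:10]), 0)
})

test_that("dF/F is invariant to multiplicative gain", {
  withr::with_seed(3, {
    tr <- new_trace(0:99, 500 + cumsum(rnorm(100)))
  })
  bw <- response_window(0, 20)
  for (g in c(0.5, 2, 17)) {
    scaled <- set_trace_values(tr, tr$value * g)
    expect_equal(delta_f_over_f(scaled, bw)$value,
                 delta_f_over_f(tr, bw)$value, tolerance = 1e-12)
  }
})

test_that("dF/F peak equals the injected amplitude under flat bleach, no noise", {
  sim <- simulate_gc_imaging_trace(ea_sample(1e-3), or42b_tuning(),
                                   flat_bleach_acq())
  gt <- sim$ground_truth
  dff <- delta_f_over_f(sim$fluor, gt$baseline_window)
  expect_equal(max(dff$value), gt$substances$amplitude[1], tolerance = 1e-9)
})

test_that("dF/F refuses a zero baseline or an empty window", {
  z <- new_trace(0:19, rep(0, 20))
  expect_error(delta_f_over_f(z, response_window(0, 5)), "F0")
  tr <- new_trace(0:19, rep(1, 20))
  expect_error(delta_f_over_f(tr, response_window(100, 110)), "no samples")
})

test_that("bleach fit recovers exact parameters on noiseless decay", {
  t <- seq(0, 300, by = 1)
  tr <- new_trace(t, 2 * exp(-t / 50) + 1)
  fit <- fit_bleach(tr, auto_mask = FALSE)
  expect_equal(fit$A, 2, tolerance = 1e-6)
  expect_equal(fit$B, 50, tolerance = 1e-6)
  expect_equal(fit$C, 1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("a constant trace gives C with an unidentifiable time constant", {
  tr <- new_trace(0:49, rep(7.5, 50))
  fit <- fit_bleach(tr)
  expect_equal(fit$C, 7.5)
  expect_equal(fit$A, 0)
  expect_true(is.na(fit$B))
  expect_false(glance(fit)$b_identifiable)
  # correction then reduces to subtracting a constant (identity here)
  expect_equal(correct_bleach(tr, fit)$value, tr$value)
})

test_that("masked bleach fit recovers B within 2% despite a large transient", {
  sim <- simulate_gc_imaging_trace(
    ea_sample(1e-3), or42b_tuning(),
    acquisition_spec("gc_coupled", noise_sd = 0.006, fid_noise_sd = 0,
                     seed = 21L)
  )
  gt <- sim$ground_truth
  fit <- fit_bleach(sim$fluor, mask = gt$response_windows)
  expect_equal(fit$B, gt$bleach[["B"]], tolerance = 0.02)
  expect_equal(fit$A, gt$bleach[["A"]], tolerance = 0.05)
})

test_that("automatic masking flags the response and matches the metadata mask", {
  sim <- simulate_gc_imaging_trace(
    ea_sample(1e-3), or42b_tuning(),
    acquisition_spec("gc_coupled", noise_sd = 0.006, fid_noise_sd = 0,
                     seed = 22L)
  )
  fit_auto <- fit_bleach(sim$fluor) # no mask given
  fit_meta <- fit_bleach(sim$fluor,
                         mask = sim$ground_truth$response_windows)
  expect_gt(nrow(fit_auto$mask), 0)
  # auto masking pads less of the response tail than the metadata windows,
  # so the two fits agree only approximately
  expect_equal(fit_auto$B, fit_meta$B, tolerance = 0.05)
})

test_that("bleach fit matches a dense grid-search oracle on a small instance", {
  t <- seq(0, 60, by = 2)
  withr::with_seed(8, y <- 3 * exp(-t / 15) + 2 + rnorm(length(t), 0, 0.05))
  tr <- new_trace(t, y)
  fit <- fit_bleach(tr, auto_mask = FALSE)
  oracle <- grid_search_bleach(t, y,
                               A_grid = seq(2, 4, by = 0.02),
                               B_grid = seq(10, 20, by = 0.1),
                               C_grid = seq(1.5, 2.5, by = 0.02))
  expect_lte(fit$rss, oracle$rss + 1e-9)
  expect_equal(fit$A, oracle$A, tolerance = 0.02)
  expect_equal(fit$B, oracle$B, tolerance = 0.02)
  expect_equal(fit$C, oracle$C, tolerance = 0.02)
})

test_that("bleach correction flattens pure decay and preserves transients", {
  t <- seq(0, 300, by = 1)
  pure <- new_trace(t, 2 * exp(-t / 50) + 1)
  fit <- fit_bleach(pure, auto_mask = FALSE)
  corr <- correct_bleach(pure, fit)
  expect_lt(max(abs(corr$value - fit$C)), 1e-9)

  # additive transient on top of the decay, masked out of the fit
  transient <- 0.4 * exp(-pmax(0, t - 150) / 8) * (t >= 150)
  tr <- new_trace(t, 2 * exp(-t / 50) + 1 + transient)
  mask <- response_window(145, 200, "resp")
  fit2 <- fit_bleach(tr, mask = mask)
  corr2 <- correct_bleach(tr, fit2)
  flat <- corr2$value[!in_windows_for_test(t, 145, 200)]
  expect_lt(max(flat) - min(flat), 0.01 * (max(pure$value) - min(pure$value)))
  amp <- max(corr2$value) - fit2$C
  expect_equal(amp, 0.4, tolerance = 0.01)

  # zero-A fit leaves the trace untouched
  id_fit <- fit_bleach(new_trace(t, rep(5, length(t))))
  expect_equal(correct_bleach(tr, id_fit)$value, tr$value)
})

test_that("bleach round trip reduces drift by 99% on generated traces", {
  sim <- simulate_gc_imaging_trace(ea_sample(1e-3), or42b_tuning(),
                                   acquisition_spec(noise_sd = 0,
                                                    fid_noise_sd = 0))
  gt <- sim$ground_truth
  fit <- fit_bleach(sim$fluor, mask = gt$response_windows)
  corr <- correct_bleach(sim$fluor, fit)
  out <- !in_windows_for_test(sim$fluor$time,
                              gt$response_windows$start[1],
                              gt$response_windows$end[1])
  drift_before <- max(sim$fluor$value[out]) - min(sim$fluor$value[out])
  drift_after <- max(corr$value[out]) - min(corr$value[out])
  expect_lt(drift_after, 0.01 * drift_before)
})

test_that("ROI extraction recovers pixel data and survives noise", {
  tr <- new_trace(0:29, 50 + cos(0:29 / 3), channel = "fluorescence")
  roi1 <- matrix(FALSE, 8, 8); roi1[3, 4] <- TRUE
  mv <- simulate_movie(tr, roi1, noise_sd = 0)
  expect_equal(extract_roi_trace(mv, roi1)$value,
               vapply(0:29 + 1, function(k) mv[3, 4, k], numeric(1)))
  roi <- matrix(TRUE, 10, 10)
  noisy <- simulate_movie(tr, roi, noise_sd = 0.5, seed = 4L)
  expect_gt(stats::cor(extract_roi_trace(noisy, roi)$value, tr$value), 0.99)
  expect_error(extract_roi_trace(mv, matrix(FALSE, 8, 8)), "empty")
})

test_that("reference normalization rescales and equalizes animal gains", {
  tr <- new_trace(0:9, c(rep(0, 5), 0.25, rep(0, 4)), channel = "dff")
  expect_equal(max(normalize_to_reference(tr, 0.5)$value), 0.5)
  expect_equal(max(normalize_to_reference(tr, 0.25)$value), 1.0)
  expect_error(normalize_to_reference(tr, -1), "positive")

  # idempotent once the reference is 1.0
  once <- normalize_to_reference(tr, 0.25)
  expect_equal(normalize_to_reference(once, 1.0)$value, once$value)

  # two animals with 1x and 2x gain agree after normalization
  amps <- vapply(c(1, 2), function(g) {
    sim <- simulate_gc_imaging_trace(ea_sample(1e-3), or42b_tuning(),
                                     flat_bleach_acq(animal_gain = g))
    dff <- delta_f_over_f(sim$fluor, sim$ground_truth$baseline_window)
    ref <- g * 0.1 # each animal's own reference amplitude scales with gain
    max(normalize_to_reference(dff, ref)$value)
  }, numeric(1))
  expect_equal(amps[1], amps[2], tolerance = 1e-9)
})

test_that("gaussian smoothing reduces noise without moving the baseline", {
  withr::with_seed(12, {
    tr <- new_trace(0:499, rnorm(500, 10, 1))
  })
  sm <- gaussian_smooth(tr, 2)
  expect_lt(stats::sd(sm$value), 0.5 * stats::sd(tr$value))
  expect_equal(mean(sm$value), mean(tr$value), tolerance = 0.05)
  expect_identical(gaussian_smooth(tr, 0), tr)
})
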