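test_that("FID trace follows the Gaussian elution generating formula", {
  lib <- substance_library()
  acq <- acquisition_spec("gc_coupled", fid_noise_sd = 0)
  sim <- simulate_fid_trace(sample_spec(lib$ethyl_acetate, 1e-2), acq)
  apex_idx <- which.max(sim$trace$value)
  expect_equal(sim$trace$time[apex_idx], 100)
  # apex height = factor * amount (unit-apex Gaussian)
  expect_equal(max(sim$trace$value), 1e4 * 1e-2, tolerance = 1e-12)
  expect_equal(sim$ground_truth$apex_height, 100)
})

test_that("a 10^-5.2 contaminant is invisible at FID scale", {
  acq <- acquisition_spec("gc_coupled", fid_noise_sd = 0)
  sim <- simulate_fid_trace(contaminated_sample(1e-2, 10^-5.2), acq)
  gt <- sim$ground_truth
  ratio <- gt$apex_height[gt$name == "ethyl_acetate"] /
    gt$apex_height[gt$name == "benzaldehyde_d5"]
  expect_lt(ratio, 1e-4)
})

test_that("an inert, FID-silent sample yields a flat zero FID trace", {
  empty <- sample_spec(
    substance_spec("blank", 100, 3, fid_response_factor = 0),
    1e-2
  )
  sim <- simulate_fid_trace(empty, acquisition_spec(fid_noise_sd = 0))
  expect_equal(max(abs(sim$trace$value)), 0)
})

test_that("FID simulation rejects invalid acquisition settings", {
  expect_error(acquisition_spec(rate = 0), "rate")
  expect_error(
    simulate_fid_trace(ea_sample(), acquisition_spec("direct_stim")),
    "gc_coupled"
  )
})

test_that("response kernel peaks at its amplitude and decays as specified", {
  lib <- substance_library()
  model <- lib$ethyl_acetate$receptor_model # tau = 8, sat = 0.3
  acq <- acquisition_spec("gc_coupled")
  expect_equal(max(abs(simulate_response_kernel(model, 0, acq, 50)$value)), 0)

  k <- simulate_response_kernel(model, 0.2, acq, 50)
  expect_equal(max(k$value), 0.2)
  expect_true(all(k$value[k$time < 50] == 0))
  expect_equal(k$value[k$time == 50 + 8], 0.2 * exp(-1), tolerance = 1e-12)

  # above the saturation amplitude the decay constant stretches
  k_hi <- simulate_response_kernel(model, 0.6, acq, 50)
  decay_ratio <- function(kk, amp) kk$value[kk$time == 58] / amp
  expect_gt(decay_ratio(k_hi, 0.6), decay_ratio(k, 0.2))

  # inhibitory kernels are the negated shape
  k_neg <- simulate_response_kernel(model, -0.2, acq, 50)
  expect_equal(k_neg$value, -k$value)
})

test_that("GC-coupled imaging trace reduces to the bleach curve without responses", {
  inert <- sample_spec(
    substance_spec("blank", 100, 3, receptor_model = receptor_inert()),
    1e-2
  )
  acq <- acquisition_spec("gc_coupled", noise_sd = 0, fid_noise_sd = 0)
  sim <- simulate_gc_imaging_trace(inert, or42b_tuning(), acq)
  b <- acq$bleach
  expect_equal(sim$fluor$value,
               b[["A"]] * exp(-sim$fluor$time / b[["B"]]) + b[["C"]],
               tolerance = 1e-12)
})

test_that("contaminated benzaldehyde-d5 shows the increase-at-100s / decrease-at-240s pattern", {
  acq <- acquisition_spec("gc_coupled", noise_sd = 0, fid_noise_sd = 0)
  sim <- simulate_gc_imaging_trace(contaminated_sample(1e-2), or42b_tuning(),
                                   acq)
  gt <- sim$ground_truth$substances
  expect_gt(gt$amplitude[gt$name == "ethyl_acetate"], 0)
  expect_lt(gt$amplitude[gt$name == "benzaldehyde_d5"], 0)
  dff <- process_trace(sim$fluor, mask = sim$ground_truth$response_windows,
                       baseline_window = sim$ground_truth$baseline_window)$dff
  expect_gt(dff$value[dff$time == 102], 0)
  expect_lt(dff$value[dff$time == 242], 0)
})

test_that("same seed and configuration give bit-identical traces", {
  acq <- acquisition_spec("gc_coupled", seed = 99L)
  a <- simulate_gc_imaging_trace(contaminated_sample(1e-1), or42b_tuning(), acq)
  b <- simulate_gc_imaging_trace(contaminated_sample(1e-1), or42b_tuning(), acq)
  expect_identical(a$fluor$value, b$fluor$value)
  expect_identical(a$fid$value, b$fid$value)
  ex1 <- simulate_experiment(seed = 5L)
  ex2 <- simulate_experiment(seed = 5L)
  expect_identical(ex1$fluor[[4]]$value, ex2$fluor[[4]]$value)
})

test_that("contaminant amount co-dilutes with the sample at every dilution", {
  for (d in 10^c(-1, -2, -4)) {
    amt <- sample_amounts(contaminated_sample(d, fraction = 10^-5.2))
    expect_equal(amt$amount[amt$name == "ethyl_acetate"] /
                   amt$amount[amt$name == "benzaldehyde_d5"],
                 10^-5.2, tolerance = 1e-12)
  }
})

test_that("noiseless mixture traces superpose per substance above the bleach baseline", {
  lib <- substance_library()
  tun <- or42b_tuning(lib)
  acq <- acquisition_spec("gc_coupled", noise_sd = 0, fid_noise_sd = 0)
  b <- acq$bleach
  baseline <- b[["A"]] * exp(-acq_times(acq) / b[["B"]]) + b[["C"]]
  mix <- contaminated_sample(1e-1, fraction = 1e-5)
  both <- simulate_gc_imaging_trace(mix, tun, acq)$fluor$value - baseline
  main_only <- simulate_gc_imaging_trace(
    sample_spec(lib$benzaldehyde_d5, 1e-1), tun, acq)$fluor$value - baseline
  ct_only <- simulate_gc_imaging_trace(
    sample_spec(lib$ethyl_acetate, 1e-6), tun, acq)$fluor$value - baseline
  expect_equal(both, main_only + ct_only, tolerance = 1e-9)
})

test_that("direct stimulation sums signed amplitudes at both pulse onsets", {
  lib <- substance_library()
  tun <- or42b_tuning(lib)
  acq <- acquisition_spec("direct_stim", noise_sd = 0)

  # benzaldehyde-h alone: two negative-going deflections
  sim <- simulate_direct_stim_trace(sample_spec(lib$benzaldehyde_h, 1e-2),
                                    tun, acq)
  expect_equal(sim$ground_truth$onsets, c(6.75, 9.25))
  dff <- process_trace(sim$fluor, mask = sim$ground_truth$response_windows,
                       baseline_window = sim$ground_truth$baseline_window)$dff
  expect_lt(dff$value[dff$time == 6.75], 0)
  expect_lt(dff$value[dff$time == 9.25], 0)

  # increasing contaminant fraction: net amplitude non-decreasing, crosses 0
  fracs <- 10^seq(-8, -1, by = 1)
  nets <- vapply(fracs, function(fr) {
    smp <- sample_spec(lib$benzaldehyde_h, 1e-2, contaminants = list(
      list(substance = lib$ethyl_acetate, relative_fraction = fr)))
    simulate_direct_stim_trace(smp, tun, acq)$ground_truth$net_amplitude
  }, numeric(1))
  expect_true(all(diff(nets) > 0))
  expect_lt(nets[1], 0)
  expect_gt(nets[length(nets)], 0)

  # zero-amplitude tuning: bleach-only trace
  inert_tun <- list(benzaldehyde_h = receptor_inert())
  sim0 <- simulate_direct_stim_trace(sample_spec(lib$benzaldehyde_h, 1e-2),
                                     inert_tun, acq)
  b <- acq$bleach
  expect_equal(sim0$fluor$value,
               b[["A"]] * exp(-sim0$fluor$time / b[["B"]]) + b[["C"]],
               tolerance = 1e-12)
})

test_that("movies round-trip through the ROI mean", {
  tr <- new_trace(0:49, 100 + sin(0:49 / 5), channel = "fluorescence")
  roi <- matrix(FALSE, 12, 10); roi[3:12, 1:10] <- TRUE # 120 px
  mv <- simulate_movie(tr, roi, noise_sd = 0)
  expect_equal(extract_roi_trace(mv, roi)$value, tr$value, tolerance = 1e-12)

  all_on <- matrix(TRUE, 6, 5)
  mv2 <- simulate_movie(tr, all_on, noise_sd = 0)
  expect_equal(apply(mv2, 3, mean), tr$value, tolerance = 1e-12)

  mv3 <- simulate_movie(tr, roi, noise_sd = 0.5, seed = 11L)
  expect_gt(stats::cor(extract_roi_trace(mv3, roi)$value, tr$value), 0.99)

  expect_error(simulate_movie(tr, matrix(FALSE, 4, 4)), "empty")
})
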