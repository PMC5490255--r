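test_that("peak detection on flat and single-Gaussian traces", {
  flat <- new_trace(0:199, rep(1, 200))
  expect_equal(nrow(detect_peaks(flat, min_prominence = 0.1)), 0)

  t <- 0:539
  g <- 0.8 * exp(-(t - 100)^2 / (2 * 9))
  tr <- new_trace(t, g)
  pk <- detect_peaks(tr, min_prominence = 0.1)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$apex_time - 100), 1)
  expect_equal(pk$amplitude, 0.8, tolerance = 0.01)
  expect_equal(pk$width, 2 * sqrt(2 * log(2)) * 3, tolerance = 0.2)
})

test_that("an ethyl-butyrate-like trial yields exactly four response peaks", {
  # mean over three animals, as the recordings are displayed
  dffs <- lapply(1:3, function(k) {
    sim <- simulate_gc_imaging_trace(
      reference_sample(1e-2), or42b_tuning(),
      acquisition_spec("gc_coupled", noise_sd = 0.006, fid_noise_sd = 0,
                       seed = 31L + k)
    )
    gt <<- sim$ground_truth
    process_trace(sim$fluor, mask = gt$response_windows,
                  baseline_window = gt$baseline_window)$dff
  })
  dff <- average_traces(dffs)
  # detect on the measurement-smoothed trace at 3x the raw trace's noise SD
  pk <- detect_peaks(gaussian_smooth(dff, 2),
                     min_prominence = 3 * robust_noise_sd(dff))
  expect_equal(nrow(pk), 4)
  expect_equal(pk$apex_time, sort(gt$substances$arrival_time),
               tolerance = 0.05)
})

test_that("peak detection is invariant to adding a constant baseline", {
  withr::with_seed(6, {
    t <- 0:299
    v <- 0.5 * exp(-(t - 80)^2 / 18) - 0.4 * exp(-(t - 200)^2 / 32) +
      rnorm(300, 0, 0.01)
  })
  tr <- new_trace(t, v)
  shifted <- set_trace_values(tr, v + 3.7)
  p1 <- detect_peaks(tr, polarity = "both")
  p2 <- detect_peaks(shifted, polarity = "both")
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$apex_time, p2$apex_time)
  expect_equal(p1$amplitude, p2$amplitude, tolerance = 1e-9)
})

test_that("alignment offset is the dff-minus-fid apex difference", {
  ref <- substance_library()$ethyl_acetate
  fidp <- tibble::tibble(apex_time = 100.0, amplitude = 50)
  dffp <- tibble::tibble(apex_time = 101.5, amplitude = 0.3)
  expect_equal(calibrate_alignment(fidp, dffp, ref)$offset, 1.5)
  expect_equal(calibrate_alignment(fidp, fidp, ref)$offset, 0)
  expect_error(
    calibrate_alignment(fidp, tibble::tibble(apex_time = 400,
                                             amplitude = 1), ref),
    "imaging"
  )
})

test_that("alignment recovers an injected transit offset", {
  # noiseless: exact to <= one sample for several injected offsets
  for (off in c(0.5, 2, 7)) {
    acq0 <- acquisition_spec("gc_coupled", noise_sd = 0, fid_noise_sd = 0,
                             gc_transit = off)
    sim <- simulate_gc_imaging_trace(ea_sample(1e-3), or42b_tuning(), acq0)
    dff <- process_trace(sim$fluor,
                         mask = sim$ground_truth$response_windows,
                         baseline_window = sim$ground_truth$baseline_window)$dff
    al <- calibrate_alignment(detect_peaks(sim$fid, min_prominence = 0.1),
                              detect_peaks(dff, min_prominence = 0.01),
                              substance_library()$ethyl_acetate)
    expect_lte(abs(al$offset - off), 1 / acq0$rate)
  }
  # seeded default-noise simulation, injected offset 2.0 s
  acq <- acquisition_spec("gc_coupled", gc_transit = 2, seed = 13L)
  sim <- simulate_gc_imaging_trace(ea_sample(1e-3), or42b_tuning(), acq)
  dff <- process_trace(sim$fluor, mask = sim$ground_truth$response_windows,
                       baseline_window = sim$ground_truth$baseline_window)$dff
  al <- calibrate_alignment(detect_peaks(sim$fid),
                            detect_peaks(dff),
                            substance_library()$ethyl_acetate)
  expect_lte(abs(al$offset - 2), 1)
})

test_that("windowed response measurement returns the signed extremum", {
  t <- 0:539
  ea <- substance_library()$ethyl_acetate
  up <- new_trace(t, 0.4 * exp(-(t - 100)^2 / 18), channel = "dff")
  m <- measure_response(up, ea, NULL, window_halfwidth = 10)
  expect_equal(m$amplitude, 0.4, tolerance = 1e-3)

  down <- new_trace(t, -0.2 * exp(-(t - 100)^2 / 18), channel = "dff")
  expect_equal(measure_response(down, ea, NULL, 10)$amplitude, -0.2,
               tolerance = 1e-3)

  expect_error(
    measure_response(new_trace(0:50, rnorm(51), channel = "dff"), ea, NULL),
    "outside"
  )
})

test_that("measured amplitude is monotone in the injected amplitude", {
  ea <- substance_library()$ethyl_acetate
  amps <- seq(-0.3, 0.4, by = 0.1)
  measured <- vapply(amps, function(a) {
    tr <- simulate_response_kernel(ea$receptor_model, a,
                                   acquisition_spec("gc_coupled"),
                                   onset = 100)
    measure_response(tr, ea, NULL, 10)$amplitude
  }, numeric(1))
  expect_true(all(diff(measured) > 0 | (amps[-1] == 0 & diff(measured) >= 0)))
  # signed extremum is antisymmetric in the injected amplitude
  expect_equal(measured[1], -measured[7], tolerance = 1e-9) # -0.3 vs 0.3
})
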