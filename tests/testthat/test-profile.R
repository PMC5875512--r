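test_that("array calibration recovers inverse sensitivities from a sweep", {
  b <- default_beam()
  nm <- noise_model(detector_sensitivity_sd = 0.05, reading_noise_sd = 0,
                    tube_drift_sd = 0.02, seed = 3)
  sweep <- simulate_calibration_sweep(b, array_spec(), nm)
  truth <- attr(sweep, "truth")$sensitivities
  factors <- calibrate_array(sweep)
  expected <- (1 / truth) / mean(1 / truth)
  expect_equal(factors$factor, expected, tolerance = 1e-12)
  expect_equal(mean(factors$factor), 1, tolerance = 1e-12)
  # invariant to a global rescale of the sweep readings
  scaled <- sweep
  scaled$reading <- sweep$reading * 17
  expect_equal(calibrate_array(scaled)$factor, factors$factor,
               tolerance = 1e-12)
  # uniform sweep -> unit factors
  uni <- tibble::tibble(detector = 1:10, reading = 2,
                        reference_reading = 3)
  expect_equal(calibrate_array(uni)$factor, rep(1, 10))
  bad <- uni
  bad$reading[4] <- NA
  expect_error(calibrate_array(bad), class = "cbctdose_error_coverage",
               regexp = "4")
})

test_that("applying calibration corrects a raw scan to the beam model", {
  b <- default_beam()
  nm <- noise_model(detector_sensitivity_sd = 0.05, reading_noise_sd = 0,
                    tube_drift_sd = 0, seed = 3)
  scan <- simulate_diode_scan(b, array_spec(), nm)
  factors <- calibrate_array(simulate_calibration_sweep(b, array_spec(), nm))
  cal <- apply_calibration(scan, factors)
  expect_identical(attr(cal, "state"), "calibrated")
  # sensitivities shared between sweep and scan cancel up to the mean-1
  # normalisation, a single scan-wide scalar that CAX normalisation removes
  rel <- cal$value / central_value(cal)
  truth <- beam_value(b, cal$position_mm) / beam_value(b, 0)
  expect_equal(rel, truth, tolerance = 1e-12)
  # unit factors are an identity
  unit <- tibble::tibble(detector = scan$detector, factor = 1)
  expect_equal(apply_calibration(scan, unit)$value, scan$value)
  # doubling one factor doubles only that detector
  f2 <- unit
  f2$factor[5] <- 2
  out <- apply_calibration(scan, f2)
  expect_equal(out$value[5], 2 * scan$value[5])
  expect_equal(out$value[-5], scan$value[-5])
  expect_error(apply_calibration(scan, unit[-1, ]),
               class = "cbctdose_error_validation")
  expect_error(apply_calibration(cal, unit), class = "cbctdose_error_state")
})

test_that("reference normalisation removes per-scan tube-output drift", {
  b <- default_beam()
  nm <- noise_model(0, 0, tube_drift_sd = 0.05, seed = 9)
  scans <- lapply(1:3, function(i) {
    simulate_diode_scan(b, array_spec(), nm, scan_index = i)
  })
  drifts <- vapply(scans, function(s) attr(s, "truth")$drift, numeric(1))
  expect_gt(max(abs(drifts / drifts[1] - 1)), 1e-4) # drift actually present
  corrected <- reference_normalize(scans)
  for (s in corrected) {
    expect_equal(s$value / scans[[1]]$value * 1,
                 rep(drifts[1] / drifts[1], 88), tolerance = 1e-12)
  }
  # equal references leave scans unchanged; correction is idempotent
  twice <- reference_normalize(corrected)
  for (i in 1:3) expect_equal(twice[[i]]$value, corrected[[i]]$value)
  bad <- scans[[1]]
  attr(bad, "reference_reading") <- 0
  expect_error(reference_normalize(list(bad)),
               class = "cbctdose_error_validation")
})

test_that("stitching merges shifted scans onto the ground-truth profile", {
  b <- default_beam()
  nm <- zero_noise()
  scans <- lapply(seq_along(campaign_shifts), function(i) {
    s <- simulate_diode_scan(b, array_spec(), nm,
                             array_shift_mm = campaign_shifts[i],
                             scan_index = i)
    apply_calibration(s, tibble::tibble(detector = s$detector, factor = 1))
  })
  merged <- stitch_scans(scans)
  expect_true(all(diff(merged$position_mm) > 0))
  expect_equal(merged$value, beam_value(b, merged$position_mm),
               tolerance = 1e-10)
  # single scan is an identity
  one <- stitch_scans(scans[1])
  expect_equal(one$value, scans[[1]]$value)
  # order invariance
  merged_rev <- stitch_scans(scans[c(3, 1, 2)])
  expect_equal(sort(merged_rev$position_mm), sort(merged$position_mm))
  expect_equal(merged_rev$value[order(merged_rev$position_mm)],
               merged$value[order(merged$position_mm)], tolerance = 1e-9)
  # insufficient overlap
  far <- simulate_diode_scan(b, array_spec(), nm, array_shift_mm = 1000,
                             scan_index = 4)
  far <- apply_calibration(far, tibble::tibble(detector = far$detector,
                                               factor = 1))
  expect_error(stitch_scans(list(scans[[1]], far)),
               class = "cbctdose_error_overlap")
  # a contradictory overlap (non-multiplicative disagreement) is flagged
  warped <- scans[[2]]
  warped$value <- warped$value * (1 + 0.2 * (warped$position_mm > 0))
  expect_warning(stitch_scans(list(scans[[1]], warped)),
                 class = "cbctdose_warning_overlap")
})

test_that("stitching leaves non-overlap regions at the scan's rescaled values", {
  b <- default_beam()
  nm <- default_noise(seed = 21)
  factors <- calibrate_array(simulate_calibration_sweep(b, array_spec(), nm))
  scans <- lapply(1:2, function(i) {
    s <- simulate_diode_scan(b, array_spec(), nm,
                             array_shift_mm = c(0, 150)[i], scan_index = i)
    apply_calibration(s, factors)
  })
  merged <- stitch_scans(scans)
  right_only <- scans[[2]]$position_mm > max(scans[[1]]$position_mm)
  merged_right <- merged$value[merged$position_mm >
                                 max(scans[[1]]$position_mm)]
  # every untouched node is the original value times one common scalar
  scale <- merged_right[1] / scans[[2]]$value[right_only][1]
  expect_equal(merged_right, scale * scans[[2]]$value[right_only],
               tolerance = 1e-14)
})

test_that("resampling interpolates linearly without extrapolation", {
  p <- cbct_profile(c(-10, 0, 10, 20), c(0, 1, 3, 3), state = "calibrated")
  expect_equal(resample_profile(p, p$position_mm)$value, p$value)
  expect_equal(resample_profile(p, 5)$value, 2) # midpoint -> mean of neighbours
  ramp <- cbct_profile(seq(-50, 50, 10), seq(-50, 50, 10) * 0.3 + 2,
                       state = "raw")
  expect_equal(resample_profile(ramp, c(-17.3, 4.1))$value,
               c(-17.3, 4.1) * 0.3 + 2)
  expect_error(resample_profile(p, 21), class = "cbctdose_error_range")
})

test_that("central value interpolates at the axis", {
  p <- cbct_profile(c(-7.5, -2.5, 2.5, 7.5), c(0.9, 1.1, 1.1, 0.9),
                    state = "calibrated")
  expect_equal(central_value(p), 1.1)
  ramp <- cbct_profile(c(-5, 5), c(-2, 2), state = "raw")
  expect_equal(central_value(ramp), 0)
  scan <- simulate_diode_scan(default_beam(), noise = zero_noise())
  expect_equal(central_value(scan), beam_value(default_beam(), 0),
               tolerance = 2e-3)
  off <- cbct_profile(c(5, 10), c(1, 1), state = "raw")
  expect_error(central_value(off), class = "cbctdose_error_range")
})

test_that("CAX normalisation is scale-invariant and idempotent", {
  scan <- simulate_diode_scan(default_beam(), noise = zero_noise())
  rel <- normalize_to_cax(scan)
  expect_identical(attr(rel, "state"), "relative")
  expect_equal(central_value(rel), 1)
  scaled <- cbct_profile(scan$position_mm, scan$value * 3.7, state = "raw")
  expect_equal(normalize_to_cax(scaled)$value, rel$value, tolerance = 1e-12)
  expect_equal(normalize_to_cax(rel)$value, rel$value)
})

test_that("profile comparison reports pointwise and area deviations", {
  x <- seq(-200, 200, 5)
  v <- beam_value(default_beam(), x)
  a <- normalize_to_cax(cbct_profile(x, v, state = "calibrated"))
  res <- compare_profiles(a, a)
  expect_equal(res$max_point_dev_pct, 0)
  expect_equal(res$area_diff_pct, 0)
  # global scale differences vanish after re-normalisation
  b2 <- normalize_to_cax(cbct_profile(x, 1.02 * v, state = "calibrated"))
  res2 <- compare_profiles(a, b2)
  expect_lt(res2$max_point_dev_pct, 1e-10)
  # a localised +0.04 bump at one interior node
  k <- 30
  vb <- a$value
  vb[k] <- vb[k] + 0.04
  bumped <- cbct_profile(x, vb, state = "calibrated")
  attr(bumped, "state") <- "relative"
  res3 <- compare_profiles(bumped, a)
  expect_equal(res3$max_point_dev_pct, 4.0, tolerance = 1e-9)
  area_a <- pracma::trapz(x, a$value)
  bump_area <- 0.04 * 5 # trapezoid: half base on each side
  expect_equal(res3$area_diff_pct, 100 * bump_area / area_a,
               tolerance = 1e-9)
  # insufficient overlap
  left <- normalize_to_cax(cbct_profile(x - 180, v, state = "calibrated"))
  expect_error(compare_profiles(a, left), class = "cbctdose_error_overlap")
})

test_that("a zero-noise campaign reproduces the CAX-normalised beam", {
  b <- default_beam()
  rel <- run_campaign(b, zero_noise())
  truth <- beam_value(b, rel$position_mm) / beam_value(b, 0)
  expect_equal(rel$value, truth, tolerance = 1e-9)
})
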