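test_that("temperature-pressure correction behaves as the ideal-gas form", {
  expect_equal(ktp(20, 101.325), 1.0)
  expect_equal(round(ktp(22, 100, 20, 101.325), 4), 1.0202)
  # monotone in temperature at fixed pressure
  temps <- seq(15, 30, by = 1)
  expect_true(all(diff(vapply(temps, ktp, numeric(1),
                              pressure_kpa = 101.325)) > 0))
  expect_error(ktp(20, -1), class = "cbctdose_error_validation")
})

test_that("polarity correction is the two-polarity mean over the used reading", {
  expect_equal(polarity_correction(1, -1), 1.0)
  expect_equal(polarity_correction(1.00, -0.98, used = "plus"), 0.99)
  expect_equal(polarity_correction(-1.00, 0.98, used = "plus"),
               polarity_correction(1.00, -0.98, used = "plus"))
  expect_error(polarity_correction(0, 1), class = "cbctdose_error_validation")
})

test_that("two-voltage recombination correction follows the continuous-beam form", {
  expect_equal(ion_recombination(2, 2, 300, 150), 1.0)
  expect_equal(round(ion_recombination(1.006, 1, 300, 150), 4), 1.0020)
  expect_gte(ion_recombination(1.01, 1, 300, 150), 1)
  expect_error(ion_recombination(4.1, 1, 300, 150),
               class = "cbctdose_error_saturation")
})

test_that("corrected reading multiplies the mean raw reading by all factors", {
  rs <- reading_set(c(2.0, 2.0))
  expect_equal(corrected_reading(rs), 2.0)
  expect_equal(corrected_reading(reading_set(c(1.9, 2.1))), 2.0)
  rs2 <- reading_set(c(2.0), temperature_c = 22, pressure_kpa = 100,
                     m_plus = 1, m_minus = -0.98, m_high = 1.006, m_low = 1,
                     extra_correction = 1.05)
  expect_equal(
    corrected_reading(rs2, electrometer_factor = 1.002),
    2.0 * ktp(22, 100) * 0.99 * ion_recombination(1.006, 1, 300, 150) *
      1.002 * 1.05
  )
})

test_that("Nk interpolation is linear in HVL with a bounded range", {
  cal <- chamber_calibration("c", data.frame(hvl_mm_al = c(5, 7),
                                             nk = c(1.00, 1.02)))
  expect_equal(interpolate_nk(cal, 5), 1.00)
  expect_equal(interpolate_nk(cal, 6), 1.01)
  expect_equal(interpolate_nk(cal, 5.75), 1.0075)
  expect_error(interpolate_nk(cal, 9), class = "cbctdose_error_range")
})

test_that("TG-61 dose is the product of reading, Nk and the two quality factors", {
  expect_equal(dose_to_water_tg61(1, 1, 1, 1), 1.0)
  expect_equal(dose_to_water_tg61(2.5, 0.045, 1.02, 1.05), 0.1204875)
  expect_equal(dose_to_water_tg61(5.0, 0.045, 1.02, 1.05),
               2 * dose_to_water_tg61(2.5, 0.045, 1.02, 1.05))
  expect_error(dose_to_water_tg61(-1, 1, 1, 1),
               class = "cbctdose_error_validation")
})

test_that("zero-noise reading sets round-trip through the TG-61 chain", {
  cal <- example_chamber_cal()
  cases <- expand.grid(dose = c(0.003, 0.031), ppol = c(1, 1.01),
                       pion = c(1, 1.004), t = c(18, 24))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    rs <- simulate_reading_set(cs$dose, cal, 6.0, zero_noise(),
                               temperature_c = cs$t, pressure_kpa = 100.2,
                               ppol = cs$ppol, pion = cs$pion)
    expect_equal(tg61_dose(rs, cal, 6.0), cs$dose, tolerance = 1e-10)
  }
})

test_that("the dose pipeline is exactly proportional to the raw reading", {
  cal <- example_chamber_cal()
  rs1 <- reading_set(c(1.0), temperature_c = 22, pressure_kpa = 100,
                     m_plus = 1, m_minus = -0.99, m_high = 1.004, m_low = 1)
  rs3 <- reading_set(c(3.0), temperature_c = 22, pressure_kpa = 100,
                     m_plus = 1, m_minus = -0.99, m_high = 1.004, m_low = 1)
  expect_identical(tg61_dose(rs3, cal, 6.0), 3 * tg61_dose(rs1, cal, 6.0))
})

test_that("HVL estimation recovers ln(2)/mu on exact exponentials", {
  for (mu in seq(0.08, 0.20, by = 0.02)) {
    att <- data.frame(thickness_mm_al = seq(0, 12, by = 1),
                      transmission = exp(-mu * seq(0, 12, by = 1)))
    expect_equal(estimate_hvl(att), log(2) / mu, tolerance = 1e-3)
  }
  expect_equal(estimate_hvl(data.frame(thickness_mm_al = 0:10,
                                       transmission = exp(-0.12 * (0:10)))),
               log(2) / 0.12, tolerance = 1e-3)
})

test_that("HVL estimation handles exact crossings, rescaling and bad series", {
  att <- data.frame(thickness_mm_al = c(0, 2, 4.2, 6),
                    transmission = c(1, 0.8, 0.5, 0.35))
  expect_identical(estimate_hvl(att), 4.2)
  scaled <- att
  scaled$transmission <- att$transmission * 7.3
  expect_equal(estimate_hvl(scaled), estimate_hvl(att))
  expect_error(
    estimate_hvl(data.frame(thickness_mm_al = 0:2,
                            transmission = c(1, 0.8, 0.9))),
    class = "cbctdose_error_validation"
  )
  expect_error(
    estimate_hvl(data.frame(thickness_mm_al = 0:2,
                            transmission = c(1, 0.9, 0.8))),
    class = "cbctdose_error_range"
  )
})

test_that("dose is rescaled to cGy per 100 mAs", {
  expect_equal(dose_per_100mas(0.030, 1000), 0.30)
  expect_equal(dose_per_100mas(0.0025, 100), 0.25)
  expect_equal(dose_per_100mas(0.006, 500), 2 * dose_per_100mas(0.003, 500))
  expect_error(dose_per_100mas(0.03, 0), class = "cbctdose_error_validation")
})

test_that("average periphery is the mean of exactly four positions", {
  expect_equal(round(average_periphery(c(0.37, 0.35, 0.35, 0.38)), 2), 0.36)
  expect_equal(round(average_periphery(c(0.29, 0.28, 0.28, 0.30)), 2), 0.29)
  expect_equal(average_periphery(rep(0.4, 4)), 0.4)
  expect_error(average_periphery(c(0.3, 0.3, 0.3)),
               class = "cbctdose_error_validation")
  expect_error(average_periphery(c(0.3, 0.3, 0.3, -0.1)),
               class = "cbctdose_error_validation")
})
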