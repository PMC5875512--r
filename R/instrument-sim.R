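#' Linear diode array geometry
#'
#' Describes the detector array used for longitudinal profile acquisition.
#' Defaults match a 440 mm array of 88 diodes at 5 mm pitch with 2.5 mm^2
#' active area, centred on the beam axis (so no diode sits exactly at
#' isocenter: positions fall at ±2.5, ±7.5, ... mm).
#'
#' @param n_detectors Number of diodes (> 1).
#' @param pitch_mm Detector spacing (mm).
#' @param active_area_mm2 Active area per diode (mm^2), metadata only.
#' @param reference_position Where the tube-output reference diode sits:
#'   `"centre"` (on the beam axis) or `"off_axis"` (at a quarter field
#'   length). Both are inside the field; the exact location cancels in
#'   output normalisation, which uses reference-reading ratios.
#' @return An `array_spec` list; `span_mm` is derived as
#'   `(n_detectors - 1) * pitch_mm`.
#' @export
array_spec <- function(n_detectors = 88L, pitch_mm = 5,
                       active_area_mm2 = 2.5,
                       reference_position = c("centre", "off_axis")) {
  reference_position <- match.arg(reference_position)
  if (!is.numeric(n_detectors) || n_detectors < 2) {
    abort_cbct("`n_detectors` must be an integer > 1.",
               "cbctdose_error_validation")
  }
  stop_if_not_number(pitch_mm, "pitch_mm", positive = TRUE)
  structure(
    list(
      n_detectors = as.integer(n_detectors),
      pitch_mm = pitch_mm,
      span_mm = (as.integer(n_detectors) - 1L) * pitch_mm,
      active_area_mm2 = active_area_mm2,
      reference_position = reference_position
    ),
    class = "array_spec"
  )
}

#' Instrument noise model
#'
#' All noise magnitudes are relative (multiplicative). One integer seed
#' drives a whole measurement campaign; every simulator derives
#' deterministic sub-streams from it, so identical inputs and seed give
#' bit-identical output, and per-detector sensitivities are shared across
#' all simulations using the same noise model (as they would be for a
#' physical array).
#'
#' @param detector_sensitivity_sd Relative sd of per-diode sensitivity.
#' @param reading_noise_sd Relative sd of a single reading.
#' @param tube_drift_sd Relative sd of the per-scan tube-output factor
#'   (captured by the reference diode).
#' @param seed Integer campaign seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(detector_sensitivity_sd = 0.03,
                        reading_noise_sd = 0.005,
                        tube_drift_sd = 0.01,
                        seed = 1L) {
  for (nm in c("detector_sensitivity_sd", "reading_noise_sd", "tube_drift_sd")) {
    v <- get(nm)
    stop_if_not_number(v, nm)
    if (v < 0 || v > 0.2) {
      abort_cbct(sprintf("`%s` must be in [0, 0.2].", nm),
                 "cbctdose_error_validation")
    }
  }
  structure(
    list(
      detector_sensitivity_sd = detector_sensitivity_sd,
      reading_noise_sd = reading_noise_sd,
      tube_drift_sd = tube_drift_sd,
      seed = as.integer(seed)
    ),
    class = "noise_model"
  )
}

# fixed sub-stream allocation for one campaign seed
.stream <- list(sensitivity = 1L, scan_base = 1L, sweep = 34L, chamber = 35L,
                readings = 36L, attenuation = 37L)

detector_positions <- function(spec, array_shift_mm = 0) {
  n <- spec$n_detectors
  (seq_len(n) - (n + 1) / 2) * spec$pitch_mm + array_shift_mm
}

detector_sensitivities <- function(spec, noise) {
  with_private_seed(
    substream_seed(noise$seed, .stream$sensitivity),
    1 + noise$detector_sensitivity_sd * stats::rnorm(spec$n_detectors)
  )
}

reference_coordinate <- function(beam, spec) {
  if (spec$reference_position == "centre") 0 else beam$field_length_mm / 4
}

#' Simulate one diode-array profile scan
#'
#' Each diode reads `beam_value(x_i) * sensitivity_i * drift * (1 + eps_i)`
#' where `drift` is a single tube-output factor shared by the whole scan and
#' recorded by the stationary reference diode. The array can be shifted
#' longitudinally (`array_shift_mm`) to capture tails beyond its span.
#'
#' @param beam A [ground_truth_beam()].
#' @param spec An [array_spec()].
#' @param noise A [noise_model()].
#' @param array_shift_mm Longitudinal array offset (mm).
#' @param scan_index Index of this scan within the campaign; selects the
#'   drift/noise sub-stream (1--32).
#' @return A raw-state [cbct_profile()] with columns `detector`,
#'   `position_mm`, `value`, the reference reading in
#'   `attr(, "reference_reading")`, and the simulation ground truth
#'   (sensitivities, drift) in `attr(, "truth")`.
#' @export
simulate_diode_scan <- function(beam, spec = array_spec(),
                                noise = noise_model(),
                                array_shift_mm = 0, scan_index = 1L) {
  stopifnot(inherits(beam, "ground_truth_beam"), inherits(spec, "array_spec"),
            inherits(noise, "noise_model"))
  if (scan_index < 1L || scan_index > 32L) {
    abort_cbct("`scan_index` must be in 1..32.", "cbctdose_error_validation")
  }
  x <- detector_positions(spec, array_shift_mm)
  sens <- detector_sensitivities(spec, noise)
  sim <- with_private_seed(
    substream_seed(noise$seed, .stream$scan_base + as.integer(scan_index)), {
      drift <- 1 + noise$tube_drift_sd * stats::rnorm(1)
      eps <- noise$reading_noise_sd * stats::rnorm(spec$n_detectors)
      eps_ref <- noise$reading_noise_sd * stats::rnorm(1)
      list(drift = drift, eps = eps, eps_ref = eps_ref)
    }
  )
  values <- beam_value(beam, x) * sens * sim$drift * (1 + sim$eps)
  ref <- beam_value(beam, reference_coordinate(beam, spec)) *
    sim$drift * (1 + sim$eps_ref)
  prof <- cbct_profile(
    position_mm = x, value = values, state = "raw",
    depth_mm = beam$depth_mm, kvp = beam$kvp,
    detector = seq_len(spec$n_detectors),
    reference_reading = ref, shift_mm = array_shift_mm
  )
  attr(prof, "truth") <- list(sensitivities = sens, drift = sim$drift)
  prof
}

#' Simulate an array calibration sweep
#'
#' Emulates the calibration procedure in which the array is stepped through
#' the beam so that every diode is exposed to the same beam portion. Each
#' positioning is a separate exposure with its own tube-output factor,
#' recorded by the reference diode, so readings are contaminated only by
#' diode sensitivity and reading noise after reference correction.
#'
#' @inheritParams simulate_diode_scan
#' @return A tibble with columns `detector`, `reading`,
#'   `reference_reading`; true sensitivities in `attr(, "truth")`.
#' @export
simulate_calibration_sweep <- function(beam, spec = array_spec(),
                                       noise = noise_model()) {
  stopifnot(inherits(beam, "ground_truth_beam"), inherits(spec, "array_spec"),
            inherits(noise, "noise_model"))
  n <- spec$n_detectors
  sens <- detector_sensitivities(spec, noise)
  b0 <- beam_value(beam, 0)
  bref <- beam_value(beam, reference_coordinate(beam, spec))
  sim <- with_private_seed(substream_seed(noise$seed, .stream$sweep), {
    drift <- 1 + noise$tube_drift_sd * stats::rnorm(n)
    eps <- noise$reading_noise_sd * stats::rnorm(n)
    eps_ref <- noise$reading_noise_sd * stats::rnorm(n)
    list(drift = drift, eps = eps, eps_ref = eps_ref)
  })
  out <- tibble::tibble(
    detector = seq_len(n),
    reading = b0 * sens * sim$drift * (1 + sim$eps),
    reference_reading = bref * sim$drift * (1 + sim$eps_ref)
  )
  attr(out, "truth") <- list(sensitivities = sens)
  class(out) <- c("calibration_sweep", class(out))
  out
}

#' Simulate an ion-chamber point-dose scan
#'
#' Point doses on a regular longitudinal grid wide enough to cover the
#' scatter tails (half-span `L/2 + 4 * tail_decay_mm`), emulating a phantom
#' stepped through the scan region with a full CBCT delivery per point.
#'
#' @inheritParams simulate_diode_scan
#' @param step_mm Grid spacing (mm), > 0.
#' @return A raw-state [cbct_profile()] (columns `position_mm`, `value`).
#' @export
simulate_chamber_scan <- function(beam, step_mm = 2, noise = noise_model()) {
  stopifnot(inherits(beam, "ground_truth_beam"), inherits(noise, "noise_model"))
  stop_if_not_number(step_mm, "step_mm", positive = TRUE)
  half_steps <- ceiling((beam$field_length_mm / 2 + 4 * beam$tail_decay_mm) /
                          step_mm)
  x <- seq(-half_steps, half_steps) * step_mm
  eps <- with_private_seed(
    substream_seed(noise$seed, .stream$chamber),
    noise$reading_noise_sd * stats::rnorm(length(x))
  )
  cbct_profile(
    position_mm = x, value = beam_value(beam, x) * (1 + eps),
    state = "raw", depth_mm = beam$depth_mm, kvp = beam$kvp
  )
}

#' Simulate an electrometer reading set with known true dose
#'
#' Constructs a [reading_set()] that, pushed through the TG-61 chain
#' ([corrected_reading()], [interpolate_nk()], [dose_to_water_tg61()]),
#' recovers `true_dose_gy`. With all noise terms zero the round trip is
#' exact; with reading noise the mean recovered dose converges on the truth.
#'
#' @param true_dose_gy Ground-truth absorbed dose to water (Gy).
#' @param cal A [chamber_calibration()].
#' @param hvl_mm_al Beam quality (first HVL, mm Al) used for Nk lookup.
#' @param noise A [noise_model()]; only `reading_noise_sd` and `seed` apply.
#' @param temperature_c,pressure_kpa Measurement environment.
#' @param ref_temperature_c,ref_pressure_kpa Calibration reference
#'   conditions.
#' @param n_readings Number of raw electrometer readings.
#' @param ppol,pion True polarity / recombination factors to embed (the
#'   generated correction-measurement pairs reproduce them exactly).
#' @param extra_correction User field-size/depth correction embedded in the
#'   set.
#' @return A [reading_set()]; the truth is stored in
#'   `attr(, "true_dose_gy")`.
#' @export
simulate_reading_set <- function(true_dose_gy, cal, hvl_mm_al,
                                 noise = noise_model(),
                                 temperature_c = 20, pressure_kpa = 101.325,
                                 ref_temperature_c = 20,
                                 ref_pressure_kpa = 101.325,
                                 n_readings = 3L, ppol = 1, pion = 1,
                                 extra_correction = 1) {
  stop_if_not_number(true_dose_gy, "true_dose_gy", positive = TRUE)
  stopifnot(inherits(cal, "chamber_calibration"), inherits(noise, "noise_model"))
  if (pion < 1) {
    abort_cbct("`pion` must be >= 1 for a continuous beam.",
               "cbctdose_error_validation")
  }
  nk <- interpolate_nk(cal, hvl_mm_al)
  m_needed <- true_dose_gy / (nk * cal$pq_cham * cal$mu_en_ratio)
  ktp_v <- ktp(temperature_c, pressure_kpa, ref_temperature_c, ref_pressure_kpa)
  raw_mean <- m_needed /
    (ktp_v * ppol * pion * cal$electrometer_factor * extra_correction)
  eps <- with_private_seed(
    substream_seed(noise$seed, .stream$readings),
    noise$reading_noise_sd * stats::rnorm(n_readings)
  )
  v_high <- 300; v_low <- 150
  r2 <- (v_high / v_low)^2
  rs <- reading_set(
    raw_readings = raw_mean * (1 + eps),
    temperature_c = temperature_c, pressure_kpa = pressure_kpa,
    ref_temperature_c = ref_temperature_c, ref_pressure_kpa = ref_pressure_kpa,
    m_plus = raw_mean, m_minus = -(2 * ppol - 1) * raw_mean,
    m_high = raw_mean, m_low = raw_mean / (r2 - (r2 - 1) / pion),
    v_high = v_high, v_low = v_low,
    extra_correction = extra_correction
  )
  attr(rs, "true_dose_gy") <- true_dose_gy
  rs
}

#' Simulate an aluminium attenuation series for HVL measurement
#'
#' Narrow-beam exponential attenuation `exp(-mu * t)` with relative reading
#' noise, normalised to the zero-thickness reading.
#'
#' @param mu_per_mm Linear attenuation coefficient (1/mm), > 0.
#' @param thicknesses_mm Added aluminium thicknesses (mm); 0 is prepended if
#'   absent.
#' @param noise A [noise_model()]; only `reading_noise_sd` and `seed` apply.
#' @return A tibble with columns `thickness_mm_al`, `transmission`
#'   (transmission is exactly 1 at zero thickness).
#' @export
simulate_attenuation <- function(mu_per_mm, thicknesses_mm = 0:10,
                                 noise = noise_model()) {
  stop_if_not_number(mu_per_mm, "mu_per_mm", positive = TRUE)
  stopifnot(inherits(noise, "noise_model"))
  t <- sort(unique(c(0, thicknesses_mm)))
  eps <- with_private_seed(
    substream_seed(noise$seed, .stream$attenuation),
    noise$reading_noise_sd * stats::rnorm(length(t))
  )
  raw <- exp(-mu_per_mm * t) * (1 + eps)
  tibble::tibble(
    thickness_mm_al = t,
    transmission = raw / raw[t == 0]
  )
}
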