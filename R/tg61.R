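#' Ion chamber calibration data
#'
#' Holds the air-kerma calibration of a thimble chamber at kilovoltage
#' qualities: an Nk table indexed by first HVL (mm Al), the overall chamber
#' correction P_Q,cham, the water-to-air mean mass energy-absorption
#' coefficient ratio, and the electrometer correction factor.
#'
#' @param chamber_id Chamber identifier (free text).
#' @param nk_table Data frame with columns `hvl_mm_al` (strictly
#'   increasing) and `nk` (Gy per reading unit, > 0); at least two rows.
#' @param pq_cham Overall chamber correction factor, in (0.9, 1.1).
#' @param mu_en_ratio Water/air mean mass energy-absorption coefficient
#'   ratio, in (1.0, 1.2).
#' @param electrometer_factor Electrometer correction, > 0.
#' @return A `chamber_calibration` list.
#' @export
#' @examples
#' cal <- chamber_calibration(
#'   "NE2571",
#'   nk_table = data.frame(hvl_mm_al = c(5, 7), nk = c(0.0450, 0.0452))
#' )
chamber_calibration <- function(chamber_id, nk_table, pq_cham = 1.0,
                                mu_en_ratio = 1.05,
                                electrometer_factor = 1.0) {
  nk_table <- tibble::as_tibble(nk_table)
  if (!all(c("hvl_mm_al", "nk") %in% names(nk_table)) ||
      nrow(nk_table) < 2) {
    abort_cbct(
      "`nk_table` needs columns hvl_mm_al and nk with at least two rows.",
      "cbctdose_error_validation"
    )
  }
  if (any(diff(nk_table$hvl_mm_al) <= 0) || any(nk_table$nk <= 0)) {
    abort_cbct("`nk_table` must have strictly increasing hvl and nk > 0.",
               "cbctdose_error_validation")
  }
  if (pq_cham <= 0.9 || pq_cham >= 1.1) {
    abort_cbct("`pq_cham` must lie in (0.9, 1.1).", "cbctdose_error_validation")
  }
  if (mu_en_ratio <= 1.0 || mu_en_ratio >= 1.2) {
    abort_cbct("`mu_en_ratio` must lie in (1.0, 1.2).",
               "cbctdose_error_validation")
  }
  stop_if_not_number(electrometer_factor, "electrometer_factor", positive = TRUE)
  structure(
    list(chamber_id = chamber_id, nk_table = nk_table, pq_cham = pq_cham,
         mu_en_ratio = mu_en_ratio, electrometer_factor = electrometer_factor),
    class = "chamber_calibration"
  )
}

#' Electrometer reading set
#'
#' Raw chamber readings together with the environmental and
#' correction-measurement data needed to form the fully corrected reading M:
#' temperature/pressure, a polarity pair, a two-voltage recombination pair,
#' and an optional user-supplied field-size/depth correction relative to the
#' calibration reference conditions.
#'
#' @param raw_readings Raw electrometer readings (nC), nonempty.
#' @param temperature_c,pressure_kpa Conditions during measurement.
#' @param ref_temperature_c,ref_pressure_kpa Calibration reference
#'   conditions (defaults 20 degC, 101.325 kPa).
#' @param m_plus,m_minus Polarity-pair readings (nC), opposite signs.
#' @param m_high,m_low Two-voltage readings (nC) at `v_high`, `v_low`.
#' @param v_high,v_low Polarising voltages (V), `v_high > v_low > 0`.
#' @param extra_correction Field-size/depth correction factor (> 0,
#'   default 1).
#' @param used_polarity Which polarity the raw readings were taken at
#'   (`"plus"` or `"minus"`).
#' @return A `reading_set` list.
#' @export
reading_set <- function(raw_readings, temperature_c = 20,
                        pressure_kpa = 101.325,
                        ref_temperature_c = 20, ref_pressure_kpa = 101.325,
                        m_plus = 1, m_minus = -1,
                        m_high = 1, m_low = 1, v_high = 300, v_low = 150,
                        extra_correction = 1,
                        used_polarity = c("plus", "minus")) {
  used_polarity <- match.arg(used_polarity)
  if (length(raw_readings) < 1 || !is.numeric(raw_readings)) {
    abort_cbct("`raw_readings` must be a nonempty numeric vector.",
               "cbctdose_error_validation")
  }
  stop_if_not_number(pressure_kpa, "pressure_kpa", positive = TRUE)
  if (!(v_high > v_low && v_low > 0)) {
    abort_cbct("Voltages must satisfy v_high > v_low > 0.",
               "cbctdose_error_validation")
  }
  stop_if_not_number(extra_correction, "extra_correction", positive = TRUE)
  structure(
    list(raw_readings = raw_readings, temperature_c = temperature_c,
         pressure_kpa = pressure_kpa, ref_temperature_c = ref_temperature_c,
         ref_pressure_kpa = ref_pressure_kpa, m_plus = m_plus,
         m_minus = m_minus, m_high = m_high, m_low = m_low,
         v_high = v_high, v_low = v_low,
         extra_correction = extra_correction, used_polarity = used_polarity),
    class = "reading_set"
  )
}

#' Temperature-pressure correction factor
#'
#' `((273.2 + T) / (273.2 + T0)) * (P0 / P)`: converts a vented-chamber
#' reading to the air density of the calibration reference conditions.
#'
#' @param temperature_c,pressure_kpa Measurement conditions.
#' @param ref_temperature_c,ref_pressure_kpa Reference conditions.
#' @return The correction factor (1 at reference conditions).
#' @export
#' @examples
#' ktp(22, 100)  # warmer and thinner air than reference -> > 1
ktp <- function(temperature_c, pressure_kpa,
                ref_temperature_c = 20, ref_pressure_kpa = 101.325) {
  if (pressure_kpa <= 0 || ref_pressure_kpa <= 0 ||
      temperature_c <= -273.2 || ref_temperature_c <= -273.2) {
    abort_cbct("Nonphysical temperature or pressure.",
               "cbctdose_error_validation")
  }
  ((273.2 + temperature_c) / (273.2 + ref_temperature_c)) *
    (ref_pressure_kpa / pressure_kpa)
}

#' Polarity correction factor
#'
#' `(|M+| + |M-|) / (2 |M_used|)`; unity when the two polarities read the
#' same magnitude.
#'
#' @param m_plus,m_minus Readings at the two polarities (nonzero).
#' @param used Which polarity the service readings use.
#' @return The polarity correction factor.
#' @export
polarity_correction <- function(m_plus, m_minus,
                                used = c("plus", "minus")) {
  used <- match.arg(used)
  if (m_plus == 0 || m_minus == 0) {
    abort_cbct("Polarity readings must be nonzero.",
               "cbctdose_error_validation")
  }
  m_used <- if (used == "plus") m_plus else m_minus
  (abs(m_plus) + abs(m_minus)) / (2 * abs(m_used))
}

#' Ion recombination correction (continuous beam, two-voltage method)
#'
#' `P_ion = ((VH/VL)^2 - 1) / ((VH/VL)^2 - MH/ML)` for continuous beams.
#' Valid while `MH/ML < (VH/VL)^2`; readings closer to saturation than that
#' indicate the two-voltage model does not apply.
#'
#' @param m_high,m_low Readings (> 0) at the high and low voltage.
#' @param v_high,v_low Polarising voltages; a ratio of at least 2 is
#'   recommended.
#' @return The recombination correction factor (>= 1 when `m_high >= m_low`).
#' @export
ion_recombination <- function(m_high, m_low, v_high, v_low) {
  if (m_high <= 0 || m_low <= 0) {
    abort_cbct("Two-voltage readings must be > 0.",
               "cbctdose_error_validation")
  }
  if (!(v_high > v_low && v_low > 0)) {
    abort_cbct("Voltages must satisfy v_high > v_low > 0.",
               "cbctdose_error_validation")
  }
  r2 <- (v_high / v_low)^2
  ratio <- m_high / m_low
  if (ratio >= r2) {
    abort_cbct(
      "m_high/m_low >= (v_high/v_low)^2: two-voltage saturation model invalid.",
      "cbctdose_error_saturation"
    )
  }
  (r2 - 1) / (r2 - ratio)
}

#' Fully corrected electrometer reading M
#'
#' Mean raw reading multiplied by the temperature-pressure, polarity and
#' recombination corrections, the electrometer factor, and any
#' user-supplied field-size/depth correction.
#'
#' @param rs A [reading_set()].
#' @param electrometer_factor Electrometer correction (usually taken from
#'   the [chamber_calibration()]).
#' @return Corrected reading M (nC).
#' @export
corrected_reading <- function(rs, electrometer_factor = 1) {
  stopifnot(inherits(rs, "reading_set"))
  stop_if_not_number(electrometer_factor, "electrometer_factor",
                     positive = TRUE)
  mean(rs$raw_readings) *
    ktp(rs$temperature_c, rs$pressure_kpa,
        rs$ref_temperature_c, rs$ref_pressure_kpa) *
    polarity_correction(rs$m_plus, rs$m_minus, used = rs$used_polarity) *
    ion_recombination(rs$m_high, rs$m_low, rs$v_high, rs$v_low) *
    electrometer_factor * rs$extra_correction
}

#' Interpolate the air-kerma calibration factor by beam quality
#'
#' Linear interpolation of Nk in first HVL. The chamber's energy dependence
#' at kV qualities is small (a few percent across the table), so the
#' interpolation scheme is not critical; extrapolation is allowed only
#' within a 5% margin beyond the table ends.
#'
#' @param cal A [chamber_calibration()].
#' @param hvl_mm_al Beam quality (first HVL, mm Al).
#' @return Nk (Gy per reading unit).
#' @export
interpolate_nk <- function(cal, hvl_mm_al) {
  stopifnot(inherits(cal, "chamber_calibration"))
  tbl <- cal$nk_table
  lo <- min(tbl$hvl_mm_al); hi <- max(tbl$hvl_mm_al)
  margin <- 0.05 * (hi - lo)
  if (hvl_mm_al < lo - margin || hvl_mm_al > hi + margin) {
    abort_cbct(
      sprintf("HVL %.3f mm Al outside calibrated range [%.3f, %.3f] (+/- 5%%).",
              hvl_mm_al, lo, hi),
      "cbctdose_error_range"
    )
  }
  # within the 5% margin, values beyond the table are clamped to the end knot
  stats::approx(tbl$hvl_mm_al, tbl$nk, xout = hvl_mm_al, rule = 2)$y
}

#' Absorbed dose to water (TG-61, in-water kV formalism)
#'
#' `Dw = M * Nk * P_Q,cham * (mu_en/rho)_air^water`: the corrected reading
#' times the air-kerma calibration factor for the beam quality, the overall
#' chamber correction, and the water-to-air mean mass energy-absorption
#' coefficient ratio.
#'
#' @param m Corrected electrometer reading (from [corrected_reading()]).
#' @param nk Air-kerma calibration factor (from [interpolate_nk()]).
#' @param pq_cham Overall chamber correction factor.
#' @param mu_en_ratio Water/air mean mass energy-absorption ratio.
#' @return Absorbed dose to water (Gy).
#' @export
dose_to_water_tg61 <- function(m, nk, pq_cham, mu_en_ratio) {
  for (nm in c("m", "nk", "pq_cham", "mu_en_ratio")) {
    stop_if_not_number(get(nm), nm, positive = TRUE)
  }
  m * nk * pq_cham * mu_en_ratio
}

#' TG-61 dose from a reading set and chamber calibration
#'
#' Convenience wrapper chaining [corrected_reading()], [interpolate_nk()]
#' and [dose_to_water_tg61()].
#'
#' @param rs A [reading_set()].
#' @param cal A [chamber_calibration()].
#' @param hvl_mm_al Beam quality for the Nk lookup.
#' @return Absorbed dose to water (Gy).
#' @export
tg61_dose <- function(rs, cal, hvl_mm_al) {
  dose_to_water_tg61(
    corrected_reading(rs, cal$electrometer_factor),
    interpolate_nk(cal, hvl_mm_al),
    cal$pq_cham, cal$mu_en_ratio
  )
}

#' Estimate first half-value layer from an attenuation series
#'
#' Log-linear interpolation of `ln(transmission)` versus added aluminium
#' thickness to the 50% crossing. The series must be normalised to unit
#' transmission at zero thickness (any overall scale is removed first) and
#' strictly decreasing.
#'
#' @param attenuation Data frame with columns `thickness_mm_al` and
#'   `transmission`, bracketing transmission 0.5.
#' @return First HVL (mm Al).
#' @export
#' @examples
#' att <- data.frame(thickness_mm_al = 0:10,
#'                   transmission = exp(-0.12 * (0:10)))
#' estimate_hvl(att)  # log(2) / 0.12
estimate_hvl <- function(attenuation) {
  if (!all(c("thickness_mm_al", "transmission") %in% names(attenuation))) {
    abort_cbct("Need columns thickness_mm_al and transmission.",
               "cbctdose_error_validation")
  }
  ord <- order(attenuation$thickness_mm_al)
  t <- attenuation$thickness_mm_al[ord]
  tr <- attenuation$transmission[ord]
  if (length(t) < 2) {
    abort_cbct("Attenuation series needs at least two points.",
               "cbctdose_error_validation")
  }
  tr <- tr / tr[1]  # rescale to the zero-thickness reading
  if (any(diff(tr) >= 0)) {
    abort_cbct("Transmission series must be strictly decreasing.",
               "cbctdose_error_validation")
  }
  exact <- which(tr == 0.5)
  if (length(exact) == 1) return(t[exact])
  if (min(tr) > 0.5 || max(tr) < 0.5) {
    abort_cbct("Series does not bracket 50% transmission.",
               "cbctdose_error_range")
  }
  # ln(T) is piecewise linear in thickness between measurements
  stats::approx(log(tr), t, xout = log(0.5))$y
}

#' Scale a measured dose to cGy per 100 mAs
#'
#' @param dose_gy Measured dose (Gy) for the delivered exposure.
#' @param delivered_mas Delivered tube current-time product (mAs), > 0.
#' @return Dose in cGy per 100 mAs.
#' @export
dose_per_100mas <- function(dose_gy, delivered_mas) {
  stop_if_not_number(delivered_mas, "delivered_mas", positive = TRUE)
  dose_gy * 100 * (100 / delivered_mas)
}

#' Average peripheral dose
#'
#' Arithmetic mean of the four peripheral point doses (anterior, left,
#' posterior, right chamber positions).
#'
#' @param doses Numeric vector of exactly 4 nonnegative doses.
#' @return Mean dose, same units as the input.
#' @export
average_periphery <- function(doses) {
  if (length(doses) != 4 || !is.numeric(doses)) {
    abort_cbct("Exactly four peripheral doses (A, L, P, R) are required.",
               "cbctdose_error_validation")
  }
  if (any(doses < 0)) {
    abort_cbct("Peripheral doses must be >= 0.", "cbctdose_error_validation")
  }
  mean(doses)
}
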