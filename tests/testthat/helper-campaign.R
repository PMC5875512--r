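# Shared fixtures: default beam, noise settings, and a full array campaign
# (calibration sweep -> three shifted scans -> calibrate/apply -> output
# correction -> stitch -> CAX normalisation).

default_beam <- function(...) ground_truth_beam(...)

zero_noise <- function(seed = 1L) noise_model(0, 0, 0, seed = seed)

default_noise <- function(seed = 1L) {
  noise_model(detector_sensitivity_sd = 0.03, reading_noise_sd = 0.005,
              tube_drift_sd = 0.01, seed = seed)
}

campaign_shifts <- c(0, -100, 100)

run_campaign <- function(beam = default_beam(), noise = zero_noise(),
                         spec = array_spec(), shifts = campaign_shifts) {
  sweep <- simulate_calibration_sweep(beam, spec, noise)
  factors <- calibrate_array(sweep)
  scans <- lapply(seq_along(shifts), function(i) {
    apply_calibration(
      simulate_diode_scan(beam, spec, noise, array_shift_mm = shifts[i],
                          scan_index = i),
      factors
    )
  })
  normalize_to_cax(stitch_scans(reference_normalize(scans)))
}

example_chamber_cal <- function() {
  chamber_calibration(
    "NE2571",
    nk_table = data.frame(hvl_mm_al = c(4, 6, 8),
                          nk = c(0.0448, 0.0450, 0.0452)),
    pq_cham = 1.02, mu_en_ratio = 1.05, electrometer_factor = 1.002
  )
}

# dense absolute profile of a beam on a grid covering the tails
dense_absolute_profile <- function(beam, step_mm = 0.5) {
  half <- beam$field_length_mm / 2 + 8 * beam$tail_decay_mm
  x <- seq(-half, half, by = step_mm)
  cbct_profile(x, beam_value(beam, x), state = "absolute")
}
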