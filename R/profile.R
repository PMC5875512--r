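#' Longitudinal dose profile
#'
#' A sampled longitudinal dose curve: a tibble with columns `position_mm`
#' (strictly increasing, isocenter at 0, positive toward the gantry) and
#' `value`, plus acquisition metadata carried as attributes. The `state`
#' attribute tracks processing: `raw` (as read from the instrument) ->
#' `calibrated` (per-detector factors applied) -> `relative` (normalised to
#' the central axis) -> `absolute` (rescaled to mGy per 100 mAs).
#' Transitions only move forward.
#'
#' @param position_mm Strictly increasing positions (mm).
#' @param value Readings (raw/calibrated), relative dose, or mGy per
#'   100 mAs (absolute).
#' @param state One of `"raw"`, `"calibrated"`, `"relative"`, `"absolute"`.
#' @param depth_mm,kvp,collimator Acquisition metadata.
#' @param detector Optional detector indices (for array scans).
#' @param reference_reading Optional reference-diode reading for the scan.
#' @param shift_mm Optional array shift applied during acquisition.
#' @return A `cbct_profile` tibble.
#' @export
cbct_profile <- function(position_mm, value,
                         state = c("raw", "calibrated", "relative", "absolute"),
                         depth_mm = NA_real_, kvp = NA_real_,
                         collimator = NA_character_, detector = NULL,
                         reference_reading = NULL, shift_mm = NULL) {
  state <- match.arg(state)
  if (length(position_mm) != length(value)) {
    abort_cbct("`position_mm` and `value` must have equal length.",
               "cbctdose_error_validation")
  }
  if (any(diff(position_mm) <= 0)) {
    abort_cbct("`position_mm` must be strictly increasing.",
               "cbctdose_error_validation")
  }
  if (state != "raw" && any(value < 0)) {
    abort_cbct("Calibrated profile values must be >= 0.",
               "cbctdose_error_validation")
  }
  cols <- if (is.null(detector)) {
    tibble::tibble(position_mm = position_mm, value = value)
  } else {
    tibble::tibble(detector = detector, position_mm = position_mm,
                   value = value)
  }
  structure(
    cols,
    class = c("cbct_profile", class(cols)),
    state = state, depth_mm = depth_mm, kvp = kvp, collimator = collimator,
    reference_reading = reference_reading, shift_mm = shift_mm
  )
}

profile_state <- function(profile) attr(profile, "state")

assert_state <- function(profile, expected, op) {
  if (!inherits(profile, "cbct_profile")) {
    abort_cbct(sprintf("%s() expects a cbct_profile.", op),
               "cbctdose_error_validation")
  }
  if (!profile_state(profile) %in% expected) {
    abort_cbct(
      sprintf("%s() requires profile state %s (got '%s').",
              op, paste(sQuote(expected), collapse = " or "),
              profile_state(profile)),
      "cbctdose_error_state"
    )
  }
  invisible(profile)
}

set_profile <- function(profile, value = NULL, position_mm = NULL,
                        state = NULL) {
  at <- attributes(profile)
  if (!is.null(value)) profile$value <- value
  if (!is.null(position_mm)) profile$position_mm <- position_mm
  for (a in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(profile, a) <- at[[a]]
  }
  if (!is.null(state)) attr(profile, "state") <- state
  profile
}

#' @export
print.cbct_profile <- function(x, ...) {
  cat(sprintf("<cbct_profile> state=%s, %d samples over [%.1f, %.1f] mm\n",
              profile_state(x), nrow(x), min(x$position_mm),
              max(x$position_mm)))
  NextMethod()
}

#' Derive per-detector calibration factors from a sweep
#'
#' In a calibration sweep every diode is exposed to the same portion of the
#' beam, so after dividing out the per-exposure reference reading the only
#' detector-to-detector variation left is sensitivity. Factors are
#' proportional to 1/sensitivity and normalised to mean 1; they are
#' invariant to any global scale of the sweep readings.
#'
#' @param sweep A sweep tibble from [simulate_calibration_sweep()] or read
#'   from file: columns `detector`, `reading`, `reference_reading`.
#' @return A tibble of class `calibration_factors` with columns `detector`,
#'   `factor`.
#' @export
calibrate_array <- function(sweep) {
  need <- c("detector", "reading", "reference_reading")
  if (!all(need %in% names(sweep))) {
    abort_cbct("Sweep needs columns detector, reading, reference_reading.",
               "cbctdose_error_validation")
  }
  bad <- sweep$detector[!is.finite(sweep$reading) | sweep$reading <= 0]
  if (length(bad) > 0) {
    abort_cbct(
      sprintf("Sweep has missing/invalid readings for detector(s) %s.",
              paste(bad, collapse = ", ")),
      "cbctdose_error_coverage"
    )
  }
  out <- sweep |>
    dplyr::group_by(.data$detector) |>
    dplyr::summarise(
      response = mean(.data$reading / .data$reference_reading),
      .groups = "drop"
    ) |>
    dplyr::mutate(factor = (1 / .data$response) /
                    mean(1 / .data$response)) |>
    dplyr::select("detector", "factor")
  class(out) <- c("calibration_factors", class(out))
  out
}

#' Apply calibration factors to a raw array scan
#'
#' @param profile A raw-state [cbct_profile()] with a `detector` column.
#' @param factors [calibrate_array()] output matching the scan's detectors.
#' @return The profile with `value * factor`, state `calibrated`.
#' @export
apply_calibration <- function(profile, factors) {
  assert_state(profile, "raw", "apply_calibration")
  if (!"detector" %in% names(profile)) {
    abort_cbct("Profile has no detector column; cannot match factors.",
               "cbctdose_error_validation")
  }
  if (!setequal(profile$detector, factors$detector)) {
    abort_cbct("Detector sets of profile and factors differ.",
               "cbctdose_error_validation")
  }
  f <- factors$factor[match(profile$detector, factors$detector)]
  set_profile(profile, value = profile$value * f, state = "calibrated")
}

#' Correct a set of scans for tube-output variation
#'
#' Divides each scan by the ratio of its reference-diode reading to the
#' first scan's, so all scans share the first scan's output level. The
#' first scan is unchanged; applying the correction twice is a no-op
#' (references are reset to the common value).
#'
#' @param scans A list of [cbct_profile()]s, each carrying a positive
#'   `reference_reading` attribute.
#' @return The list of corrected scans.
#' @export
reference_normalize <- function(scans) {
  if (inherits(scans, "cbct_profile")) scans <- list(scans)
  refs <- vapply(scans, function(s) {
    r <- attr(s, "reference_reading")
    if (is.null(r) || !is.finite(r) || r <= 0) {
      abort_cbct("Every scan needs a positive reference_reading.",
                 "cbctdose_error_validation")
    }
    r
  }, numeric(1))
  purrr::map2(scans, refs, function(s, r) {
    out <- set_profile(s, value = s$value / (r / refs[1]))
    attr(out, "reference_reading") <- refs[1]
    out
  })
}

#' Stitch shifted array scans into one profile
#'
#' For long fields at depth the centred array cannot capture the full
#' scatter tail; the array is shifted each way and the shifted acquisitions
#' are superimposed. Each subsequent scan is rescaled by a single
#' least-squares scalar so it agrees with the accumulating merge over their
#' overlap (at least 3 detectors), then positions are merged; samples at
#' coinciding positions are averaged. Regions with no overlap keep the
#' scan's values unchanged (up to its global rescale).
#'
#' @param scans A list of output-corrected, calibrated [cbct_profile()]s
#'   whose positions already include the acquisition shift.
#' @param min_overlap Minimum number of overlapping samples (default 3).
#' @return A merged, calibrated [cbct_profile()].
#' @export
stitch_scans <- function(scans, min_overlap = 3L) {
  if (inherits(scans, "cbct_profile")) scans <- list(scans)
  if (length(scans) == 0) {
    abort_cbct("Need at least one scan.", "cbctdose_error_validation")
  }
  for (s in scans) assert_state(s, c("raw", "calibrated"), "stitch_scans")
  merged <- tibble::tibble(position_mm = scans[[1]]$position_mm,
                           value = scans[[1]]$value)
  for (s in scans[-1]) {
    inside <- s$position_mm >= min(merged$position_mm) &
      s$position_mm <= max(merged$position_mm)
    if (sum(inside) < min_overlap) {
      abort_cbct(
        sprintf("Scan overlaps merge by %d samples; need >= %d.",
                sum(inside), min_overlap),
        "cbctdose_error_overlap"
      )
    }
    m <- stats::approx(merged$position_mm, merged$value,
                       xout = s$position_mm[inside])$y
    v <- s$value[inside]
    scale <- sum(m * v) / sum(v * v)
    resid <- max(abs(m - scale * v))
    ref_level <- if (0 >= min(merged$position_mm) &&
                     0 <= max(merged$position_mm)) {
      stats::approx(merged$position_mm, merged$value, xout = 0)$y
    } else {
      max(merged$value)
    }
    if (resid > 0.05 * ref_level) {
      rlang::warn(sprintf(
        "stitch_scans: post-fit overlap residual %.3g exceeds 5%% of the central value.",
        resid
      ), class = "cbctdose_warning_overlap")
    }
    merged <- dplyr::bind_rows(
      merged,
      tibble::tibble(position_mm = s$position_mm, value = scale * s$value)
    ) |>
      dplyr::mutate(pos_key = round(.data$position_mm / 1e-6) * 1e-6) |>
      dplyr::group_by(.data$pos_key) |>
      dplyr::summarise(position_mm = .data$position_mm[1],
                       value = mean(.data$value), .groups = "drop") |>
      dplyr::arrange(.data$position_mm) |>
      dplyr::select("position_mm", "value")
  }
  first <- scans[[1]]
  cbct_profile(
    position_mm = merged$position_mm, value = pmax(merged$value, 0),
    state = "calibrated",
    depth_mm = attr(first, "depth_mm"), kvp = attr(first, "kvp"),
    collimator = attr(first, "collimator"),
    reference_reading = attr(first, "reference_reading")
  )
}

#' Resample a profile onto a new position grid
#'
#' Linear interpolation; exact at original nodes. No extrapolation: the
#' grid must lie within the measured extent.
#'
#' @param profile A [cbct_profile()].
#' @param grid_mm New positions (mm), strictly increasing.
#' @return The profile resampled onto `grid_mm`.
#' @export
resample_profile <- function(profile, grid_mm) {
  stopifnot(inherits(profile, "cbct_profile"))
  if (min(grid_mm) < min(profile$position_mm) ||
      max(grid_mm) > max(profile$position_mm)) {
    abort_cbct("Grid extends beyond the measured extent; no extrapolation.",
               "cbctdose_error_range")
  }
  v <- stats::approx(profile$position_mm, profile$value, xout = grid_mm)$y
  out <- cbct_profile(
    position_mm = grid_mm, value = v, state = profile_state(profile),
    depth_mm = attr(profile, "depth_mm"), kvp = attr(profile, "kvp"),
    collimator = attr(profile, "collimator")
  )
  out
}

#' Central-axis value of a profile
#'
#' Linear interpolation at position 0. The 88-diode centred array has no
#' detector exactly on the axis, so interpolation between the two central
#' samples is used; for the flat-topped fields measured here the
#' interpolation error is negligible.
#'
#' @param profile A [cbct_profile()] whose extent contains 0.
#' @return The value at `position_mm = 0`.
#' @export
central_value <- function(profile) {
  stopifnot(inherits(profile, "cbct_profile"))
  if (min(profile$position_mm) > 0 || max(profile$position_mm) < 0) {
    abort_cbct("Position 0 is outside the measured extent.",
               "cbctdose_error_range")
  }
  stats::approx(profile$position_mm, profile$value, xout = 0)$y
}

#' Normalise a profile to its central-axis value
#'
#' @param profile A calibrated (or raw) [cbct_profile()] with positive
#'   central value.
#' @return The profile divided by its central value, state `relative`
#'   (central value of the result is 1). Idempotent and scale-invariant.
#' @export
normalize_to_cax <- function(profile) {
  assert_state(profile, c("raw", "calibrated", "relative"),
               "normalize_to_cax")
  cv <- central_value(profile)
  if (!is.finite(cv) || cv <= 0) {
    abort_cbct("Central value must be > 0 to normalise.",
               "cbctdose_error_validation")
  }
  set_profile(profile, value = profile$value / cv, state = "relative")
}

#' Compare two central-axis-normalised profiles
#'
#' Pointwise deviation is `(a - b)` at matched positions, expressed as a
#' percentage of the central-axis value (which is 1 for relative profiles);
#' this avoids dividing by near-zero tail values. The area difference is
#' the relative difference of the trapezoidal areas over the common extent.
#'
#' @param a,b Relative-state [cbct_profile()]s whose extents overlap by at
#'   least 80% of the shorter profile.
#' @return A one-row tibble: `max_point_dev_pct`, `area_diff_pct`.
#' @export
compare_profiles <- function(a, b) {
  assert_state(a, "relative", "compare_profiles")
  assert_state(b, "relative", "compare_profiles")
  lo <- max(min(a$position_mm), min(b$position_mm))
  hi <- min(max(a$position_mm), max(b$position_mm))
  shorter <- min(diff(range(a$position_mm)), diff(range(b$position_mm)))
  if (hi <= lo || (hi - lo) < 0.8 * shorter) {
    abort_cbct("Profiles overlap by less than 80% of the shorter extent.",
               "cbctdose_error_overlap")
  }
  keep <- a$position_mm >= lo & a$position_mm <= hi
  x <- a$position_mm[keep]
  av <- a$value[keep]
  bv <- stats::approx(b$position_mm, b$value, xout = x)$y
  area_a <- trapz_area(x, av)
  area_b <- trapz_area(x, bv)
  tibble::tibble(
    max_point_dev_pct = 100 * max(abs(av - bv)),
    area_diff_pct = 100 * abs(area_a - area_b) / area_b
  )
}
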