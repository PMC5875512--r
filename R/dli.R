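#' Rescale a relative profile to absolute dose
#'
#' Multiplies a central-axis-normalised profile by the absolute point dose
#' measured at the corresponding phantom position, so the central value of
#' the result equals the point dose (converted cGy -> mGy).
#'
#' @param profile A relative-state [cbct_profile()].
#' @param point_dose_cgy_per_100mas Absolute point dose (cGy per 100 mAs);
#'   must be positive.
#' @return An absolute-state [cbct_profile()] in mGy per 100 mAs.
#' @export
to_absolute <- function(profile, point_dose_cgy_per_100mas) {
  assert_state(profile, "relative", "to_absolute")
  stop_if_not_number(point_dose_cgy_per_100mas, "point_dose_cgy_per_100mas",
                     positive = TRUE)
  set_profile(profile,
              value = profile$value * point_dose_cgy_per_100mas * 10,
              state = "absolute")
}

#' Dose line integral of an absolute profile
#'
#' Trapezoidal integration of the absolute longitudinal dose profile over
#' its full measured extent (positions converted mm -> cm). No
#' extrapolation is performed beyond the measured span; the span used is
#' recorded in the `truncation_extent_mm` attribute so results measured
#' with different spans can be flagged when compared.
#'
#' @param profile An absolute-state [cbct_profile()] with at least 2 nodes.
#' @return DLI in mGy.cm per 100 mAs, with attribute
#'   `truncation_extent_mm`.
#' @export
integrate_dli <- function(profile) {
  assert_state(profile, "absolute", "integrate_dli")
  if (nrow(profile) < 2) {
    abort_cbct("Need at least 2 nodes to integrate.",
               "cbctdose_error_validation")
  }
  dli <- trapz_area(profile$position_mm / 10, profile$value)
  structure(dli,
            truncation_extent_mm = diff(range(profile$position_mm)))
}

#' Radially weighted dose length product for CBCT
#'
#' Combines central and peripheral dose line integrals with the 1/3 : 2/3
#' radial weighting used in CT dosimetry:
#' \deqn{DLP_{CBCT} = \tfrac{1}{3}\,DLI_{centre} + \tfrac{2}{3}\,DLI_{periphery}.}
#' A convex combination: the result always lies between its two arguments.
#'
#' @param dli_center,dli_periphery DLIs (mGy.cm per 100 mAs), >= 0;
#'   vectorised.
#' @return DLP_CBCT (mGy.cm per 100 mAs).
#' @export
#' @examples
#' dlp_cbct(62.5, 73.4)
dlp_cbct <- function(dli_center, dli_periphery) {
  if (any(dli_center < 0) || any(dli_periphery < 0)) {
    abort_cbct("DLIs must be >= 0.", "cbctdose_error_validation")
  }
  dli_center / 3 + 2 * dli_periphery / 3
}

#' Integral dose from DLP_CBCT
#'
#' Total energy metric: DLP_CBCT multiplied by the phantom cross-sectional
#' area and tissue density. Defaults describe the 30 cm x 20 cm oval body
#' phantom (area pi*15*10 cm^2) with physical density 1.039 g/cm^3.
#'
#' @param dlp DLP_CBCT (mGy.cm).
#' @param cross_section_area_cm2 Phantom cross-sectional area (cm^2), > 0.
#' @param density_g_cm3 Tissue density (g/cm^3), > 0.
#' @return The product, in mGy.cm * cm^2 * g/cm^3.
#' @export
integral_dose <- function(dlp, cross_section_area_cm2 = pi * 15 * 10,
                          density_g_cm3 = 1.039) {
  stop_if_not_number(dlp, "dlp", positive = TRUE)
  stop_if_not_number(cross_section_area_cm2, "cross_section_area_cm2",
                     positive = TRUE)
  stop_if_not_number(density_g_cm3, "density_g_cm3", positive = TRUE)
  dlp * cross_section_area_cm2 * density_g_cm3
}

#' Build a DLI result row
#'
#' Packages central and peripheral DLIs with their DLP_CBCT and acquisition
#' metadata into a tidy one-row tibble.
#'
#' @param dli_center,dli_periphery DLIs (mGy.cm per 100 mAs).
#' @param phantom,collimator,kvp Metadata keys.
#' @param truncation_extent_mm Measured span used for the integration.
#' @return A one-row tibble of class `dli_result`.
#' @export
dli_result <- function(dli_center, dli_periphery, phantom = NA_character_,
                       collimator = NA_character_, kvp = NA_real_,
                       truncation_extent_mm = NA_real_) {
  out <- tibble::tibble(
    phantom = phantom, kvp = kvp, collimator = collimator,
    dli_center = as.numeric(dli_center),
    dli_periphery = as.numeric(dli_periphery),
    dlp_cbct = dlp_cbct(as.numeric(dli_center), as.numeric(dli_periphery)),
    truncation_extent_mm = truncation_extent_mm
  )
  class(out) <- c("dli_result", class(out))
  out
}
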