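#' Plot a longitudinal dose profile
#'
#' @param object A [cbct_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbct_profile <- function(object, ...) {
  ylab <- switch(profile_state(object),
                 raw = "reading",
                 calibrated = "calibrated reading",
                 relative = "relative dose (CAX = 1)",
                 absolute = "dose (mGy per 100 mAs)")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$position_mm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "longitudinal position (mm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a per-100-mAs dose table
#'
#' DLP_CBCT per collimator, grouped by phantom/kVp, showing how the
#' integral-dose metric tracks field length while point doses barely move.
#'
#' @param table A `dose_table`, e.g. [xvi_dose_table()].
#' @return A ggplot.
#' @export
plot_dose_table <- function(table) {
  stopifnot(is.data.frame(table))
  df <- dplyr::mutate(
    tibble::as_tibble(table),
    panel = sprintf("%s phantom, %g kVp (%s rotation)", .data$phantom,
                    .data$kvp, .data$rotation)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$collimator, y = .data$dlp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "collimator", y = "DLP_CBCT (mGy.cm per 100 mAs)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
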