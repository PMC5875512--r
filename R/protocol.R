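# XVI collimator cassette geometry: FOV width by letter, field length by number
.fov_width_mm <- c(S = 276.7, M = 426.4, L = 524)
.field_length_mm <- c(`2` = 35.2, `10` = 135.4, `15` = 178.7, `20` = 276.7)

#' Parse an XVI collimator code
#'
#' A collimator cassette is named by field-of-view letter (S/M/L, fixing
#' the transverse FOV width) and a field-length number (2/10/15/20, fixing
#' the longitudinal extent at isocenter).
#'
#' @param code Collimator code, e.g. `"M15"`; vectorised.
#' @return A tibble with columns `code`, `fov_width_mm`,
#'   `field_length_mm`.
#' @export
#' @examples
#' collimator(c("S20", "M10"))
collimator <- function(code) {
  m <- regmatches(code, regexec("^([SML])(2|10|15|20)$", code))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    abort_cbct(
      sprintf("Invalid collimator code(s): %s. Expected S/M/L + 2/10/15/20.",
              paste(code[bad], collapse = ", ")),
      "cbctdose_error_validation"
    )
  }
  tibble::tibble(
    code = code,
    fov_width_mm = unname(.fov_width_mm[vapply(m, `[`, "", 2)]),
    field_length_mm = unname(.field_length_mm[vapply(m, `[`, "", 3)])
  )
}

#' Define a CBCT acquisition protocol
#'
#' @param name Protocol name.
#' @param kvp Tube potential (kV).
#' @param ma_per_frame Tube current per frame (mA), > 0.
#' @param ms_per_frame Exposure time per frame (ms), > 0.
#' @param frames Number of frames, > 0.
#' @param collimator Collimator code (e.g. `"S20"`).
#' @param start_deg,stop_deg Gantry start/stop angles (degrees).
#' @param direction Rotation direction, metadata only.
#' @param filter_id Beam filter; only the open field `"F0"` is supported
#'   (bowtie-filter protocols need their own measured data).
#' @param site Optional treatment site label used to select the phantom
#'   (see [predict_protocol_dose()]).
#' @return A one-row tibble of class `cbct_protocol`.
#' @export
cbct_protocol <- function(name, kvp, ma_per_frame, ms_per_frame, frames,
                          collimator, start_deg = 0, stop_deg = 0,
                          direction = "CW", filter_id = "F0",
                          site = NA_character_) {
  for (nm in c("ma_per_frame", "ms_per_frame", "frames")) {
    stop_if_not_number(get(nm), nm, positive = TRUE)
  }
  if (!identical(filter_id, "F0")) {
    abort_cbct(
      "Only the open F0 filter is supported; filtered protocols require new point dose and profile measurements.",
      "cbctdose_error_validation"
    )
  }
  collimator(collimator)  # validates the code
  out <- tibble::tibble(
    name = name, site = site, kvp = kvp, ma_per_frame = ma_per_frame,
    ms_per_frame = ms_per_frame, frames = frames, collimator = collimator,
    start_deg = start_deg, stop_deg = stop_deg, direction = direction,
    filter_id = filter_id
  )
  class(out) <- c("cbct_protocol", class(out))
  out
}

#' Total tube current-time product of a protocol
#'
#' `mA/frame * ms/frame * frames / 1000`.
#'
#' @param protocol A [cbct_protocol()] (any number of rows).
#' @return Total mAs, one value per protocol row.
#' @export
#' @examples
#' total_mas(cbct_protocol("HN", 100, 10, 10, 361, "S20"))  # 36.1
total_mas <- function(protocol) {
  stopifnot(is.data.frame(protocol))
  protocol$ma_per_frame * protocol$ms_per_frame * protocol$frames / 1000
}

# full if arc within 10 deg of a full turn, half if within 30 deg of 200
rotation_class <- function(start_deg, stop_deg) {
  arc <- (stop_deg - start_deg) %% 360
  arc[arc == 0] <- 360
  dplyr::case_when(
    arc >= 350 ~ "full",
    abs(arc - 200) <= 30 ~ "half",
    .default = NA_character_
  )
}

#' Factory XVI volume-view protocols
#'
#' The three bundled factory presets (head and neck, chest, prostate) with
#' their tube settings, collimators and arcs.
#'
#' @return A [cbct_protocol()] tibble with three rows.
#' @export
xvi_factory_protocols <- function() {
  path <- system.file("extdata", "xvi_factory_protocols.json",
                      package = "cbctdose", mustWork = TRUE)
  read_protocol_json(path)
}

#' Assemble a per-100-mAs summary dose table
#'
#' Joins absolute point doses (centre plus four peripheral positions) with
#' dose line integrals into the per-100-mAs summary table used for
#' protocol dose prediction: one row per (phantom, kVp, rotation,
#' collimator) with centre dose, average peripheral dose, both DLIs and
#' the recomputed DLP_CBCT.
#'
#' @param point_doses Long tibble with columns `phantom`, `kvp`,
#'   `rotation`, `collimator`, `position` (one of center/A/L/P/R) and
#'   `dose_cgy_per_100mas`.
#' @param dlis Tibble with columns `phantom`, `kvp`, `collimator`,
#'   `dli_center`, `dli_periphery` (per 100 mAs). DLIs are keyed without
#'   rotation: one profile integral is measured per collimator and shared
#'   between rotation classes, since per-100-mAs doses are
#'   rotation-normalised.
#' @return A tibble of class `dose_table`.
#' @export
build_summary_table <- function(point_doses, dlis) {
  need_pd <- c("phantom", "kvp", "rotation", "collimator", "position",
               "dose_cgy_per_100mas")
  if (!all(need_pd %in% names(point_doses))) {
    abort_cbct(paste("point_doses needs columns",
                     paste(need_pd, collapse = ", ")),
               "cbctdose_error_validation")
  }
  need_dli <- c("phantom", "kvp", "collimator", "dli_center", "dli_periphery")
  if (!all(need_dli %in% names(dlis))) {
    abort_cbct(paste("dlis needs columns", paste(need_dli, collapse = ", ")),
               "cbctdose_error_validation")
  }
  if (nrow(point_doses) == 0) {
    out <- tibble::tibble(
      phantom = character(), kvp = numeric(), rotation = character(),
      collimator = character(), center_dose = numeric(),
      avg_periphery_dose = numeric(), dli_center = numeric(),
      dli_periphery = numeric(), dlp = numeric()
    )
    class(out) <- c("dose_table", class(out))
    return(out)
  }
  dup <- point_doses |>
    dplyr::count(.data$phantom, .data$kvp, .data$rotation, .data$collimator,
                 .data$position) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_cbct(
      sprintf("Duplicate point-dose entries for key(s): %s.",
              paste(paste(dup$phantom, dup$kvp, dup$rotation, dup$collimator,
                          dup$position), collapse = "; ")),
      "cbctdose_error_key"
    )
  }
  if (anyDuplicated(dlis[c("phantom", "kvp", "collimator")]) > 0) {
    abort_cbct("Duplicate DLI entries for a (phantom, kvp, collimator) key.",
               "cbctdose_error_key")
  }
  points <- point_doses |>
    tidyr::pivot_wider(
      id_cols = c("phantom", "kvp", "rotation", "collimator"),
      names_from = "position", values_from = "dose_cgy_per_100mas"
    )
  if (!all(c("center", "A", "L", "P", "R") %in% names(points)) ||
      anyNA(points[c("center", "A", "L", "P", "R")])) {
    abort_cbct(
      "Every key needs a center dose and all four peripheral doses (A, L, P, R).",
      "cbctdose_error_key"
    )
  }
  out <- points |>
    dplyr::rowwise() |>
    dplyr::mutate(
      center_dose = .data$center,
      avg_periphery_dose = average_periphery(c(.data$A, .data$L, .data$P,
                                               .data$R))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("phantom", "kvp", "rotation", "collimator", "center_dose",
                  "avg_periphery_dose") |>
    dplyr::inner_join(
      dlis[c("phantom", "kvp", "collimator", "dli_center", "dli_periphery")],
      by = c("phantom", "kvp", "collimator")
    ) |>
    dplyr::mutate(dlp = dlp_cbct(.data$dli_center, .data$dli_periphery))
  if (nrow(out) < nrow(points)) {
    missing <- dplyr::anti_join(points, dlis,
                                by = c("phantom", "kvp", "collimator"))
    abort_cbct(
      sprintf("No DLI entry for key(s): %s.",
              paste(paste(missing$phantom, missing$kvp, missing$collimator),
                    collapse = "; ")),
      "cbctdose_error_key"
    )
  }
  class(out) <- c("dose_table", class(out))
  out
}

#' Bundled per-100-mAs dose table for an Elekta XVI system
#'
#' The package's reference summary table, assembled with
#' [build_summary_table()] from the bundled published point-dose and DLI
#' measurements (see `inst/extdata/PROVENANCE.md`). Replace with your own
#' measurements for clinical use.
#'
#' @return A `dose_table` tibble.
#' @export
xvi_dose_table <- function() {
  ref <- xvi_reference_data()
  build_summary_table(ref$point_doses, ref$dli)
}

#' Bundled published reference measurements
#'
#' @return A list with elements `point_doses` (long point-dose tibble) and
#'   `dli` (per-collimator DLIs including the published DLP column
#'   `dlp_published`).
#' @export
xvi_reference_data <- function() {
  pd <- readr::read_csv(
    system.file("extdata", "xvi_point_doses.csv", package = "cbctdose",
                mustWork = TRUE),
    show_col_types = FALSE
  )
  dli <- readr::read_csv(
    system.file("extdata", "xvi_dli.csv", package = "cbctdose",
                mustWork = TRUE),
    show_col_types = FALSE
  )
  list(point_doses = pd, dli = dli)
}

# default treatment-site -> phantom mapping; extend for new sites
default_site_map <- c(head = "head", "head and neck" = "head",
                      chest = "body", pelvis = "body", prostate = "body")

#' Predict protocol dose from a per-100-mAs dose table
#'
#' Looks up the (phantom, kVp, rotation class, collimator) entry and scales
#' every per-100-mAs quantity by `total_mas / 100`. The phantom is chosen
#' from the protocol's treatment site via `site_map`, falling back to kVp
#' (100 kVp -> head, 120 kVp -> body). The DLP in the report is recomputed
#' from the scaled DLIs, so it is always the exact 1/3 : 2/3 combination.
#'
#' @param protocol A [cbct_protocol()] (one or more rows).
#' @param table A `dose_table`, e.g. [xvi_dose_table()].
#' @param site_map Named character vector mapping site labels to
#'   `"head"`/`"body"`.
#' @return A tibble of class `protocol_dose_report`: one row per protocol
#'   with `total_mas`, point doses (cGy), DLIs and `dlp_mgy_cm`.
#' @export
#' @examples
#' predict_protocol_dose(xvi_factory_protocols())
predict_protocol_dose <- function(protocol, table = xvi_dose_table(),
                                  site_map = default_site_map) {
  stopifnot(is.data.frame(protocol), is.data.frame(table))
  rows <- purrr::map(seq_len(nrow(protocol)), function(i) {
    p <- protocol[i, ]
    if (!p$kvp %in% table$kvp) {
      abort_cbct(
        sprintf(
          "No dose table data at %g kVp; a different kVp or filter requires new point dose and profile measurements.",
          p$kvp
        ),
        "cbctdose_error_key"
      )
    }
    site <- if ("site" %in% names(p)) tolower(p$site) else NA_character_
    phantom <- if (!is.na(site) && site %in% names(site_map)) {
      unname(site_map[site])
    } else if (p$kvp == 100) "head" else "body"
    rot <- rotation_class(p$start_deg, p$stop_deg)
    if (is.na(rot)) {
      abort_cbct(
        "Unsupported rotation arc: only full (360 deg) and half (~200 deg) scans have table entries; peripheral dose is not interpolable between arcs.",
        "cbctdose_error_key"
      )
    }
    entry <- table |>
      dplyr::filter(.data$phantom == !!phantom, .data$kvp == p$kvp,
                    .data$rotation == rot, .data$collimator == p$collimator)
    if (nrow(entry) != 1) {
      abort_cbct(
        sprintf("No dose table entry for (phantom=%s, kvp=%g, rotation=%s, collimator=%s).",
                phantom, p$kvp, rot, p$collimator),
        "cbctdose_error_key"
      )
    }
    mas <- total_mas(p)
    if (mas <= 0) {
      abort_cbct("Protocol delivers zero mAs.", "cbctdose_error_validation")
    }
    k <- mas / 100
    tibble::tibble(
      protocol = p$name, phantom = phantom, kvp = p$kvp,
      collimator = p$collimator, rotation = rot, total_mas = mas,
      point_dose_center_cgy = entry$center_dose * k,
      point_dose_avg_periphery_cgy = entry$avg_periphery_dose * k,
      dli_center_mgy_cm = entry$dli_center * k,
      dli_periphery_mgy_cm = entry$dli_periphery * k,
      dlp_mgy_cm = dlp_cbct(entry$dli_center, entry$dli_periphery) * k
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("protocol_dose_report", class(out))
  out
}

#' Accumulate imaging dose over a treatment course
#'
#' Scales a per-fraction protocol dose report by the number of fractions
#' and converts point doses cGy -> Gy.
#'
#' @param report A `protocol_dose_report` from [predict_protocol_dose()].
#' @param fractions Number of imaging fractions (integer >= 1).
#' @return A tibble with course totals: `course_center_gy`,
#'   `course_periphery_gy`, `course_dlp_mgy_cm`.
#' @export
cumulative_course_dose <- function(report, fractions) {
  stopifnot(is.data.frame(report))
  if (length(fractions) != 1 || fractions < 1 ||
      fractions != as.integer(fractions)) {
    abort_cbct("`fractions` must be a single integer >= 1.",
               "cbctdose_error_validation")
  }
  tibble::as_tibble(report) |>
    dplyr::transmute(
      protocol = .data$protocol,
      fractions = as.integer(fractions),
      course_center_gy = .data$point_dose_center_cgy * fractions / 100,
      course_periphery_gy = .data$point_dose_avg_periphery_cgy * fractions / 100,
      course_dlp_mgy_cm = .data$dlp_mgy_cm * fractions
    )
}

#' @export
print.protocol_dose_report <- function(x, ...) {
  cat("CBCT protocol dose report (point doses cGy, DLP mGy.cm):\n")
  y <- dplyr::mutate(
    tibble::as_tibble(x),
    dplyr::across(dplyr::starts_with("point_dose"), ~ round(.x, 2)),
    dplyr::across(dplyr::starts_with("dl"), ~ round(.x, 1))
  )
  print(y, ...)
  invisible(x)
}
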