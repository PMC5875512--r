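# File formats: CSV for tabular data (comma, dot decimal, header row,
# UTF-8), sidecar JSON for metadata. Units live in column names and
# metadata fields, never implicitly. Every JSON document carries a
# schema_version; readers reject unknown major versions.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a profile CSV with sidecar metadata
#'
#' The CSV holds `position_mm,reading`; acquisition metadata (state, depth,
#' kVp, collimator, shift, reference reading, schema version) goes in a
#' JSON sidecar next to the CSV (same basename, `.json` extension). The
#' round trip is lossless at full double precision.
#'
#' @param profile A [cbct_profile()].
#' @param path CSV path; the sidecar is written alongside.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns the [cbct_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "cbct_profile"))
  readr::write_csv(
    tibble::tibble(position_mm = profile$position_mm,
                   reading = profile$value),
    path
  )
  meta <- list(
    schema_version = schema_version,
    state = profile_state(profile),
    depth_mm = attr(profile, "depth_mm"),
    kvp = attr(profile, "kvp"),
    collimator = attr(profile, "collimator"),
    shift_mm = attr(profile, "shift_mm"),
    reference_reading = attr(profile, "reference_reading")
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("position_mm", "reading") %in% names(df))) {
    abort_cbct(sprintf("%s must have columns position_mm, reading.", path),
               "cbctdose_error_format")
  }
  if (any(diff(df$position_mm) <= 0)) {
    abort_cbct(sprintf("%s: position_mm must be strictly increasing.", path),
               "cbctdose_error_format")
  }
  sp <- sidecar_path(path)
  meta <- if (file.exists(sp)) jsonlite::read_json(sp) else list()
  if (length(meta)) check_schema(meta, sp)
  state <- meta$state %||% "raw"
  if (!state %in% c("raw", "calibrated", "relative", "absolute")) {
    abort_cbct(sprintf("%s: unknown profile state '%s'.", sp, state),
               "cbctdose_error_format")
  }
  cbct_profile(
    position_mm = df$position_mm, value = df$reading, state = state,
    depth_mm = meta$depth_mm %||% NA_real_,
    kvp = meta$kvp %||% NA_real_,
    collimator = meta$collimator %||% NA_character_,
    shift_mm = meta$shift_mm,
    reference_reading = meta$reference_reading
  )
}

#' Read an aluminium attenuation series
#'
#' @param path CSV with columns `thickness_mm_al`, `transmission`.
#' @return A tibble suitable for [estimate_hvl()].
#' @export
read_attenuation_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("thickness_mm_al", "transmission") %in% names(df))) {
    abort_cbct(
      sprintf("%s must have columns thickness_mm_al, transmission.", path),
      "cbctdose_error_format"
    )
  }
  df
}

#' Write / read an electrometer reading set as JSON
#'
#' @param rs A [reading_set()].
#' @param path JSON path.
#' @return The path (write) or the [reading_set()] (read).
#' @export
write_reading_set_json <- function(rs, path) {
  stopifnot(inherits(rs, "reading_set"))
  jsonlite::write_json(c(list(schema_version = schema_version),
                         unclass(rs)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reading_set_json
#' @export
read_reading_set_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(x, path)
  reading_set(
    raw_readings = x$raw_readings,
    temperature_c = x$temperature_c, pressure_kpa = x$pressure_kpa,
    ref_temperature_c = x$ref_temperature_c,
    ref_pressure_kpa = x$ref_pressure_kpa,
    m_plus = x$m_plus, m_minus = x$m_minus,
    m_high = x$m_high, m_low = x$m_low,
    v_high = x$v_high, v_low = x$v_low,
    extra_correction = x$extra_correction %||% 1,
    used_polarity = x$used_polarity %||% "plus"
  )
}

#' Read a chamber calibration from JSON
#'
#' Expected fields: `chamber_id`, `nk_table` (records with `hvl_mm_al`,
#' `nk`), `pq_cham`, `mu_en_ratio`, `electrometer_factor`.
#'
#' @param path JSON path.
#' @return A [chamber_calibration()].
#' @export
read_chamber_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(x, path)
  chamber_calibration(
    chamber_id = x$chamber_id,
    nk_table = tibble::as_tibble(x$nk_table),
    pq_cham = x$pq_cham %||% 1,
    mu_en_ratio = x$mu_en_ratio %||% 1.05,
    electrometer_factor = x$electrometer_factor %||% 1
  )
}

#' Read CBCT protocols from JSON
#'
#' Accepts a single protocol object or a document with a `protocols`
#' array.
#'
#' @param path JSON path.
#' @return A [cbct_protocol()] tibble.
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_schema(x, path)
  entries <- x$protocols %||% list(x)
  dplyr::bind_rows(purrr::map(entries, function(p) {
    cbct_protocol(
      name = p$name, kvp = p$kvp, ma_per_frame = p$ma_per_frame,
      ms_per_frame = p$ms_per_frame, frames = p$frames,
      collimator = p$collimator,
      start_deg = p$start_deg %||% 0, stop_deg = p$stop_deg %||% 0,
      direction = p$direction %||% "CW", filter_id = p$filter_id %||% "F0",
      site = p$site %||% NA_character_
    )
  })) -> out
  class(out) <- c("cbct_protocol", class(out))
  out
}

#' Write / read a per-100-mAs dose table as CSV
#'
#' @param table A `dose_table` (see [build_summary_table()]).
#' @param path CSV path.
#' @return The path (write) or the `dose_table` (read).
#' @export
write_dose_table_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_dose_table_csv
#' @export
read_dose_table_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("phantom", "kvp", "rotation", "collimator", "center_dose",
            "avg_periphery_dose", "dli_center", "dli_periphery", "dlp")
  if (!all(need %in% names(df))) {
    abort_cbct(sprintf("%s is not a dose table (missing columns).", path),
               "cbctdose_error_format")
  }
  class(df) <- c("dose_table", class(df))
  df
}

#' Run the full dosimetry pipeline from a configuration
#'
#' Executes the measurement-to-report chain described by a run
#' configuration (an R list or a JSON file): optionally simulate and
#' process a diode-array campaign (calibrate, apply, output-correct,
#' stitch, CAX-normalise, integrate), then predict protocol doses from a
#' per-100-mAs dose table, and write the reports plus a manifest recording
#' the seed, configuration and MD5 hash of every emitted file. Reruns with
#' the same configuration are byte-identical.
#'
#' Configuration fields: `out_dir` (required), `seed` (default 1),
#' `protocols` (`"factory"` or a protocol JSON path), `dose_table`
#' (`"bundled"` or a dose-table CSV path), `fractions` (optional course
#' length), `simulate` (optional list with beam parameters `amplitude`,
#' `field_length_mm`, ... plus `point_dose_center_cgy` and
#' `point_dose_avg_periphery_cgy`).
#'
#' @param config A list, or path to a config JSON.
#' @return Invisibly, a list with the report tibble, any simulated DLI
#'   result, and the manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    check_schema(config, "run config")
  }
  if (!is.list(config) || is.null(config$out_dir)) {
    abort_cbct("Config must be a list with at least `out_dir`.",
               "cbctdose_error_validation")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  emitted <- character()

  dli_res <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    beam <- ground_truth_beam(
      field_length_mm = sim$field_length_mm %||% 178.7,
      penumbra_sigma_mm = sim$penumbra_sigma_mm %||% 6,
      tail_fraction = sim$tail_fraction %||% 0.12,
      tail_decay_mm = sim$tail_decay_mm %||% 40,
      amplitude = sim$amplitude %||% 3.1
    )
    noise <- noise_model(
      detector_sensitivity_sd = sim$detector_sensitivity_sd %||% 0.03,
      reading_noise_sd = sim$reading_noise_sd %||% 0.005,
      tube_drift_sd = sim$tube_drift_sd %||% 0.01,
      seed = seed
    )
    spec <- array_spec()
    sweep <- simulate_calibration_sweep(beam, spec, noise)
    factors <- calibrate_array(sweep)
    shifts <- sim$shifts_mm %||% c(0, -100, 100)
    scans <- purrr::imap(shifts, function(sh, i) {
      apply_calibration(
        simulate_diode_scan(beam, spec, noise, array_shift_mm = sh,
                            scan_index = i),
        factors
      )
    })
    merged <- stitch_scans(reference_normalize(scans))
    rel <- normalize_to_cax(merged)
    prof_path <- file.path(config$out_dir, "processed_profile.csv")
    write_profile_csv(rel, prof_path)
    emitted <- c(emitted, prof_path, sidecar_path(prof_path))
    # one measured profile shape serves both radial positions; the
    # peripheral DLI is the central shape rescaled by the peripheral dose
    pd_c <- sim$point_dose_center_cgy %||% 0.31
    pd_p <- sim$point_dose_avg_periphery_cgy %||% pd_c
    dli <- integrate_dli(to_absolute(rel, pd_c))
    dli_res <- dli_result(
      dli_center = as.numeric(dli),
      dli_periphery = as.numeric(dli) * pd_p / pd_c,
      truncation_extent_mm = attr(dli, "truncation_extent_mm")
    )
    dli_path <- file.path(config$out_dir, "dli_result.json")
    jsonlite::write_json(
      c(list(schema_version = schema_version, seed = seed),
        as.list(tibble::as_tibble(dli_res))),
      dli_path, auto_unbox = TRUE, digits = NA
    )
    emitted <- c(emitted, dli_path)
  }

  table <- if (is.null(config$dose_table) ||
               identical(config$dose_table, "bundled")) {
    xvi_dose_table()
  } else {
    read_dose_table_csv(config$dose_table)
  }
  protocols <- if (is.null(config$protocols) ||
                   identical(config$protocols, "factory")) {
    xvi_factory_protocols()
  } else {
    read_protocol_json(config$protocols)
  }
  report <- predict_protocol_dose(protocols, table)
  report_path <- file.path(config$out_dir, "protocol_report.json")
  jsonlite::write_json(
    list(schema_version = schema_version, seed = seed,
         report = tibble::as_tibble(report)),
    report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  emitted <- c(emitted, report_path)

  if (!is.null(config$fractions)) {
    course <- cumulative_course_dose(report, config$fractions)
    course_path <- file.path(config$out_dir, "course_report.json")
    jsonlite::write_json(
      list(schema_version = schema_version, seed = seed,
           course = tibble::as_tibble(course)),
      course_path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    emitted <- c(emitted, course_path)
  }

  hashes <- tools::md5sum(sort(emitted))
  manifest <- list(
    schema_version = schema_version,
    package_version = as.character(utils::packageVersion("cbctdose")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    files = as.list(stats::setNames(unname(hashes), basename(names(hashes))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(report = report, dli = dli_res,
                 manifest_path = manifest_path))
}
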