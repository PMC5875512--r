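# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_cbct <- function(msg, class) {
  rlang::abort(msg, class = c(class, "cbctdose_error"))
}

stop_if_not_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_cbct(sprintf("`%s` must be a single finite number.", name),
               "cbctdose_error_validation")
  }
  if (positive && x <= 0) {
    abort_cbct(sprintf("`%s` must be > 0 (got %g).", name, x),
               "cbctdose_error_validation")
  }
  invisible(x)
}

# trapezoidal area; positions and values same length
trapz_area <- function(x, y) pracma::trapz(x, y)

# Evaluate expr with a private RNG stream, restoring the caller's RNG state.
with_private_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic sub-stream seeds: one campaign seed fans out to up to 64
# independent stream seeds (sensitivities, per-scan drift, reading noise).
substream_seed <- function(seed, stream) {
  stopifnot(stream >= 1L, stream <= 64L)
  with_private_seed(as.integer(seed), sample.int(2^30, 64L))[stream]
}

schema_version <- "1.0"

check_schema <- function(meta, what) {
  ver <- meta$schema_version %||% NA_character_
  if (is.na(ver)) {
    abort_cbct(sprintf("%s is missing a schema_version field.", what),
               "cbctdose_error_schema")
  }
  major <- strsplit(as.character(ver), ".", fixed = TRUE)[[1]][1]
  if (major != strsplit(schema_version, ".", fixed = TRUE)[[1]][1]) {
    abort_cbct(sprintf("%s has unsupported schema version %s.", what, ver),
               "cbctdose_error_schema")
  }
  invisible(TRUE)
}
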