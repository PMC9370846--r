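SECONDS_PER_DAY <- 86400

#' @keywords internal
hr_log <- function(fmt, ...) {
  message(sprintf(paste0("[herdrhythm] ", fmt), ...))
}

#' @keywords internal
hr_abort <- function(class, fmt, ...) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "herdrhythm_error"))
}

#' @keywords internal
hr_warn <- function(fmt, ...) {
  rlang::warn(sprintf(fmt, ...), class = "herdrhythm_warning")
}

# Parse a timestamp column that may be ISO-8601 strings or epoch seconds.
# Returns numeric seconds since 1970-01-01 UTC.
#' @keywords internal
parse_timestamps <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) hr_abort("hr_structural_input", "unparseable timestamps in input")
  as.numeric(ts)
}

#' @keywords internal
as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  if (inherits(x, "Date")) return(as.numeric(as.POSIXct(as.character(x), tz = "UTC")))
  if (is.character(x)) return(parse_timestamps(x))
  as.numeric(x)
}

# Deterministic per-animal stream seed below 2^31, derived from a run seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(index) * 7919) %% 2147483647L)
}
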