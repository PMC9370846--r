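# Pre-processing chain: raw triaxial stream -> signal vector magnitude ->
# zero-phase Butterworth band-pass -> rectification -> fixed-epoch means.

#' Construct a triaxial accelerometer stream
#'
#' Container for one animal's raw collar-accelerometer recording: a strictly
#' increasing timestamp vector (seconds since 1970-01-01 UTC) and the three
#' acceleration axes in g. Sampling is nominally regular (default 12.5 Hz) but
#' gaps and jitter are tolerated downstream; epoch binning is timestamp-driven.
#'
#' @param time Numeric timestamps in seconds (or POSIXct), strictly increasing.
#' @param x,y,z Acceleration per axis in g; sensor range is +/- 8 g.
#' @param animal_id Identifier string.
#' @param nominal_rate Nominal sampling rate in Hz (default 12.5).
#' @return A `triaxial_stream`: a tibble with columns `time`, `x`, `y`, `z`
#'   and attributes `animal_id`, `nominal_rate`.
#' @export
triaxial_stream <- function(time, x, y, z, animal_id = "animal", nominal_rate = 12.5) {
  time <- as_utc_time(time)
  n <- length(time)
  if (length(x) != n || length(y) != n || length(z) != n)
    hr_abort("hr_structural_input",
             "axis lengths differ: time %d, x %d, y %d, z %d",
             n, length(x), length(y), length(z))
  if (n > 1 && any(diff(time) <= 0))
    hr_abort("hr_structural_input", "timestamps must be strictly increasing")
  rng <- suppressWarnings(max(abs(c(x, y, z)), na.rm = TRUE))
  if (is.finite(rng) && rng > 8 + 1e-9)
    hr_abort("hr_structural_input", "acceleration outside sensor range (+/- 8 g): %.3f", rng)
  out <- tibble::tibble(time = time, x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  structure(out, class = c("triaxial_stream", class(out)),
            animal_id = animal_id, nominal_rate = nominal_rate)
}

#' Band-pass filter specification
#'
#' Fourth-order Butterworth band-pass with a 0.5--20 Hz design band. When the
#' upper edge exceeds the Nyquist frequency of the data (it does at the 12.5 Hz
#' collar sampling rate, Nyquist 6.25 Hz), the applied edge is clamped to
#' 0.99 x Nyquist and the effective band is logged; see
#' `vignette("herd-circadian-analysis")`.
#'
#' @param order Filter design order passed to the Butterworth designer
#'   (default 4; a band-pass of design order n has 2n poles).
#' @param low_hz,high_hz Band edges in Hz (defaults 0.5 and 20).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4, low_hz = 0.5, high_hz = 20) {
  stopifnot(order >= 1, low_hz > 0, low_hz < high_hz)
  structure(list(order = as.integer(order), low_hz = low_hz, high_hz = high_hz,
                 family = "butterworth-bandpass"),
            class = "filter_spec")
}

#' Signal vector magnitude of a triaxial stream
#'
#' Euclidean norm sqrt(x^2 + y^2 + z^2) per sample: an orientation-invariant
#' overall-movement measure, unaffected by the collar rotating on the neck.
#'
#' @param stream A [triaxial_stream()].
#' @return A tibble with columns `time`, `value` carrying the stream's
#'   `animal_id` and `nominal_rate` attributes.
#' @export
svm_magnitude <- function(stream) {
  stopifnot(inherits(stream, "triaxial_stream"))
  out <- tibble::tibble(time = stream$time,
                        value = sqrt(stream$x^2 + stream$y^2 + stream$z^2))
  structure(out, animal_id = attr(stream, "animal_id"),
            nominal_rate = attr(stream, "nominal_rate"))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the filter forward and backward (`signal::filtfilt`) so activity
#' bouts are not shifted in time. The upper band edge is clamped to
#' 0.99 x Nyquist when it exceeds it; the effective band is logged.
#'
#' @param values Numeric series (e.g. per-sample magnitude).
#' @param rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered numeric series, same length.
#' @export
bandpass <- function(values, rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), rate > 0)
  nyq <- rate / 2
  if (spec$low_hz >= nyq)
    hr_abort("hr_unusable_band",
             "low edge %.3g Hz is at or above Nyquist (%.3g Hz): band unusable",
             spec$low_hz, nyq)
  if (length(values) <= 3 * spec$order)
    hr_abort("hr_insufficient_data",
             "series of length %d too short for an order-%d filter",
             length(values), spec$order)
  high_eff <- min(spec$high_hz, 0.99 * nyq)
  if (high_eff < spec$high_hz)
    hr_warn("upper band edge %.3g Hz exceeds Nyquist %.3g Hz; clamped to %.4g Hz",
            spec$high_hz, nyq, high_eff)
  hr_log("band-pass applied: effective band %.4g-%.4g Hz (order %d, zero-phase)",
         spec$low_hz, high_eff, spec$order)
  bf <- signal::butter(spec$order, c(spec$low_hz, high_eff) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, values))
}

#' Frequency response gain of a band-pass specification
#'
#' Magnitude gain of the zero-phase (forward-backward) filter at given
#' frequencies; used as an independent check on filter behaviour.
#'
#' @param freqs_hz Frequencies in Hz.
#' @param rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Numeric gains (|H|^2 of the single-pass design, i.e. the zero-phase
#'   amplitude gain).
#' @export
bandpass_gain <- function(freqs_hz, rate, spec = filter_spec()) {
  nyq <- rate / 2
  high_eff <- min(spec$high_hz, 0.99 * nyq)
  bf <- signal::butter(spec$order, c(spec$low_hz, high_eff) / nyq, type = "pass")
  w <- 2 * pi * freqs_hz / rate
  h <- vapply(w, function(wi) {
    e <- exp(-1i * wi * (seq_along(bf$b) - 1))
    abs(sum(bf$b * e) / sum(bf$a * e))
  }, numeric(1))
  h^2
}

#' Full-wave rectification
#'
#' @param values Numeric series.
#' @return Elementwise absolute values.
#' @export
rectify <- function(values) abs(values)

#' Aggregate a timestamped series into fixed epochs
#'
#' Bins samples into half-open epochs `[start, start + epoch_len)` on a regular
#' grid from the first to the last sample and takes the mean per epoch. Epochs
#' holding fewer than half the expected `epoch_len * rate` samples are flagged
#' missing (gaps appear as flagged rows, never as absent rows).
#'
#' @param series A data frame with `time` (seconds) and `value` columns, e.g.
#'   from [svm_magnitude()].
#' @param epoch_len Epoch length in seconds (default 60).
#' @param rate Expected sampling rate in Hz; taken from the series'
#'   `nominal_rate` attribute when `NULL`.
#' @return An `epoch_series`: tibble `epoch_start`, `value`, `missing` with
#'   attributes `animal_id`, `epoch_len`.
#' @export
epoch_aggregate <- function(series, epoch_len = 60, rate = NULL) {
  stopifnot(epoch_len > 0)
  if (is.null(rate)) rate <- attr(series, "nominal_rate")
  if (is.null(rate)) hr_abort("hr_structural_input", "sampling rate unknown: pass `rate`")
  t <- series$time
  v <- series$value
  if (length(t) == 0) hr_abort("hr_empty_series", "cannot aggregate an empty series")
  if (is.unsorted(t, strictly = FALSE))
    hr_abort("hr_structural_input", "timestamps must be increasing")
  if (length(t) > 1) {
    med_gap <- stats::median(diff(t))
    if (abs(med_gap - 1 / rate) > 0.05 / rate)
      hr_warn("median inter-sample gap %.4g s deviates > 5%% from nominal %.4g s",
              med_gap, 1 / rate)
  }
  t0 <- t[1]
  idx <- floor((t - t0) / epoch_len)        # half-open bins
  n_epochs <- idx[length(idx)] + 1
  counts <- tabulate(idx + 1L, nbins = n_epochs)
  sums <- numeric(n_epochs)
  agg <- tapply(v, idx, sum)
  sums[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  value <- ifelse(counts > 0, sums / counts, NA_real_)
  missing <- counts < 0.5 * epoch_len * rate
  value[missing] <- NA_real_
  out <- tibble::tibble(epoch_start = t0 + epoch_len * (seq_len(n_epochs) - 1),
                        value = value, missing = missing)
  structure(out, class = c("epoch_series", class(out)),
            animal_id = attr(series, "animal_id") %||% "animal",
            epoch_len = epoch_len)
}

#' Run the full pre-processing chain on a raw stream
#'
#' Magnitude, zero-phase band-pass, rectification, epoch means, in that order.
#'
#' @param stream A [triaxial_stream()].
#' @param spec A [filter_spec()].
#' @param epoch_len Epoch length in seconds (default 60).
#' @return An `epoch_series` (see [epoch_aggregate()]).
#' @export
preprocess_stream <- function(stream, spec = filter_spec(), epoch_len = 60) {
  if (nrow(stream) == 0) hr_abort("hr_empty_series", "empty stream")
  mag <- svm_magnitude(stream)
  rate <- attr(stream, "nominal_rate")
  filt <- bandpass(mag$value, rate, spec)
  mag$value <- rectify(filt)
  es <- epoch_aggregate(mag, epoch_len = epoch_len, rate = rate)
  hr_log("preprocessed %s: %d samples -> %d epochs (%d missing)",
         attr(stream, "animal_id"), nrow(stream), nrow(es), sum(es$missing))
  es
}

#' Read a raw triaxial CSV export
#'
#' Expects header `timestamp,x,y,z`; timestamps ISO-8601 or epoch seconds
#' (auto-detected). The animal id defaults to the file name stem.
#'
#' @param path CSV path.
#' @param animal_id Identifier; default derived from the file name.
#' @param nominal_rate Nominal rate in Hz.
#' @return A [triaxial_stream()].
#' @export
read_triaxial_csv <- function(path, animal_id = NULL, nominal_rate = 12.5) {
  if (is.null(animal_id)) animal_id <- tools::file_path_sans_ext(basename(path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(timestamp = readr::col_character(),
                                                .default = readr::col_double()))
  need <- c("timestamp", "x", "y", "z")
  if (!all(need %in% names(df)))
    hr_abort("hr_structural_input", "%s: expected header timestamp,x,y,z", path)
  triaxial_stream(parse_timestamps(df$timestamp), df$x, df$y, df$z,
                  animal_id = animal_id, nominal_rate = nominal_rate)
}

#' Write an epoch series to CSV
#'
#' Header `epoch_start,value,missing`; missing values written as empty fields.
#'
#' @param epochs An `epoch_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(epochs, path) {
  readr::write_csv(tibble::tibble(epoch_start = epochs$epoch_start,
                                  value = epochs$value,
                                  missing = epochs$missing),
                   path, na = "")
  invisible(path)
}

#' Read an epoch series written by [write_epoch_csv()]
#'
#' @param path CSV path.
#' @param animal_id Identifier (default: file name stem).
#' @return An `epoch_series`.
#' @export
read_epoch_csv <- function(path, animal_id = NULL) {
  if (is.null(animal_id)) animal_id <- tools::file_path_sans_ext(basename(path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(epoch_start = readr::col_double(),
                                                value = readr::col_double(),
                                                missing = readr::col_logical()))
  df$missing <- ifelse(is.na(df$missing), is.na(df$value), df$missing)
  len <- if (nrow(df) > 1) stats::median(diff(df$epoch_start)) else 60
  structure(tibble::as_tibble(df), class = c("epoch_series", class(tibble::tibble())),
            animal_id = animal_id, epoch_len = len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
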