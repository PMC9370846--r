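# 24 h periodicity intensity: variance explained by the best-fit single
# sinusoid at the target period (intercept + sine + cosine), equivalent to the
# standard-normalised Lomb-Scargle periodogram at that one frequency. Bounded
# in [0, 1]; 1 = perfectly regular diurnal rhythm, 0 = aperiodic. Missing
# epochs (collar-off gaps) are simply left out of the fit.

#' Sliding-window specification for periodicity traces
#'
#' Defaults follow the study design: a 7-day window slid in 15-minute steps,
#' scoring the 24 h component. Seven full cycles per window keep the diurnal
#' component well separated from slower trends.
#'
#' @param window_len Window length in seconds (default 7 days).
#' @param step Slide step in seconds (default 15 min).
#' @param target_period Target period in seconds (default 24 h).
#' @param min_coverage Minimum fraction of non-missing epochs for a window to
#'   yield a value (default 0.5); windows below it keep their anchor but carry
#'   a missing intensity.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_len = 7 * 86400, step = 900,
                        target_period = 86400, min_coverage = 0.5) {
  stopifnot(step > 0, step <= window_len, target_period < window_len,
            min_coverage > 0, min_coverage <= 1)
  structure(list(window_len = window_len, step = step,
                 target_period = target_period, min_coverage = min_coverage),
            class = "window_spec")
}

# Core fit: R^2 of y ~ 1 + sin(wt) + cos(wt) from raw moment sums.
# Degenerate windows (zero variance, collinear basis) score 0.
#' @keywords internal
.r2_from_moments <- function(n, Sy, Syy, Ss, Sc, Sss, Scc, Ssc, Sys, Syc) {
  Cyy <- Syy - Sy^2 / n
  Css <- Sss - Ss^2 / n
  Ccc <- Scc - Sc^2 / n
  Csc <- Ssc - Ss * Sc / n
  Csy <- Sys - Ss * Sy / n
  Ccy <- Syc - Sc * Sy / n
  det <- Css * Ccc - Csc^2
  # degenerate if the centered variance or the basis Gram determinant is zero
  # up to cancellation error (thresholds relative to the uncentered moments)
  bad <- !is.finite(Cyy) | Cyy <= 1e-12 * pmax(Syy, Sy^2 / n) |
    !is.finite(det) | det <= 1e-12 * pmax(Css * Ccc, Csc^2)
  b1 <- (Csy * Ccc - Ccy * Csc) / det
  b2 <- (Ccy * Css - Csy * Csc) / det
  r2 <- (b1 * Csy + b2 * Ccy) / Cyy
  r2[bad] <- 0
  pmin(pmax(r2, 0), 1)
}

#' Periodicity intensity of one window at a target period
#'
#' Fits `value ~ intercept + sin + cos` at frequency `1/target_period` to the
#' non-missing epochs by least squares and returns the coefficient of
#' determination: the fraction of within-window variance explained by the
#' periodic component. Invariant under affine transforms of the values; a
#' zero-variance window scores 0 by convention.
#'
#' @param epochs An `epoch_series` (one window's worth), or a data frame with
#'   `epoch_start`, `value`, `missing` columns.
#' @param target_period Period in seconds (default 24 h).
#' @param min_coverage Minimum non-missing fraction; below it a classed
#'   condition `hr_undefined_window` is signalled.
#' @return Intensity in `[0, 1]`.
#' @export
intensity_at_period <- function(epochs, target_period = 86400, min_coverage = 0) {
  ok <- !epochs$missing & !is.na(epochs$value)
  if (min_coverage > 0 && mean(ok) < min_coverage)
    hr_abort("hr_undefined_window",
             "window coverage %.2f below minimum %.2f", mean(ok), min_coverage)
  t <- epochs$epoch_start[ok]
  y <- epochs$value[ok]
  n <- length(y)
  if (n < 3) return(0)
  w <- 2 * pi / target_period
  tt <- t - t[1]            # shift the origin: better-conditioned trig sums
  s <- sin(w * tt); cc <- cos(w * tt)
  .r2_from_moments(n, sum(y), sum(y^2), sum(s), sum(cc),
                   sum(s^2), sum(cc^2), sum(s * cc), sum(y * s), sum(y * cc))
}

#' Slide a periodicity window through an epoch series
#'
#' Windows start at `epoch_start[1] + k * step` for
#' `k = 0 ... floor((span - window_len)/step)` where `span` is the epoch grid
#' extent; each scores [intensity_at_period()] over its epochs. Windows whose
#' non-missing coverage falls below `spec$min_coverage` keep their anchor with
#' a missing intensity, so all animals stay on comparable anchor grids.
#'
#' Windowed moment sums are taken from cumulative sums, so the whole trace
#' costs O(n) regardless of the number of anchors.
#'
#' @param epochs An `epoch_series` on a regular grid.
#' @param spec A [window_spec()]; the epoch spacing must divide `spec$step`.
#' @return A `periodicity_trace`: tibble `anchor`, `intensity`, `coverage`
#'   with attributes `animal_id`, `step`, `window_len`, `target_period`.
#' @export
sliding_trace <- function(epochs, spec = window_spec()) {
  d <- attr(epochs, "epoch_len") %||%
    (if (nrow(epochs) > 1) epochs$epoch_start[2] - epochs$epoch_start[1] else 60)
  if (abs(spec$step / d - round(spec$step / d)) > 1e-9)
    hr_abort("hr_structural_input",
             "epoch spacing %.4g s does not divide the step %.4g s", d, spec$step)
  n <- nrow(epochs)
  span <- n * d
  k_max <- floor((span - spec$window_len) / spec$step)
  mk_trace <- function(df) {
    structure(df, class = c("periodicity_trace", class(tibble::tibble())),
              animal_id = attr(epochs, "animal_id") %||% "animal",
              step = spec$step, window_len = spec$window_len,
              target_period = spec$target_period)
  }
  if (k_max < 0) {
    hr_warn("series span %.3g d shorter than the window (%.3g d): empty trace",
            span / 86400, spec$window_len / 86400)
    return(mk_trace(tibble::tibble(anchor = numeric(0), intensity = numeric(0),
                                   coverage = numeric(0))))
  }
  ok <- !epochs$missing & !is.na(epochs$value)
  y <- ifelse(ok, epochs$value, 0)
  w <- 2 * pi / spec$target_period
  tt <- epochs$epoch_start - epochs$epoch_start[1]
  s <- ifelse(ok, sin(w * tt), 0)
  cc <- ifelse(ok, cos(w * tt), 0)
  csum <- function(v) c(0, cumsum(v))
  Cn <- csum(as.numeric(ok)); Cy <- csum(y); Cyy <- csum(y^2)
  Cs <- csum(s); Cc <- csum(cc); Css <- csum(s^2); Ccc <- csum(cc^2)
  Csc <- csum(s * cc); Cys <- csum(y * s); Cyc <- csum(y * cc)
  per <- as.integer(round(spec$step / d))
  win <- as.integer(round(spec$window_len / d))
  k <- 0:k_max
  i0 <- k * per          # windows cover epochs (i0+1) .. (i0+win)
  i1 <- i0 + win
  rng <- function(C) C[i1 + 1L] - C[i0 + 1L]
  nw <- rng(Cn)
  coverage <- nw / win
  intensity <- rep(NA_real_, length(k))
  usable <- coverage >= spec$min_coverage & nw >= 3
  if (any(usable)) {
    intensity[usable] <- .r2_from_moments(
      nw[usable], rng(Cy)[usable], rng(Cyy)[usable], rng(Cs)[usable],
      rng(Cc)[usable], rng(Css)[usable], rng(Ccc)[usable], rng(Csc)[usable],
      rng(Cys)[usable], rng(Cyc)[usable])
  }
  mk_trace(tibble::tibble(anchor = epochs$epoch_start[1] + k * spec$step,
                          intensity = intensity, coverage = coverage))
}

#' Summarise a periodicity trace
#'
#' @param trace A `periodicity_trace`.
#' @return A list: `mean`, `min`, `max`, and the anchors achieving them
#'   (`argmin`, `argmax`, absolute time) plus `argmin_min`/`argmax_min` in
#'   minutes from the trace start, over non-missing anchors.
#' @export
trace_summary <- function(trace) {
  ok <- !is.na(trace$intensity)
  if (!any(ok)) hr_abort("hr_empty_summary", "trace has no non-missing intensities")
  v <- trace$intensity[ok]; a <- trace$anchor[ok]
  i_min <- which.min(v); i_max <- which.max(v)
  t0 <- trace$anchor[1]
  list(mean = mean(v), min = v[i_min], max = v[i_max],
       argmin = a[i_min], argmax = a[i_max],
       argmin_min = (a[i_min] - t0) / 60, argmax_min = (a[i_max] - t0) / 60,
       n = sum(ok))
}

#' Write a periodicity trace to CSV
#'
#' Header `anchor,intensity,coverage`; missing intensities written as empty
#' fields.
#'
#' @param trace A `periodicity_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tibble::tibble(anchor = trace$anchor,
                                  intensity = trace$intensity,
                                  coverage = trace$coverage),
                   path, na = "")
  invisible(path)
}

#' Read a periodicity trace written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @param animal_id Identifier (default: file name stem).
#' @return A `periodicity_trace`.
#' @export
read_trace_csv <- function(path, animal_id = NULL) {
  if (is.null(animal_id)) animal_id <- tools::file_path_sans_ext(basename(path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  step <- if (nrow(df) > 1) df$anchor[2] - df$anchor[1] else 900
  structure(tibble::as_tibble(df),
            class = c("periodicity_trace", class(tibble::tibble())),
            animal_id = animal_id, step = step,
            window_len = NA_real_, target_period = 86400)
}
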