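# Herd-level synchrony analysis: align per-animal periodicity traces on a
# common anchor grid, exclude animals with excessive missing data, build the
# stacked aggregate, validate it against sub-groups, and flag individual
# animals deviating from herd-synchronous change.

#' Align periodicity traces into a herd panel
#'
#' Builds the union anchor grid across animals (all traces must share the same
#' step); each animal carries missing values outside its own logging span, so
#' staggered births and battery-end truncation are represented explicitly.
#'
#' @param traces A list of `periodicity_trace` objects.
#' @return A `herd_panel`: list with `grid` (anchor times), `intensities`
#'   (anchors x animals matrix, `NA` = missing), `animals` (tibble
#'   `animal_id`, `excluded`, `reason`, `first_anchor`, `last_anchor`) and
#'   `step`.
#' @export
align_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  steps <- vapply(traces, function(tr) attr(tr, "step") %||% NA_real_, numeric(1))
  if (length(unique(steps)) != 1 || anyNA(steps))
    hr_abort("hr_incompatible_traces", "traces have mixed steps: %s",
             paste(unique(steps), collapse = ", "))
  step <- steps[1]
  ids <- vapply(traces, function(tr) attr(tr, "animal_id") %||% "animal", character(1))
  if (anyDuplicated(ids)) hr_abort("hr_incompatible_traces", "duplicate animal ids")
  firsts <- vapply(traces, function(tr) if (nrow(tr)) tr$anchor[1] else NA_real_, numeric(1))
  lasts <- vapply(traces, function(tr) if (nrow(tr)) tr$anchor[nrow(tr)] else NA_real_, numeric(1))
  off <- (firsts - min(firsts, na.rm = TRUE)) / step
  if (any(abs(off - round(off)) > 1e-6, na.rm = TRUE))
    hr_abort("hr_incompatible_traces", "trace anchors not on a common step grid")
  g0 <- min(firsts, na.rm = TRUE); g1 <- max(lasts, na.rm = TRUE)
  grid <- seq(g0, g1, by = step)
  ord <- order(ids)
  mat <- matrix(NA_real_, nrow = length(grid), ncol = length(traces),
                dimnames = list(NULL, ids[ord]))
  for (j in seq_along(ord)) {
    tr <- traces[[ord[j]]]
    if (!nrow(tr)) next
    pos <- round((tr$anchor - g0) / step) + 1L
    mat[pos, j] <- tr$intensity
  }
  nm_first <- apply(mat, 2, function(col) {
    i <- which(!is.na(col)); if (length(i)) grid[i[1]] else NA_real_
  })
  nm_last <- apply(mat, 2, function(col) {
    i <- which(!is.na(col)); if (length(i)) grid[i[length(i)]] else NA_real_
  })
  animals <- tibble::tibble(animal_id = ids[ord], excluded = FALSE,
                            reason = NA_character_,
                            first_anchor = nm_first, last_anchor = nm_last)
  structure(list(grid = grid, intensities = mat, animals = animals, step = step),
            class = "herd_panel")
}

#' @export
print.herd_panel <- function(x, ...) {
  cat(sprintf("<herd_panel> %d animals (%d excluded), %d anchors, step %g s\n",
              ncol(x$intensities), sum(x$animals$excluded), length(x$grid), x$step))
  invisible(x)
}

#' Ids of animals currently included in a panel
#' @param panel A `herd_panel`.
#' @return Character vector of included animal ids (ascending).
#' @export
included_ids <- function(panel) panel$animals$animal_id[!panel$animals$excluded]

#' Exclude animals with excessive missing data
#'
#' Flags (never deletes) animals whose missing fraction over their own logging
#' span -- first to last non-missing anchor -- exceeds `max_missing_frac`,
#' mirroring the study's removal of collar-off outliers. Animals with no data
#' at all are excluded outright.
#'
#' @param panel A `herd_panel`.
#' @param max_missing_frac Threshold fraction in (0, 1), default 0.2.
#' @return The panel with updated `excluded`/`reason` flags.
#' @export
exclude_missing <- function(panel, max_missing_frac = 0.2) {
  stopifnot(max_missing_frac > 0, max_missing_frac < 1)
  for (j in seq_len(ncol(panel$intensities))) {
    col <- panel$intensities[, j]
    i <- which(!is.na(col))
    if (!length(i)) {
      panel$animals$excluded[j] <- TRUE
      panel$animals$reason[j] <- "no data"
      next
    }
    span <- col[i[1]:i[length(i)]]
    frac <- mean(is.na(span))
    if (frac > max_missing_frac) {
      panel$animals$excluded[j] <- TRUE
      panel$animals$reason[j] <- sprintf("missing fraction %.2f > %.2f",
                                         frac, max_missing_frac)
    } else {
      panel$animals$excluded[j] <- FALSE
      panel$animals$reason[j] <- NA_character_
    }
  }
  n_ex <- sum(panel$animals$excluded)
  if (n_ex == nrow(panel$animals))
    hr_warn("every animal excluded at threshold %.2f", max_missing_frac)
  hr_log("exclusion at threshold %.2f: %d of %d animals excluded",
         max_missing_frac, n_ex, nrow(panel$animals))
  panel
}

#' Stacked herd aggregate
#'
#' Per anchor, the sum of non-missing intensities over included animals (the
#' top line of the stacked graph) plus the number of contributing animals, so
#' a fall in the aggregate caused by loggers ending can be told apart from a
#' genuine synchronous welfare fall.
#'
#' @param panel A `herd_panel`.
#' @param ids Optional subset of included animal ids.
#' @return Tibble `anchor`, `aggregate`, `n_contributing`; `aggregate` is `NA`
#'   where no animal contributes.
#' @export
herd_aggregate <- function(panel, ids = NULL) {
  inc <- included_ids(panel)
  if (!is.null(ids)) {
    if (!all(ids %in% inc))
      hr_abort("hr_invalid_grouping", "ids not among included animals: %s",
               paste(setdiff(ids, inc), collapse = ", "))
    inc <- sort(ids)
  }
  if (!length(inc)) hr_abort("hr_empty_aggregate", "no included animals")
  m <- panel$intensities[, inc, drop = FALSE]
  cnt <- rowSums(!is.na(m))
  agg <- rowSums(m, na.rm = TRUE)
  agg[cnt == 0] <- NA_real_
  tibble::tibble(anchor = panel$grid, aggregate = agg, n_contributing = cnt)
}

#' Sub-group consistency check of the stacked aggregate
#'
#' Stacked graphs can show peaks and troughs driven by a small subset of
#' animals. This check rebuilds the aggregate from sub-groups and scores each
#' against the full-herd aggregate by Pearson correlation over anchors where
#' both are defined -- a quantitative surrogate for the study's visual
#' shape comparison (logged as such). Two schemes: `"contiguous-ranges"`
#' (overlapping id-ordered ranges, the reproduction mode; default ranges are
#' the 1-5 / 1-10 / 6-15 / 11-19 / 16-19 pattern rescaled to the herd size)
#' and `"random-partition"` (seeded split into `k_groups`).
#'
#' @param panel A `herd_panel`.
#' @param scheme `"contiguous-ranges"` or `"random-partition"`.
#' @param k_groups Number of groups for the random partition (default 4).
#' @param ranges Optional list of integer vectors `c(first, last)` (positions
#'   in the ascending included-id order) for the contiguous scheme.
#' @param seed Seed for the random partition.
#' @return A `subgroup_report`: list with `groups` (id lists), `agreement`
#'   (tibble `group`, `n_animals`, `agreement`, `peak_anchor`,
#'   `trough_anchor`), `aggregates` (list of group aggregate tibbles) and the
#'   herd `aggregate`.
#' @export
subgroup_check <- function(panel, scheme = c("contiguous-ranges", "random-partition"),
                           k_groups = 4, ranges = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  inc <- included_ids(panel)
  n <- length(inc)
  if (n < 2) hr_abort("hr_invalid_grouping", "need at least 2 included animals")
  if (scheme == "contiguous-ranges") {
    if (is.null(ranges)) {
      # the five overlapping reference ranges, rescaled from a 19-animal herd
      frac <- list(c(1, 5), c(1, 10), c(6, 15), c(11, 19), c(16, 19))
      ranges <- lapply(frac, function(r) {
        c(max(1L, round(r[1] / 19 * n)), min(n, round(r[2] / 19 * n)))
      })
    }
    groups <- lapply(ranges, function(r) {
      if (r[1] < 1 || r[2] > n || r[1] > r[2])
        hr_abort("hr_invalid_grouping", "range %d-%d outside herd of %d", r[1], r[2], n)
      inc[r[1]:r[2]]
    })
    names(groups) <- vapply(ranges, function(r) sprintf("animals %d-%d", r[1], r[2]),
                            character(1))
  } else {
    if (k_groups > n) hr_abort("hr_invalid_grouping", "more groups than animals")
    set.seed(seed)
    assign <- sample(rep_len(seq_len(k_groups), n))
    groups <- split(inc, assign)
    names(groups) <- sprintf("random group %s", names(groups))
  }
  herd <- herd_aggregate(panel)
  hr_log("sub-group agreement uses Pearson correlation with the herd aggregate (shape surrogate)")
  rows <- list(); aggs <- list()
  for (g in seq_along(groups)) {
    ga <- herd_aggregate(panel, ids = groups[[g]])
    aggs[[names(groups)[g]]] <- ga
    both <- !is.na(ga$aggregate) & !is.na(herd$aggregate)
    agree <- if (sum(both) > 2) stats::cor(ga$aggregate[both], herd$aggregate[both])
             else NA_real_
    ok <- which(!is.na(ga$aggregate))
    rows[[g]] <- tibble::tibble(
      group = names(groups)[g], n_animals = length(groups[[g]]),
      agreement = agree,
      peak_anchor = if (length(ok)) ga$anchor[ok[which.max(ga$aggregate[ok])]] else NA_real_,
      trough_anchor = if (length(ok)) ga$anchor[ok[which.min(ga$aggregate[ok])]] else NA_real_)
  }
  structure(list(groups = groups, agreement = do.call(rbind, rows),
                 aggregates = aggs, herd_aggregate = herd),
            class = "subgroup_report")
}

#' Flag an animal's deviations from herd-synchronous change
#'
#' At each anchor the animal's intensity is standardised against the
#' leave-one-out herd mean and standard deviation (the animal is removed from
#' its own reference so it cannot mask its own deviation). Maximal runs of at
#' least `min_duration` consecutive anchors with |z| above `z_threshold` are
#' reported.
#'
#' @param panel A `herd_panel`.
#' @param animal_id An included animal.
#' @param z_threshold Standardised-deviation threshold (default 2).
#' @param min_duration Minimum run length in anchors (default 4, i.e. 1 h at
#'   the 15-min step).
#' @param min_comparators Minimum number of other included animals with data
#'   at an anchor for a z-score to be defined (default 3).
#' @return Tibble `animal_id`, `start`, `end`, `n_anchors`, `score` (mean |z|
#'   over the run); zero rows when the animal tracks the herd.
#' @export
detect_deviation <- function(panel, animal_id, z_threshold = 2, min_duration = 4,
                             min_comparators = 3) {
  inc <- included_ids(panel)
  if (!animal_id %in% inc)
    hr_abort("hr_invalid_grouping", "animal %s is not included", animal_id)
  others <- setdiff(inc, animal_id)
  if (length(others) < min_comparators)
    hr_abort("hr_insufficient_herd", "need >= %d other included animals, have %d",
             min_comparators, length(others))
  x <- panel$intensities[, animal_id]
  m <- panel$intensities[, others, drop = FALSE]
  cnt <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sd_loo <- apply(m, 1, stats::sd, na.rm = TRUE)
  z <- (x - mu) / sd_loo
  z[is.na(x) | cnt < min_comparators | !is.finite(z)] <- NA_real_
  over <- !is.na(z) & abs(z) > z_threshold
  r <- rle(over)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_duration)
  if (!length(keep))
    return(tibble::tibble(animal_id = character(0), start = numeric(0),
                          end = numeric(0), n_anchors = integer(0),
                          score = numeric(0)))
  tibble::tibble(
    animal_id = animal_id,
    start = panel$grid[starts[keep]],
    end = panel$grid[ends[keep]],
    n_anchors = r$lengths[keep],
    score = vapply(keep, function(i) mean(abs(z[starts[i]:ends[i]])), numeric(1)))
}

#' Maximum lag between a point event and its trace signature
#'
#' A point stressor enters every sliding window that covers it, so its trough
#' in the periodicity trace can trail the event by up to one window length
#' (7 days at the defaults). Used to back-date observed troughs to candidate
#' events.
#'
#' @param spec A [window_spec()].
#' @return Lag bound in seconds (`spec$window_len`).
#' @export
event_lag_bound <- function(spec = window_spec()) spec$window_len

#' Restrict a herd panel to a time interval
#'
#' The study analyses the herd from the date every animal contributes data;
#' this crops the anchor grid to `[start, end]` (inclusive) without touching
#' exclusion flags.
#'
#' @param panel A `herd_panel`.
#' @param start,end Interval bounds in seconds (defaults: unbounded).
#' @return The cropped panel, with per-animal first/last anchors refreshed.
#' @export
crop_panel <- function(panel, start = -Inf, end = Inf) {
  keep <- panel$grid >= start & panel$grid <= end
  if (!any(keep)) hr_abort("hr_structural_input", "crop interval empty")
  panel$grid <- panel$grid[keep]
  panel$intensities <- panel$intensities[keep, , drop = FALSE]
  for (j in seq_len(ncol(panel$intensities))) {
    i <- which(!is.na(panel$intensities[, j]))
    panel$animals$first_anchor[j] <- if (length(i)) panel$grid[i[1]] else NA_real_
    panel$animals$last_anchor[j] <- if (length(i)) panel$grid[i[length(i)]] else NA_real_
  }
  panel
}

#' Locate the trough of a herd aggregate
#'
#' Finds the minimum of the aggregate over anchors with enough contributing
#' animals (so the end-of-logging decline, where loggers drop out one by one,
#' is not mistaken for a welfare fall). Two times are reported for the trough
#' window: its anchor (window start) and `observed`, the window's end -- the
#' moment the 7 days of evidence are complete, which is the time at which a
#' synchronous welfare fall manifests in the trace and from which candidate
#' events are back-dated by up to [event_lag_bound()].
#'
#' @param agg A [herd_aggregate()] tibble.
#' @param spec The [window_spec()] the traces were built with.
#' @param min_contributing Minimum contributing-animal count for an anchor to
#'   be searched; default half the maximum count.
#' @return A list: `anchor`, `observed` (anchor + window length), `value`,
#'   `n_contributing`.
#' @export
aggregate_trough <- function(agg, spec = window_spec(), min_contributing = NULL) {
  if (is.null(min_contributing)) min_contributing <- max(agg$n_contributing) / 2
  ok <- which(!is.na(agg$aggregate) & agg$n_contributing >= min_contributing)
  if (!length(ok)) hr_abort("hr_empty_aggregate", "no searchable anchors")
  i <- ok[which.min(agg$aggregate[ok])]
  list(anchor = agg$anchor[i], observed = agg$anchor[i] + spec$window_len,
       value = agg$aggregate[i], n_contributing = agg$n_contributing[i])
}

#' Write a herd panel to CSV
#'
#' Wide CSV (`anchor` plus one column per animal id, empty = missing) and a
#' sidecar metadata CSV (`animal_id,excluded,reason,first_anchor,last_anchor`).
#'
#' @param panel A `herd_panel`.
#' @param path Panel CSV path.
#' @param meta_path Metadata CSV path (default `<path>` with `_meta` suffix).
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- sub("(\\.[^.]*)?$", "_meta\\1", path)
  wide <- tibble::as_tibble(cbind(tibble::tibble(anchor = panel$grid),
                                  as.data.frame(panel$intensities)))
  readr::write_csv(wide, path, na = "")
  readr::write_csv(panel$animals, meta_path, na = "")
  invisible(path)
}

#' Read a herd panel written by [write_panel_csv()]
#'
#' @param path Panel CSV path.
#' @param meta_path Metadata CSV path (default `<path>` with `_meta` suffix).
#' @return A `herd_panel`.
#' @export
read_panel_csv <- function(path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- sub("(\\.[^.]*)?$", "_meta\\1", path)
  wide <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_double()))
  meta <- readr::read_csv(meta_path, show_col_types = FALSE,
                          col_types = readr::cols(animal_id = readr::col_character(),
                                                  excluded = readr::col_logical(),
                                                  reason = readr::col_character(),
                                                  .default = readr::col_double()))
  meta$excluded[is.na(meta$excluded)] <- FALSE
  grid <- wide$anchor
  mat <- as.matrix(wide[, setdiff(names(wide), "anchor"), drop = FALSE])
  structure(list(grid = grid, intensities = mat, animals = tibble::as_tibble(meta),
                 step = if (length(grid) > 1) grid[2] - grid[1] else 900),
            class = "herd_panel")
}
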