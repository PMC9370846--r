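# Figures: per-animal raw-activity + intensity-trace pairs, and herd /
# sub-group stacked line graphs. Every figure gets a tidy CSV sidecar of
# exactly what was plotted; missing anchors are drawn as gaps, never
# interpolated, and the stacked top line is the herd aggregate verbatim.

#' Stacked layer boundaries of a herd panel
#'
#' Cumulative intensity boundaries in ascending animal-id order (missing
#' contributions stack as zero-thickness layers); the top boundary equals
#' [herd_aggregate()]'s sum.
#'
#' @param panel A `herd_panel`.
#' @param ids Optional subset of included animal ids.
#' @return Tibble `anchor`, `animal_id`, `lower`, `upper`, `value`, `missing`.
#' @export
stack_layers <- function(panel, ids = NULL) {
  inc <- included_ids(panel)
  if (!is.null(ids)) {
    if (!all(ids %in% inc))
      hr_abort("hr_invalid_grouping", "ids not among included animals")
    inc <- sort(ids)
  }
  if (!length(inc)) hr_abort("hr_empty_aggregate", "no included animals")
  m <- panel$intensities[, inc, drop = FALSE]
  filled <- ifelse(is.na(m), 0, m)
  upper <- t(apply(filled, 1, cumsum))
  if (length(inc) == 1) upper <- matrix(filled, ncol = 1)
  lower <- cbind(0, upper[, -ncol(upper), drop = FALSE])
  out <- lapply(seq_along(inc), function(j) {
    tibble::tibble(anchor = panel$grid, animal_id = inc[j],
                   lower = lower[, j], upper = upper[, j],
                   value = m[, j], missing = is.na(m[, j]))
  })
  do.call(rbind, out)
}

#' Two-panel figure for one animal: activity epochs and periodicity trace
#'
#' Top panel: per-epoch activity magnitude; bottom panel: the 24 h
#' periodicity-intensity trace on `[0, 1]`. The x axis is minutes from the
#' start of the animal's record (calendar date as a secondary axis). Missing
#' windows appear as gaps. A tidy CSV of the plotted values is written next
#' to the figure.
#'
#' @param epochs The animal's `epoch_series`.
#' @param trace The animal's `periodicity_trace`.
#' @param out_path Figure path (`.png` or `.svg`); `NULL` for no file.
#' @param width,height,dpi Device settings.
#' @return Invisibly, a list with the `patchwork` plot and the tidy `data`;
#'   `NULL` (with a logged message) on empty input.
#' @export
plot_animal <- function(epochs, trace, out_path = NULL,
                        width = 9, height = 6, dpi = 150) {
  if (nrow(epochs) == 0 || nrow(trace) == 0) {
    hr_log("plot_animal: empty input, no figure written")
    return(invisible(NULL))
  }
  t0 <- epochs$epoch_start[1]
  ep <- tibble::tibble(minutes = (epochs$epoch_start - t0) / 60,
                       value = ifelse(epochs$missing, NA_real_, epochs$value))
  tr <- tibble::tibble(minutes = (trace$anchor - t0) / 60,
                       intensity = trace$intensity)
  id <- attr(epochs, "animal_id") %||% "animal"
  sec_axis <- ggplot2::sec_axis(~ ., name = "date",
                                labels = function(m)
                                  format(as.POSIXct(m * 60 + t0, tz = "UTC",
                                                    origin = "1970-01-01"),
                                         "%d %b"))
  p1 <- ggplot2::ggplot(ep, ggplot2::aes(minutes, value)) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::scale_x_continuous(sec.axis = sec_axis) +
    ggplot2::labs(y = "activity (g, epoch mean)", x = NULL,
                  title = sprintf("%s: activity and 24 h periodicity intensity", id)) +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(tr, ggplot2::aes(minutes, intensity)) +
    ggplot2::geom_line(linewidth = 0.4, na.rm = FALSE, colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "minutes from start of record", y = "periodicity intensity") +
    ggplot2::theme_minimal()
  p <- patchwork::wrap_plots(p1, p2, ncol = 1)
  data <- list(epochs = ep, trace = tr)
  if (!is.null(out_path)) {
    .save_figure(p, out_path, width, height, dpi)
    readr::write_csv(merge(ep, tr, by = "minutes", all = TRUE),
                     paste0(tools::file_path_sans_ext(out_path), ".csv"), na = "")
  }
  invisible(list(plot = p, data = data))
}

#' Stacked line graph of a herd panel
#'
#' Each included animal's intensity is stacked cumulatively in ascending id
#' order (a distinct colour per animal); the top line is the herd aggregate
#' exactly -- no resampling or smoothing -- and anchors with no contributing
#' animal are gaps. A tidy CSV of the layer boundaries is written next to the
#' figure.
#'
#' @param panel A `herd_panel`.
#' @param out_path Figure path (`.png` or `.svg`); `NULL` for no file.
#' @param subset Optional subset of included animal ids.
#' @param title Figure title.
#' @param width,height,dpi Device settings.
#' @return Invisibly, a list: `plot`, `layers` (tidy boundaries), `top` (the
#'   aggregate tibble); `NULL` (logged) if no animal is included.
#' @export
plot_stacked <- function(panel, out_path = NULL, subset = NULL,
                         title = "Stacked 24 h periodicity intensities",
                         width = 10, height = 5, dpi = 150) {
  inc <- if (is.null(subset)) included_ids(panel) else sort(subset)
  if (!length(inc)) {
    hr_log("plot_stacked: no included animals, no figure written")
    return(invisible(NULL))
  }
  layers <- stack_layers(panel, ids = inc)
  top <- herd_aggregate(panel, ids = inc)
  t0 <- panel$grid[1]
  layers$days <- (layers$anchor - t0) / 86400
  topdf <- tibble::tibble(days = (top$anchor - t0) / 86400,
                          aggregate = top$aggregate)
  p <- ggplot2::ggplot(layers,
                       ggplot2::aes(days, ymin = lower, ymax = upper,
                                    fill = animal_id)) +
    ggplot2::geom_ribbon(alpha = 0.85) +
    ggplot2::geom_line(data = topdf, na.rm = FALSE,
                       ggplot2::aes(days, aggregate),
                       inherit.aes = FALSE, linewidth = 0.5) +
    ggplot2::labs(x = "days from start of panel",
                  y = "stacked periodicity intensity",
                  fill = "animal", title = title) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    .save_figure(p, out_path, width, height, dpi)
    readr::write_csv(layers, paste0(tools::file_path_sans_ext(out_path), ".csv"),
                     na = "")
  }
  invisible(list(plot = p, layers = layers, top = top))
}

#' @keywords internal
.save_figure <- function(p, out_path, width, height, dpi) {
  ext <- tolower(tools::file_ext(out_path))
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi,
                  device = if (ext == "svg") grDevices::svg else NULL)
  hr_log("figure written: %s", out_path)
}
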