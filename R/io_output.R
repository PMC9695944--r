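# Result output: CSV time series and PNG/SVG charts.

#' Write a simulated time series to CSV
#'
#' One row per recorded minute, a `time_h` column plus one column per
#' selected series. With `log10 = TRUE` every selected series (titres and
#' nutrient concentration alike) is transformed with [log10_titre()], so an
#' exact zero appears as -16. Column headers use the plain-letter series
#' names (the micro prefix is written "u" throughout the package, so no
#' non-ASCII symbols appear in output files).
#'
#' @param sim a `cocktail_sim` from [run_cocktail()].
#' @param path output file path.
#' @param log10 transform the series? Defaults to the configuration's
#'   `log10_output` flag.
#' @param selection integer indices (1--16) of the series to write; defaults
#'   to the configuration's `output_selection`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(sim, path, log10 = NULL, selection = NULL) {
  if (!inherits(sim, "cocktail_sim")) stop("not a cocktail_sim", call. = FALSE)
  if (nrow(sim$series) == 0L) stop("empty time series", call. = FALSE)
  if (is.null(log10)) log10 <- sim$config$log10_output
  if (is.null(selection)) selection <- sim$config$output_selection
  selection <- as.integer(selection)
  if (length(selection) == 0L || any(selection < 1L) || any(selection > 16L))
    stop("selection must be indices within 1..16", call. = FALSE)
  nm <- cocktail_series_names()[selection]
  out <- sim$series[, c("time_h", nm), drop = FALSE]
  if (log10) for (v in nm) out[[v]] <- log10_titre(out[[v]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Render a titre-versus-time chart to PNG or SVG
#'
#' @param sim a `cocktail_sim` from [run_cocktail()].
#' @param path output file path.
#' @param format `"png"` or `"svg"`.
#' @param log10 draw on a log10 scale (0 mapped to -16)? Default `TRUE`.
#' @param selection integer indices (1--16) of the series to draw; defaults
#'   to the configuration's `output_selection`.
#' @param width,height device size in pixels (PNG) or converted to inches at
#'   100 dpi (SVG).
#' @return `path`, invisibly. Errors (with nothing written) on an unknown
#'   format or an empty selection.
#' @export
render_chart <- function(sim, path, format = c("png", "svg"), log10 = TRUE,
                         selection = NULL, width = 900, height = 600) {
  if (!inherits(sim, "cocktail_sim")) stop("not a cocktail_sim", call. = FALSE)
  format <- tolower(format)
  if (length(format) > 1L) format <- format[1L]
  if (!format %in% c("png", "svg"))
    stop(sprintf("unknown chart format '%s' (use 'png' or 'svg')", format),
         call. = FALSE)
  if (nrow(sim$series) == 0L) stop("empty time series", call. = FALSE)
  if (is.null(selection)) selection <- sim$config$output_selection
  if (length(selection) == 0L)
    stop("empty output selection; nothing to draw", call. = FALSE)
  if (format == "png") {
    grDevices::png(path, width = width, height = height)
  } else {
    grDevices::svg(path, width = width / 100, height = height / 100)
  }
  on.exit(grDevices::dev.off())
  plot(sim, selection = selection, log10 = log10)
  invisible(path)
}
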