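# S3 methods for simulation results.

#' @export
print.cocktail_sim <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  cat(sprintf("<cocktail_sim> %g h simulated at %g s steps (%d records)\n",
              x$config$duration, x$config$step_size, n))
  fin <- s[n, c("S", "I_A", "I_B", "I_AB", "R_A", "R_B", "R_AB", "A", "B", "C")]
  cat("final titres:\n")
  print(signif(unlist(fin), 4))
  invisible(x)
}

#' @export
summary.cocktail_sim <- function(object, ...) {
  s <- object$series
  nm <- cocktail_series_names()
  tab <- t(vapply(nm, function(v) {
    c(start = s[[v]][1], min = min(s[[v]]), max = max(s[[v]]),
      final = s[[v]][nrow(s)])
  }, numeric(4)))
  res <- list(table = tab, config = object$config)
  class(res) <- "summary.cocktail_sim"
  res
}

#' @export
print.summary.cocktail_sim <- function(x, ...) {
  print(x$config)
  cat("\nseries (CFU/mL, PFU/mL, ug/mL):\n")
  print(signif(x$table, 4))
  invisible(x)
}

#' @export
as.data.frame.cocktail_sim <- function(x, ...) x$series

#' Plot simulated titres over time
#'
#' Draws the selected series against time, by default on a log10 scale with
#' the titre-0-to--16 convention of [log10_titre()].
#'
#' @param x a `cocktail_sim`.
#' @param selection integer indices (1--16) of the series to draw; defaults
#'   to the configuration's `output_selection`.
#' @param log10 logical: log-transform titres (default `TRUE`).
#' @param ... further arguments passed to [graphics::matplot()].
#' @return the plotted data, invisibly.
#' @export
plot.cocktail_sim <- function(x, selection = x$config$output_selection,
                              log10 = TRUE, ...) {
  nm <- cocktail_series_names()[selection]
  if (length(nm) == 0L) stop("empty output selection", call. = FALSE)
  y <- as.matrix(x$series[, nm, drop = FALSE])
  if (log10) y <- apply(y, 2, log10_titre)
  graphics::matplot(x$series$time_h, y, type = "l", lty = 1,
                    col = seq_along(nm), xlab = "time (h)",
                    ylab = if (log10) "log10 titre" else "titre", ...)
  graphics::legend("topright", legend = nm, col = seq_along(nm), lty = 1,
                   cex = 0.7, bty = "n")
  invisible(y)
}
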