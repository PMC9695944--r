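# Small shared helpers: numeral parsing and output conventions.

#' Parse a numeral in any of the accepted input notations
#'
#' Accepts plain decimal and scientific notation with a point as the decimal
#' separator (`0.7`, `1e-10`, `2E6`), integers with grouped thousands written
#' without spaces (`1,000,000`), and the spelled-out power notation
#' `1.0 x 10^6` (the multiplication sign may be `x`, `X` or the Unicode
#' times sign; the caret is optional).
#'
#' @param x character vector of numerals.
#' @return numeric vector of the same length.
#' @examples
#' parse_numeral(c("1,000,000", "1.0 x 10^6", "2e-06"))
#' @export
parse_numeral <- function(x) {
  x <- trimws(as.character(x))
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (!nzchar(s)) stop("empty numeral", call. = FALSE)
    # grouped thousands: digits in groups of three, no spaces
    if (grepl("^[+-]?\\d{1,3}(,\\d{3})+$", s)) {
      s <- gsub(",", "", s, fixed = TRUE)
    }
    # explicit power-of-ten notation: <mantissa> x 10^<exp>
    m <- regmatches(s, regexec(
      "^([+-]?[0-9]*\\.?[0-9]+)\\s*[xX×✕]\\s*10\\^?([+-]?[0-9]+)\\^?$", s))[[1]]
    if (length(m) == 3L) {
      out[i] <- as.numeric(m[2]) * 10^as.numeric(m[3])
      next
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(sprintf("cannot parse numeral '%s'", x[i]), call. = FALSE)
    out[i] <- v
  }
  out
}

#' Logarithmic titre with the zero convention
#'
#' Returns `log10(x)` for positive titres and -16 for a titre of exactly 0,
#' so that extinct populations remain representable on a log chart
#' (-16 corresponds to one particle per 10^16 mL).
#'
#' @param x nonnegative numeric vector of titres.
#' @return numeric vector.
#' @examples
#' log10_titre(c(0, 1, 1e8))
#' @export
log10_titre <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("titres must be finite and nonnegative", call. = FALSE)
  }
  ifelse(x == 0, -16, log10(x))
}

#' Round sub-unity pools to zero
#'
#' Applies the "round off values below one" rule: every pool strictly between
#' 0 and 1 is set to exactly 0. Values of exactly 1 or more, and exact zeros,
#' are unchanged. Within a simulation this is applied to whole bacterial and
#' phage pools after each completed step when `round_below_one` is enabled in
#' the run configuration.
#'
#' @param state named or unnamed nonnegative numeric vector of pool sizes.
#' @return the state with sub-unity pools zeroed.
#' @examples
#' apply_rounding(c(S = 0.01, R_A = 1, A = 2.5))
#' @export
apply_rounding <- function(state) {
  if (any(state < 0, na.rm = TRUE)) stop("pools must be nonnegative", call. = FALSE)
  state[state > 0 & state < 1] <- 0
  state
}

#' Names of the recorded series in canonical output order
#'
#' The sixteen series a run records, in the order referenced by the
#' `output_selection` indices (1--16): the thirteen bacterial compartments,
#' the two free-phage pools and the nutrient concentration.
#'
#' @return character vector of length 16.
#' @export
cocktail_series_names <- function() {
  c("S", "I_A", "I_B", "I_AB", "R_A", "R_B", "R_AB", "R_AIB", "R_BIA",
    "S_r", "R_rA", "R_rB", "R_rAB", "A", "B", "C")
}
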