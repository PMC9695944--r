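# Plain-text run-configuration files (".ctl").
#
# The canonical schema is a fixed sequence of labelled lines; a comma
# separates the label from its value(s) and the values from one another, and
# the final line lists the selected output indices blank-separated after the
# label "Output parameters:". The line order is strict: a permuted file is a
# file error, reported with the offending line number. Numerals may be
# decimal, scientific, grouped-thousands (written without spaces, e.g.
# 1,000,000) or spelled powers of ten (1.0 x 10^6); the micro prefix is
# written "u" (uA, ug/mL).

.ctl_header <- "Cocktail chemostat run configuration"

# label, number of values (NA = variable pairs, -1 = bare word(s))
.ctl_schema <- list(
  list("S0 (CFU/mL)", 1L),
  list("fRA fRB fRAB", 3L),
  list("psi psiRA psiRB psiRAB (/h)", 4L),
  list("K (ug/mL)", 1L),
  list("epsilon (ug/cell)", 1L),
  list("gamma (/h)", 1L),
  list("uA uB (/cell division)", 2L),
  list("sigma rho (/min)", 2L),
  list("C0 Cin (ug/mL)", 2L),
  list("omega (/h)", 1L),
  list("deltaA lA betaA phiA (mL/min min PFU/cell /h)", 4L),
  list("Phage A additions (h PFU/mL)", NA_integer_),
  list("deltaB lB betaB phiB (mL/min min PFU/cell /h)", 4L),
  list("Phage B additions (h PFU/mL)", NA_integer_),
  list("Primary adsorption", -1L),
  list("Secondary adsorption", -1L),
  list("Mutation mode", -1L),
  list("Refuge mode", -1L),
  list("Round below one", -1L),
  list("Log10 output", -1L),
  list("Step size (s)", 1L),
  list("Duration (h)", 1L),
  list("Seed", 1L))

.fmt <- function(x) sprintf("%.15g", x)

#' Write a run configuration to a canonical `.ctl` text file
#'
#' The file is strictly ordered and re-readable with [read_config()]; the
#' round trip reproduces the configuration field for field.
#'
#' @param config a validated [cocktail_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  b <- config$bacteria; ch <- config$chemostat
  pA <- config$phage_A; pB <- config$phage_B
  adds <- function(p) {
    if (nrow(p$additions) == 0L) return(character(0))
    .fmt(as.vector(t(p$additions)))
  }
  line <- function(i, ...) {
    vals <- c(...)
    if (length(vals) == 0L) .ctl_schema[[i]][[1]]
    else paste(c(.ctl_schema[[i]][[1]], vals), collapse = ", ")
  }
  out <- c(
    .ctl_header,
    line(1, .fmt(b$S0)),
    line(2, .fmt(c(b$f_RA, b$f_RB, b$f_RAB))),
    line(3, .fmt(c(b$psi, b$psi_RA, b$psi_RB, b$psi_RAB))),
    line(4, .fmt(b$K)),
    line(5, .fmt(b$epsilon)),
    line(6, .fmt(b$gamma)),
    line(7, .fmt(c(b$mu_A, b$mu_B))),
    line(8, .fmt(c(b$sigma, b$rho))),
    line(9, .fmt(c(ch$C0, ch$C_in))),
    line(10, .fmt(ch$omega)),
    line(11, .fmt(c(pA$delta, pA$latent, pA$burst, pA$phi))),
    line(12, adds(pA)),
    line(13, .fmt(c(pB$delta, pB$latent, pB$burst, pB$phi))),
    line(14, adds(pB)),
    line(15, config$primary_adsorption),
    line(16, config$secondary_adsorption),
    line(17, config$mutation_mode),
    line(18, config$refuge_mode),
    line(19, if (config$round_below_one) "TRUE" else "FALSE"),
    line(20, if (config$log10_output) "TRUE" else "FALSE"),
    line(21, .fmt(config$step_size)),
    line(22, .fmt(config$duration)),
    line(23, .fmt(config$seed)),
    paste0("Output parameters: ",
           paste(config$output_selection, collapse = " "), " "))
  writeLines(out, path)
  invisible(path)
}

# split a value string on commas; rejoin grouped thousands, which are written
# without spaces (a bare 3-digit continuation of a preceding digit run)
.split_items <- function(rest) {
  pieces <- strsplit(rest, ",", fixed = TRUE)[[1]]
  out <- character(0)
  for (p in pieces) {
    if (length(out) > 0L && grepl("^[0-9]{3}$", p) &&
        grepl("[0-9]$", out[length(out)])) {
      out[length(out)] <- paste0(out[length(out)], p)
    } else {
      out <- c(out, p)
    }
  }
  trimws(out)
}

.ctl_err <- function(lineno, msg) {
  stop(sprintf("file error at line %d: %s", lineno, msg), call. = FALSE)
}

#' Read a run configuration from a `.ctl` text file
#'
#' The parser is strict about the canonical line order: a missing, permuted
#' or mislabelled line is a file error naming the line. Values are validated
#' against the allowed parameter ranges after parsing; out-of-range values
#' are errors (no silent auto-correction), with the allowed range in the
#' message.
#'
#' @param path path to the file.
#' @return a validated [cocktail_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_expect <- length(.ctl_schema) + 2L  # header + schema + output line
  if (length(lines) != n_expect)
    stop(sprintf("file error: expected %d lines, found %d", n_expect,
                 length(lines)), call. = FALSE)
  if (trimws(lines[1]) != .ctl_header)
    .ctl_err(1L, sprintf("expected header '%s'", .ctl_header))
  all_labels <- vapply(.ctl_schema, `[[`, "", 1L)
  vals <- vector("list", length(.ctl_schema))
  for (i in seq_along(.ctl_schema)) {
    lineno <- i + 1L
    ln <- lines[lineno]
    lab <- .ctl_schema[[i]][[1]]
    nv <- .ctl_schema[[i]][[2]]
    has_comma <- grepl(",", ln, fixed = TRUE)
    got <- trimws(if (has_comma) sub(",.*$", "", ln) else ln)
    if (got != lab) {
      hint <- if (got %in% all_labels) " (line out of place)" else ""
      .ctl_err(lineno, sprintf("expected label '%s', found '%s'%s",
                               lab, got, hint))
    }
    rest <- if (has_comma) sub("^[^,]*,", "", ln) else ""
    items <- if (nzchar(trimws(rest))) .split_items(rest) else character(0)
    if (!is.na(nv) && nv > 0L) {
      if (!has_comma) .ctl_err(lineno, "missing comma delimiter")
      if (length(items) != nv)
        .ctl_err(lineno, sprintf("expected %d value(s), found %d", nv,
                                 length(items)))
    }
    if (is.na(nv) && length(items) %% 2L != 0L)
      .ctl_err(lineno, "phage additions must come in time,titre pairs")
    if (identical(nv, -1L) && length(items) != 1L)
      .ctl_err(lineno, "expected a single word")
    num <- NULL
    if (!identical(nv, -1L) && length(items)) {
      num <- tryCatch(parse_numeral(items),
                      error = function(e) .ctl_err(lineno, conditionMessage(e)))
    }
    vals[[i]] <- if (identical(nv, -1L)) items else num
  }
  outline <- lines[length(lines)]
  if (!grepl("^Output parameters:", outline))
    .ctl_err(length(lines), "expected 'Output parameters:' line")
  idx_str <- strsplit(trimws(sub("^Output parameters:", "", outline)),
                      "[[:blank:]]+")[[1]]
  idx_str <- idx_str[nzchar(idx_str)]
  if (length(idx_str) == 0L)
    .ctl_err(length(lines), "no output indices given")
  sel <- tryCatch(as.integer(parse_numeral(idx_str)),
                  error = function(e) .ctl_err(length(lines),
                                               conditionMessage(e)))
  to_bool <- function(i) {
    w <- toupper(vals[[i]])
    if (!w %in% c("TRUE", "FALSE"))
      .ctl_err(i + 1L, "expected TRUE or FALSE")
    w == "TRUE"
  }
  adds <- function(i) {
    v <- vals[[i]]
    if (length(v) == 0L) {
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("time_h", "titre")))
    } else {
      matrix(v, ncol = 2, byrow = TRUE,
             dimnames = list(NULL, c("time_h", "titre")))
    }
  }
  cocktail_config(
    bacteria = bacterial_params(
      S0 = vals[[1]], f_RA = vals[[2]][1], f_RB = vals[[2]][2],
      f_RAB = vals[[2]][3], psi = vals[[3]][1], psi_RA = vals[[3]][2],
      psi_RB = vals[[3]][3], psi_RAB = vals[[3]][4], K = vals[[4]],
      epsilon = vals[[5]], gamma = vals[[6]], mu_A = vals[[7]][1],
      mu_B = vals[[7]][2], sigma = vals[[8]][1], rho = vals[[8]][2]),
    chemostat = chemostat_params(C0 = vals[[9]][1], C_in = vals[[9]][2],
                                 omega = vals[[10]]),
    phage_A = phage_params(delta = vals[[11]][1], latent = vals[[11]][2],
                           burst = vals[[11]][3], phi = vals[[11]][4],
                           additions = adds(12)),
    phage_B = phage_params(delta = vals[[13]][1], latent = vals[[13]][2],
                           burst = vals[[13]][3], phi = vals[[13]][4],
                           additions = adds(14)),
    primary_adsorption = vals[[15]],
    secondary_adsorption = vals[[16]],
    mutation_mode = vals[[17]],
    refuge_mode = vals[[18]],
    round_below_one = to_bool(19),
    log10_output = to_bool(20),
    step_size = vals[[21]],
    duration = vals[[22]],
    seed = vals[[23]],
    output_selection = sel)
}
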