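# Internal helpers: argument validation and display-rounding conventions.

stop_ngra <- function(..., class = "ngra_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE, len = 1L) {
  if (!is.numeric(x) || length(x) != len) {
    stop_ngra(sprintf("`%s` must be a numeric vector of length %d", name, len),
              class = "ngra_validation_error")
  }
  if (finite && any(!is.finite(x))) {
    stop_ngra(sprintf("`%s` must be finite", name), class = "ngra_validation_error")
  }
  if (positive && any(x <= 0)) {
    stop_ngra(sprintf("`%s` must be > 0", name), class = "ngra_validation_error")
  }
  if (nonneg && any(x < 0)) {
    stop_ngra(sprintf("`%s` must be >= 0", name), class = "ngra_validation_error")
  }
  invisible(x)
}

check_fraction <- function(x, name, allow_zero = FALSE) {
  check_number(x, name)
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!lo_ok || x > 1) {
    stop_ngra(sprintf("`%s` must be a fraction in %s0, 1]", name,
                      if (allow_zero) "[" else "("),
              class = "ngra_validation_error")
  }
  invisible(x)
}

# round-half-up at `digits` decimal places (base round() is half-to-even),
# with a relative epsilon so values a few ulp below a half-boundary (e.g. a
# ratio of two recomputed medians) still round up
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps) * abs(x * p)) / p
}

#' Display rounding for derived concentrations
#'
#' Concentrations are carried at full precision; for reporting they are
#' rounded the way safety assessors print them: values of 10 or more as
#' integers, smaller values to three significant figures (so a NOEC of
#' 33.33 nM prints as 33 and one of 1.733 nM prints as 1.73).
#'
#' @param x numeric concentration(s).
#' @return numeric vector rounded for display.
#' @export
display_conc <- function(x) {
  check_number(x, "x", nonneg = TRUE, len = length(x))
  ifelse(x >= 10, round_half_up(x), signif(x, 3))
}

#' Display rounding for bioactivity-exposure ratios
#'
#' Ratios of 20 or more print as integers, ratios between 1 and 20 with one
#' decimal, and ratios below 1 to one significant figure (so 166.7 prints as
#' 167, 1.68 as 1.7 and 0.00318 as 0.003).
#'
#' @param x numeric ratio(s), > 0.
#' @return numeric vector rounded for display.
#' @export
display_ber <- function(x) {
  check_number(x, "x", positive = TRUE, len = length(x))
  ifelse(x >= 20, round_half_up(x),
         ifelse(x >= 1, round_half_up(x, 1), signif(x, 1)))
}

# geometric mean / sd of a positive vector
geomean <- function(x) exp(mean(log(x)))
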