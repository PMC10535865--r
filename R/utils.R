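# Internal helpers shared across modules.

# Boltzmann constant in kcal/mol/K (gas constant R in thermochemical kcal).
.kB <- 0.0019872041

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the
#' convention of the published resistance/reversal tables), unlike base
#' [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(23.666, 1)  # 23.7
#' round_half_up(0.34375, 1) # 0.3
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", what), call. = FALSE)
  }
  invisible(x)
}

# least-squares slope of y on x; NA if degenerate
ls_slope <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / sxx
}
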