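#' Round half away from zero
#'
#' Reported rates, percentages and euro amounts are rounded half away from
#' zero at the reporting layer only; all intermediate arithmetic is exact.
#' Base \code{round()} rounds half to even, which is not the convention used
#' in clinical reporting.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Deterministic 31-bit hash of a string
#'
#' Polynomial string hash over a Mersenne prime, used to derive per-admission
#' random substreams and the scenario-B weekday assignment from
#' (seed, admission id). Results are independent of table ordering and of the
#' platform's RNG state.
#'
#' @param x character vector to hash.
#' @param seed integer seed mixed into the initial state.
#' @return integer vector in [0, 2^31 - 2].
#' @keywords internal
hash31 <- function(x, seed = 0L) {
  p <- 2147483647  # 2^31 - 1
  vapply(x, function(s) {
    h <- (as.numeric(seed) %% p + 17) %% p
    for (code in utf8ToInt(s)) {
      h <- (h * 31 + code) %% p
      # extra mixing pass so nearby ids decorrelate in the low bits
      h <- (h * 2654435761) %% p
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Day of week as an integer
#'
#' @param date a Date vector.
#' @return integer vector, 0 = Sunday ... 6 = Saturday (locale independent).
#' @keywords internal
wday_num <- function(date) {
  as.POSIXlt(date)$wday
}

# Quantiles throughout the package use the median-unbiased convention
# (type 8); documented in the README since no convention is standard in
# clinical costing tables.
quant8 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 8, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
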