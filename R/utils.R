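#' Round half away from zero
#'
#' Reporting helper: `base::round()` rounds half to even, whereas the printed
#' percentages this package reproduces (class support, BUSCO-style fractions,
#' assembly gap/GC content) follow conventional half-up rounding.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a total, printed-style
#'
#' @param k count
#' @param n total (> 0)
#' @param digits decimal places (default 1)
#' @return numeric percentage rounded half-up
#' @export
percent_of <- function(k, n, digits = 1) {
  stopifnot(n > 0)
  round_half_up(100 * k / n, digits)
}

# Deterministic per-generator seed derived from a master seed and a label.
# Each simulator draws from its own substream so adding one generator never
# perturbs another. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
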