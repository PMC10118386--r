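# Internal numerical helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
logdiffexp <- function(a, b) {
  stopifnot(a >= b)
  if (is.infinite(b) && b < 0) return(a)
  a + log1p(-exp(b - a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

# smallest representable positive p-value used when inputs underflow
.P_FLOOR <- 1e-300

#' Bonferroni adjustment helper
#'
#' Adjusted p-value `min(1, p * n_tests)`; monotone in `p`. The number of
#' tests is an explicit argument because genome-wide screens rarely carry
#' their own denominator.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param n_tests Positive integer, the Bonferroni denominator.
#' @return Numeric vector of adjusted p-values.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  stopifnot(is.numeric(p), n_tests >= 1)
  pmin(1, p * n_tests)
}
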