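#' @keywords internal
"_PACKAGE"

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Anderson-Darling statistic against a fully specified continuous
## distribution, given its CDF values at the sample points.
## Asymptotic 1% critical value for the fully-specified case is 3.857.
ad_statistic <- function(u) {
  u <- sort(u)
  n <- length(u)
  eps <- .Machine$double.eps
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
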