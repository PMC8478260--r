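#' @importFrom methods new validObject is slot
#' @importFrom stats rpois runif quantile kmeans var sd dist cor dpois
#'   rlnorm rgamma rnorm nls coef predict smooth.spline binom.test
#' @importFrom utils head tail
NULL

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# pairwise log(exp(a) + exp(b)), vectorised
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
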