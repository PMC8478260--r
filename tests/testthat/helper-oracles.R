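## Shared fixtures and independent oracles for the test suite.

# truncated double-sum oracle for the change / no-change likelihood ratio:
# P(Z = z) = sum_x P(X = x) P(Y = x + z) with explicit Poisson pmfs,
# summed over x = 0..x_max
oracle_diff_pmf <- function(z, g1, g2, x_max = 500L) {
  xs <- 0:x_max
  ok <- xs + z >= 0
  sum(dpois(xs[ok], g1) * dpois(xs[ok] + z, g2))
}

oracle_logL <- function(z, lam, mu, m, q, x_max = 500L) {
  lo <- max(lam - mu, 1e-6); hi <- lam + mu
  num <- 0.5 * (oracle_diff_pmf(z, m * hi, q * lo, x_max) +
                  oracle_diff_pmf(z, m * lo, q * hi, x_max))
  den <- oracle_diff_pmf(z, m * lam, q * lam, x_max)
  log(num / den)
}

# exhaustive edit-script search: minimal edits by explicit recursion
# (memoised), independent of the DP implementation
oracle_edit <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + (ca[i] != cb[j]))
    memo[[key]] <- v
    v
  }
  rec(length(ca), length(cb))
}

# small reusable image pairs (built once per test run)
tiny_pair <- local({
  cache <- new.env(parent = emptyenv())
  function(contrast, seed = 1L, width = 144L, height = 108L, radius = 10) {
    key <- sprintf("c%g_s%d_w%d", contrast, seed, width)
    if (is.null(cache[[key]]))
      cache[[key]] <- makeChangePair(width_px = width, height_px = height,
                                     contrast = contrast, radius = radius,
                                     seed = seed, n_objects = 5L)
    cache[[key]]
  }
})

# fast model parameters for short simulator tests (12 x 9 grid trials)
fast_params <- function(...) {
  args <- list(...)
  if (!"trial_bins" %in% names(args)) args$trial_bins <- 400L
  do.call(modelParams, args)
}
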