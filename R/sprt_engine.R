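## SPRT engine: Poisson spike generation, the Bessel-function change /
## no-change likelihood ratio on spike-count differences, the spatial decay
## field, leaky noisy evidence accumulation and the dual decision bounds.

#' Draw Poisson spike counts
#'
#' Independent Poisson counts per region and time bin, with mean rates in
#' spikes/bin. Blank bins (handled by the stimulus schedule) contribute zero
#' counts and are not drawn here.
#'
#' @param rates per-region mean rates (spikes/bin), all >= 0.
#' @param n_bins number of time bins.
#' @param seed optional integer; when given, draws are made under a local RNG
#'   seed so repeated calls are bitwise reproducible.
#' @return length(rates) x n_bins integer matrix of counts.
#' @export
drawSpikes <- function(rates, n_bins, seed = NULL) {
  if (any(rates < 0)) stop("rates must be non-negative")
  draw <- function() matrix(rpois(length(rates) * n_bins, rates),
                            length(rates), n_bins)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

## log I_nu(x) for x >= 0, nu >= 0, vectorised.
## Primary path: exponentially scaled besselI. When the scaled evaluation
## underflows or loses precision (large order relative to argument), the
## large-order closed form log I_nu(x) ~ nu log(x/2) - lgamma(nu + 1) is
## used; a non-finite direct evaluation at very large argument falls back to
## the two-term large-argument expansion
## I_nu(x) ~ e^x / sqrt(2 pi x) * (1 - (4 nu^2 - 1) / (8 x)).
log_besseli <- function(x, nu) {
  n <- max(length(x), length(nu))
  x <- rep_len(x, n); nu <- rep_len(nu, n)
  out <- rep(NA_real_, n)

  ## large-argument asymptotic series (the "sufficiently large x" form,
  ## carried to enough terms for machine accuracy in its validity region)
  big <- x >= 400 & nu^2 <= x
  if (any(big)) {
    xs <- x[big]; ns <- nu[big]
    term <- rep(1, length(xs)); acc <- term
    for (k in 1:15) {
      term <- term * -(4 * ns^2 - (2 * k - 1)^2) / (8 * k * xs)
      acc <- acc + term
    }
    out[big] <- xs - 0.5 * log(2 * pi * xs) + log(pmax(acc, 1e-300))
  }

  ## primary path: exponentially scaled Bessel evaluation
  rest <- which(!big)
  if (length(rest)) {
    b <- suppressWarnings(besselI(x[rest], nu[rest], expon.scaled = TRUE))
    ok <- is.finite(b) & b > 0
    out[rest[ok]] <- x[rest[ok]] + log(b[ok])
    fail <- rest[!ok]
    if (length(fail)) {
      xf <- x[fail]; nf <- nu[fail]
      res <- numeric(length(fail))
      ## large-order limit (x small relative to the order)
      go <- xf == 0 | xf^2 < 2 * (nf + 1)
      res[go] <- ifelse(xf[go] == 0 & nf[go] == 0, 0,
                        nf[go] * log(xf[go] / 2) - lgamma(nf[go] + 1))
      ## uniform large-order (Debye) form bridging the remaining zone
      du <- !go & nf >= 1
      if (any(du)) {
        t <- xf[du] / nf[du]
        s <- sqrt(1 + t^2)
        eta <- s + log(t / (1 + s))
        res[du] <- nf[du] * eta - 0.5 * log(2 * pi * nf[du]) - 0.5 * log(s)
      }
      ## tiny order, huge argument: two-term large-argument form
      lx <- !go & nf < 1
      if (any(lx))
        res[lx] <- xf[lx] - 0.5 * log(2 * pi * xf[lx]) +
          log1p(-(4 * nf[lx]^2 - 1) / (8 * xf[lx]))
      out[fail] <- res
    }
  }
  out
}

## log P(Z = z) with Z = Y - X, X ~ Poisson(g1), Y ~ Poisson(g2):
## the Skellam law, -(g1+g2) + (z/2) log(g2/g1) + log I_|z|(2 sqrt(g1 g2)),
## with degenerate-rate edges handled explicitly.
log_skellam <- function(z, g1, g2) {
  n <- max(length(z), length(g1), length(g2))
  z <- rep_len(z, n); g1 <- rep_len(g1, n); g2 <- rep_len(g2, n)
  out <- numeric(n)
  main <- g1 > 0 & g2 > 0
  if (any(main)) {
    zz <- z[main]
    out[main] <- -(g1[main] + g2[main]) +
      (zz / 2) * (log(g2[main]) - log(g1[main])) +
      log_besseli(2 * sqrt(g1[main] * g2[main]), abs(zz))
  }
  d1 <- !main & g1 <= 0   # X degenerate at 0: Z = Y
  out[d1] <- ifelse(z[d1] >= 0, dpois(pmax(z[d1], 0), g2[d1], log = TRUE),
                    -Inf)
  d2 <- !main & g1 > 0 & g2 <= 0   # Y degenerate at 0: Z = -X
  out[d2] <- ifelse(z[d2] <= 0, dpois(pmax(-z[d2], 0), g1[d2], log = TRUE),
                    -Inf)
  out
}

#' Log-likelihood ratio for change versus no change
#'
#' For spike-count difference z = Y - X observed over m bins on the first
#' image and q bins on the second, with estimated mean rate `lam`
#' (spikes/bin) and a singleton prior `mu_f` on the firing-rate difference:
#' under change, X and Y come from rates lam +/- mu_f (the two signs equally
#' likely, hence the 1/2 mixture); under no change both come from rate lam.
#' Each hypothesis likelihood is a Skellam probability evaluated through
#' exponentially-scaled modified Bessel functions of the first kind, with
#' log-space asymptotic fallbacks where direct evaluation under- or
#' overflows. The change-hypothesis rate lam - mu_f is clamped at 1e-6 when
#' mu_f >= lam.
#'
#' @param z integer spike-count difference(s), Y - X.
#' @param lam estimated mean rate(s), > 0 (spikes/bin).
#' @param mu_f prior firing-rate difference, >= 0 (spikes/bin).
#' @param m,q bins spent on the first / second image (>= 1).
#' @return log L, vectorised over z and lam.
#' @examples
#' logLikRatio(6, 10, 3, 5, 5)
#' logLikRatio(0, 10, 0, 5, 5)  # mu_f = 0: hypotheses coincide, log L = 0
#' @export
logLikRatio <- function(z, lam, mu_f, m, q) {
  if (any(z != round(z))) stop("z must be integer-valued")
  if (any(lam <= 0)) stop("lam must be > 0")
  if (mu_f < 0) stop("mu_f must be >= 0")
  if (m < 1 || q < 1) stop("m and q must be >= 1")
  n <- max(length(z), length(lam))
  z <- rep_len(z, n); lam <- rep_len(lam, n)
  if (mu_f == 0) return(numeric(n))
  lo <- pmax(lam - mu_f, 1e-6)
  hi <- lam + mu_f
  num <- log(0.5) + logaddexp(log_skellam(z, m * hi, q * lo),
                              log_skellam(z, m * lo, q * hi))
  num - log_skellam(z, m * lam, q * lam)
}

#' Spatial decay field of the evidence accumulator
#'
#' Per-region decay factors gamma_i = gamma * exp(-d^2 / (2 beta_decay^2)),
#' a two-dimensional Gaussian peaking at the fixated region, where d is the
#' Euclidean distance in grid units between region centres.
#'
#' @param fixated_region region index of the current fixation.
#' @param gamma peak decay factor, in [0, 1].
#' @param beta_decay spatial scale (grid units), > 0.
#' @param grid the \linkS4class{GridSpec}.
#' @return numeric vector of per-region decay factors in [0, gamma].
#' @export
decayField <- function(fixated_region, gamma, beta_decay, grid) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (beta_decay <= 0) stop("beta_decay must be > 0")
  rc <- regionRowCol(grid, seq_len(nRegions(grid)))
  f <- regionRowCol(grid, fixated_region)
  d2 <- (rc[, "row"] - f[1L, "row"])^2 + (rc[, "col"] - f[1L, "col"])^2
  gamma * exp(-d2 / (2 * beta_decay^2))
}

#' One leaky, noisy evidence-accumulation step
#'
#' E_i(t) = (1 - gamma_i) E_i(t-1) + log L_i(t) + log P + W_i(t) with
#' W_i ~ U(-w, w) drawn independently per region. The log-prior term is
#' added only where `prior_mask` is TRUE (by default everywhere a likelihood
#' was evaluated).
#'
#' @param E per-region evidence at t-1.
#' @param logL per-region log-likelihood-ratio input (0 where no likelihood
#'   is available).
#' @param prior_odds prior odds of change to no change, > 0.
#' @param decay per-region decay factors (see [decayField()]).
#' @param noise_half_width half-width w of the uniform accumulation noise.
#' @param prior_mask logical (recycled) selecting the regions that receive
#'   the log-prior term.
#' @param seed optional integer for a locally seeded, reproducible noise
#'   draw.
#' @return the updated per-region evidence vector.
#' @export
updateEvidence <- function(E, logL, prior_odds, decay, noise_half_width,
                           prior_mask = TRUE, seed = NULL) {
  if (length(logL) != length(E)) stop("logL must match E in length")
  draw <- function() if (noise_half_width > 0)
    runif(length(E), -noise_half_width, noise_half_width) else numeric(length(E))
  W <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  (1 - decay) * E + logL + log(prior_odds) * as.numeric(prior_mask) + W
}

#' Dual-bound decision at the fixated region
#'
#' @param e_fixated accumulated evidence at the fixated region.
#' @param f_c change bound (> 0).
#' @param f_n_t (possibly decayed) no-change bound (< 0).
#' @return "detect" if e >= f_c, "break_fixation" if e <= f_n_t, else
#'   "continue".
#' @export
checkThresholds <- function(e_fixated, f_c, f_n_t) {
  if (!(f_n_t < 0 && 0 < f_c)) stop("need f_n_t < 0 < f_c")
  if (e_fixated >= f_c) "detect"
  else if (e_fixated <= f_n_t) "break_fixation"
  else "continue"
}

#' Decay schedule of the no-change bound
#'
#' |F_n(t)| = |F_n| exp(-zeta t), with t counted in bins from fixation
#' onset; zeta = 0 leaves the bound constant.
#'
#' @param f_n the no-change bound at fixation onset (< 0).
#' @param zeta decay rate (>= 0, per bin).
#' @param t_bins bins elapsed within the current fixation (vectorised).
#' @return the decayed (still negative) bound.
#' @export
thresholdSchedule <- function(f_n, zeta, t_bins) {
  if (zeta < 0) stop("zeta must be >= 0")
  -abs(f_n) * exp(-zeta * t_bins)
}
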