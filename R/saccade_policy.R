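## Saccade policy: clipped third-order-Taylor softmax over evidence, human
## amplitude/turn-angle bias imposition, categorical sampling, and the
## inhibition-of-return saliency baseline sampler.

# third-order Taylor expansion of exp(x), clipped below at 0
taylor3 <- function(x) pmax(1 + x + x^2 / 2 + x^3 / 6, 0)

#' Softmax saccade probabilities from an evidence map
#'
#' Weights are the clipped third-order Taylor approximation of exp(E_i / T)
#' (a softer saturation than the exact exponential), renormalised to sum to
#' 1. When every weight clips to zero the policy falls back to a uniform
#' distribution rather than failing mid-trial.
#'
#' @param E per-region evidence (any numeric vector).
#' @param temperature softmax temperature T, > 0.
#' @return per-region probabilities summing to 1.
#' @examples
#' softmaxProbabilities(c(0, 0, 0, 0), 1)     # uniform by symmetry
#' softmaxProbabilities(c(2, 1, 0), 1)        # clipped-Taylor weights
#' @export
softmaxProbabilities <- function(E, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  w <- taylor3(E / temperature)
  s <- sum(w)
  if (!is.finite(s) || s <= 0) return(rep(1 / length(E), length(E)))
  w / s
}

# amplitude (grid units) and turn angle (degrees, (-180, 180]) of a saccade
# from `from` to every region, relative to the previous saccade direction
saccade_geometry <- function(grid, from, prev = NULL) {
  rc <- regionRowCol(grid, seq_len(nRegions(grid)))
  f <- regionRowCol(grid, from)
  dx <- rc[, "col"] - f[1L, "col"]
  dy <- rc[, "row"] - f[1L, "row"]
  amp <- sqrt(dx^2 + dy^2)
  ang <- rep(NA_real_, length(amp))
  if (!is.null(prev)) {
    p <- regionRowCol(grid, prev)
    vx <- f[1L, "col"] - p[1L, "col"]; vy <- f[1L, "row"] - p[1L, "row"]
    if (vx != 0 || vy != 0) {
      a <- atan2(dy, dx) - atan2(vy, vx)
      a <- (a + pi) %% (2 * pi) - pi          # wrap to (-pi, pi]
      a[a <= -pi] <- pi
      ang <- a * 180 / pi
    }
  }
  list(amplitude = amp, angle = ang)
}

# bias mass for given amplitudes/angles; angle NA (first saccade or unknown
# direction) uses the amplitude marginal
bias_lookup <- function(bias, amplitude, angle) {
  ai <- findInterval(amplitude, bias@amp_breaks, rightmost.closed = TRUE)
  ai <- clamp(ai, 1L, nrow(bias@density))
  marg <- rowSums(bias@density)
  out <- numeric(length(amplitude))
  known <- !is.na(angle)
  if (any(known)) {
    ni <- findInterval(angle[known], bias@angle_breaks,
                       rightmost.closed = TRUE)
    ni <- clamp(ni, 1L, ncol(bias@density))
    out[known] <- bias@density[cbind(ai[known], ni)]
  }
  out[!known] <- marg[ai[!known]] / ncol(bias@density)
  out
}

#' Impose the human saccade amplitude/turn-angle bias on saccade weights
#'
#' Each candidate region's weight is multiplied by the bias mass at its
#' (amplitude, turn angle) relative to the current and previous fixations,
#' then renormalised. Before the first saccade (no previous fixation) only
#' the amplitude marginal is applied. A uniform bias leaves the weights
#' unchanged.
#'
#' @param weights non-negative per-region saccade weights.
#' @param current_fix,prev_fix region indices; `prev_fix` may be NULL.
#' @param bias a \linkS4class{BiasDistribution}.
#' @param grid the \linkS4class{GridSpec}.
#' @return re-weighted, renormalised probabilities (uniform fallback if all
#'   mass vanishes).
#' @export
applySaccadeBias <- function(weights, current_fix, prev_fix, bias, grid) {
  geo <- saccade_geometry(grid, current_fix, prev_fix)
  w <- weights * bias_lookup(bias, geo$amplitude, geo$angle)
  s <- sum(w)
  if (!is.finite(s) || s <= 0) return(rep(1 / length(w), length(w)))
  w / s
}

#' Sample the next fixation region
#'
#' @param probabilities per-region probabilities (non-negative, summing to a
#'   positive total).
#' @param seed optional integer for a locally seeded, reproducible draw.
#' @return a single region index.
#' @export
sampleNextFixation <- function(probabilities, seed = NULL) {
  if (any(probabilities < 0) || sum(probabilities) <= 0)
    stop("degenerate probability vector")
  draw <- function() sample.int(length(probabilities), 1L,
                                prob = probabilities)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' One step of the inhibition-of-return saliency baseline
#'
#' The saccade sampler used to compare saliency-only gaze prediction with the
#' SPRT model: an IOR map accumulates a Gaussian patch (sd `sigma_px`)
#' centred on the current fixation, scaled by the ramp tanh(0.05 t) and
#' discounted by 0.25 per step, clipped to [0, 1]; saccade weights are the
#' complement of the IOR map times the (foveally magnified) saliency map,
#' passed through the same clipped-Taylor softmax as the SPRT policy.
#'
#' @param sal saliency matrix (any resolution; [0, 1]).
#' @param ior IOR state matrix, same dim as `sal` (zeros at trial start).
#' @param fixation c(x, y) of the current fixation, in `sal` coordinates.
#' @param t time step (ramp argument); t = 0 gives pure saliency weights.
#' @param temperature softmax temperature.
#' @param sigma_px Gaussian patch sd (default 20 px).
#' @param discount IOR memory discount per step (default 0.25).
#' @return list(probabilities = matrix summing to 1, ior = updated state).
#' @export
iorSaliencyStep <- function(sal, ior, fixation, t, temperature = 0.01,
                            sigma_px = 20, discount = 0.25) {
  if (!identical(dim(sal), dim(ior))) stop("sal and ior dims must match")
  g <- outer((seq_len(nrow(sal)) - fixation[2L])^2,
             (seq_len(ncol(sal)) - fixation[1L])^2, "+")
  g <- exp(-g / (2 * sigma_px^2))
  ior <- clamp(discount * ior + tanh(0.05 * t) * g, 0, 1)
  w <- softmaxProbabilities(as.vector((1 - ior) * sal), temperature)
  list(probabilities = matrix(w, nrow(sal), ncol(sal)), ior = ior)
}

#' Sample a scanpath from the IOR saliency baseline
#'
#' Iterates [iorSaliencyStep()] from a fixed saliency map, sampling each next
#' fixation from the step's probabilities. Fixation durations may be imposed
#' (e.g. matched to an SPRT run); by default each step advances one time
#' unit.
#'
#' @param sal saliency matrix.
#' @param n_fixations number of fixations to generate.
#' @param temperature softmax temperature.
#' @param durations optional per-fixation durations (time units for the
#'   ramp); default all 1.
#' @param start c(x, y) of the first fixation; defaults to the map centre.
#' @param seed optional integer seed.
#' @inheritParams iorSaliencyStep
#' @return data.frame with x, y, t per fixation.
#' @export
sampleIorScanpath <- function(sal, n_fixations, temperature = 0.01,
                              durations = NULL, start = NULL, seed = NULL,
                              sigma_px = 20, discount = 0.25) {
  run <- function() {
    if (is.null(start)) start <- c(ncol(sal) / 2, nrow(sal) / 2)
    if (is.null(durations)) durations <- rep(1, n_fixations)
    ior <- matrix(0, nrow(sal), ncol(sal))
    fix <- start; t <- 0
    out <- data.frame(x = numeric(n_fixations), y = numeric(n_fixations),
                      t = numeric(n_fixations))
    for (k in seq_len(n_fixations)) {
      out[k, ] <- c(fix, t)
      t <- t + durations[k]
      step <- iorSaliencyStep(sal, ior, fix, t, temperature, sigma_px,
                              discount)
      ior <- step$ior
      idx <- sample.int(length(step$probabilities), 1L,
                        prob = as.vector(step$probabilities))
      fix <- c((idx - 1L) %/% nrow(sal) + 1L, (idx - 1L) %% nrow(sal) + 1L)
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
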