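## Synthetic test inputs: flicker image pairs with a known localised change,
## identical catch pairs, two-group human-like gaze logs, and a parametric
## saccade amplitude/turn-angle bias distribution.

# band-limited noise background plus scattered geometric objects, keeping a
# clear zone around the (optional) change location
synth_background <- function(h, w, n_objects = 10L, clear = NULL,
                             clear_radius = 0) {
  img <- array(0, c(h, w, 3))
  base <- EBImage::gblur(matrix(runif(h * w), h, w), sigma = 8)
  for (ch in 1:3) {
    chan <- 0.6 * base + 0.4 * EBImage::gblur(matrix(runif(h * w), h, w),
                                              sigma = 8)
    rng <- range(chan)
    img[, , ch] <- 0.25 + 0.5 * (chan - rng[1L]) / max(rng[2L] - rng[1L],
                                                       1e-12)
  }
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  placed <- 0L; tries <- 0L
  while (placed < n_objects && tries < 20L * n_objects) {
    tries <- tries + 1L
    cx <- runif(1, 20, w - 20); cy <- runif(1, 20, h - 20)
    r <- runif(1, 8, 22)
    if (!is.null(clear) &&
        sqrt((cx - clear[1L])^2 + (cy - clear[2L])^2) < clear_radius + r + 10)
      next
    # saturated colours so the global saliency maximum is set by the
    # background objects, not by the change object
    col <- runif(3)
    col[sample.int(3L, 1L)] <- runif(1, 0.85, 1)
    col[sample.int(3L, 1L)] <- runif(1, 0, 0.15)
    inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    for (ch in 1:3) {
      p <- img[, , ch]; p[inside] <- 0.75 * col[ch] + 0.25 * p[inside]
      img[, , ch] <- p
    }
    placed <- placed + 1L
  }
  clamp(img, 0, 1)
}

# blend a disk of the given colour into the image with weight `alpha`
blend_disk <- function(img, cx, cy, r, col, alpha) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  for (ch in 1:3) {
    p <- img[, , ch]
    p[inside] <- (1 - alpha) * p[inside] + alpha * col[ch]
    img[, , ch] <- p
  }
  img
}

#' Generate a synthetic flicker image pair with a known localised change
#'
#' `A` is a band-limited-noise background with scattered geometric objects
#' and one object at the change location; `A'` is identical except inside
#' the change region, which is modified according to `kind`: `"appearance"`
#' (the object fades toward the background), `"color"` (its colour rotates),
#' or `"size"` (its radius grows). `contrast` in [0, 1] scales the
#' modification; 0 yields a bitwise-identical catch pair. The ground-truth
#' mask marks exactly the altered pixels, and the pair differs nowhere
#' outside it.
#'
#' @param width_px,height_px image size (default the reduced 432 x 324
#'   frame; the full 864 x 648 frame is supported).
#' @param kind change kind: "appearance", "color" or "size".
#' @param center change-region centre c(x, y); default image centre offset.
#' @param radius change-object radius in px.
#' @param contrast change magnitude in [0, 1]; 0 gives a catch pair.
#' @param seed integer seed; generation is deterministic given it.
#' @param n_objects number of additional background objects.
#' @return an \linkS4class{ImagePair} carrying the ground-truth mask.
#' @examples
#' pair <- makeChangePair(seed = 1, contrast = 0.8)
#' pair
#' @export
makeChangePair <- function(width_px = 432L, height_px = 324L,
                           kind = c("appearance", "color", "size"),
                           center = NULL, radius = 18, contrast = 1,
                           seed = 1L, n_objects = 10L) {
  kind <- match.arg(kind)
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  withr::with_seed(seed, {
    if (is.null(center))
      center <- c(runif(1, 0.2, 0.8) * width_px,
                  runif(1, 0.2, 0.8) * height_px)
    if (center[1L] - radius < 1 || center[1L] + radius > width_px ||
        center[2L] - radius < 1 || center[2L] + radius > height_px)
      stop("change region must lie fully inside the image")
    a <- synth_background(height_px, width_px, n_objects, center,
                          2 * radius)
    obj_col <- runif(3)
    obj_col[sample.int(3L, 1L)] <- runif(1, 0.85, 1)
    obj_col[sample.int(3L, 1L)] <- runif(1, 0, 0.15)
    a <- blend_disk(a, center[1L], center[2L], radius, obj_col, 0.75)
    ap <- a
    if (contrast > 0) {
      if (kind == "appearance") {
        bg <- apply(a, 3, median)
        ap <- blend_disk(ap, center[1L], center[2L], radius, bg, contrast)
      } else if (kind == "color") {
        ap <- blend_disk(ap, center[1L], center[2L], radius,
                         obj_col[c(2, 3, 1)], contrast)
      } else {
        ap <- blend_disk(ap, center[1L], center[2L],
                         radius * (1 + 0.6 * contrast), obj_col, 0.9)
      }
    }
    mask <- apply(abs(a - ap), c(1, 2), max) > 0
    if (contrast > 0 && !any(mask))
      warning("contrast too small to alter any pixel")
    new("ImagePair", a = a, a_prime = ap, mask = mask)
  })
}

#' Generate two-group synthetic gaze logs
#'
#' Event streams (fixations and saccades) for two groups of subjects whose
#' distributions differ only in mean fixation duration and
#' saccade-amplitude variance. Fixation durations are log-normal
#' (parameterised by mean and sd in ms); saccade amplitudes are gamma
#' (mean deg, variance deg^2); saccade duration and peak speed follow
#' main-sequence-style monotone maps of amplitude with small multiplicative
#' jitter, so they carry only the variance induced through amplitude.
#'
#' @param n_subjects subjects per group.
#' @param n_trials trials per subject.
#' @param n_fixations fixations per trial.
#' @param groups named list of two group parameter lists with entries
#'   fd_mean, fd_sd (ms), sa_mean, sa_var (deg, deg^2).
#' @param width_px,height_px nominal screen size for fixation coordinates.
#' @param px_per_deg pixels per degree of visual angle.
#' @param seed integer seed.
#' @return a long data.frame of events (see [writeGazeLogs()] for columns),
#'   with an extra `group` column.
#' @export
makeGazeLogs <- function(n_subjects = 8L, n_trials = 10L, n_fixations = 30L,
                         groups = list(
                           good = list(fd_mean = 280, fd_sd = 70,
                                       sa_mean = 5, sa_var = 4),
                           poor = list(fd_mean = 220, fd_sd = 70,
                                       sa_mean = 5, sa_var = 9)),
                         width_px = 1024L, height_px = 768L,
                         px_per_deg = 30, seed = 1L) {
  stopifnot(length(groups) == 2L, !is.null(names(groups)))
  withr::with_seed(seed, {
    rows <- vector("list", 2L * n_subjects * n_trials)
    ri <- 0L
    for (g in names(groups)) {
      gp <- groups[[g]]
      sdlog <- sqrt(log(1 + (gp$fd_sd / gp$fd_mean)^2))
      meanlog <- log(gp$fd_mean) - sdlog^2 / 2
      shape <- gp$sa_mean^2 / gp$sa_var
      scale <- gp$sa_var / gp$sa_mean
      for (s in seq_len(n_subjects)) {
        sid <- sprintf("%s_%02d", g, s)
        for (tr in seq_len(n_trials)) {
          nf <- n_fixations
          fd <- rlnorm(nf, meanlog, sdlog)
          sa <- rgamma(nf - 1L, shape = shape, scale = scale)
          sdur <- 21 + 2.2 * sa + rnorm(nf - 1L, 0, 6)
          sps <- 35 * sa^0.6 * exp(rnorm(nf - 1L, 0, 0.25))
          ang <- runif(nf - 1L, 0, 2 * pi)
          x <- numeric(nf); y <- numeric(nf)
          x[1L] <- width_px / 2; y[1L] <- height_px / 2
          for (k in seq_len(nf - 1L)) {
            x[k + 1L] <- clamp(x[k] + sa[k] * px_per_deg * cos(ang[k]),
                               1, width_px)
            y[k + 1L] <- clamp(y[k] + sa[k] * px_per_deg * sin(ang[k]),
                               1, height_px)
          }
          ev <- data.frame(
            subject_id = sid, trial_id = tr, image_id = tr,
            event_type = c(rep(c("fixation", "saccade"), nf - 1L),
                           "fixation"),
            x_px = NA_real_, y_px = NA_real_, duration_ms = NA_real_,
            amplitude_deg = NA_real_, peak_speed_deg_s = NA_real_,
            outcome = "miss", change_x_px = NA_real_,
            change_y_px = NA_real_, change_r_px = NA_real_,
            group = g)
          fi <- which(ev$event_type == "fixation")
          si <- which(ev$event_type == "saccade")
          ev$x_px[fi] <- x; ev$y_px[fi] <- y; ev$duration_ms[fi] <- fd
          ev$duration_ms[si] <- sdur
          ev$amplitude_deg[si] <- sa
          ev$peak_speed_deg_s[si] <- sps
          ri <- ri + 1L
          rows[[ri]] <- ev
        }
      }
    }
    do.call(rbind, rows[seq_len(ri)])
  })
}

#' Parametric saccade amplitude / turn-angle bias distribution
#'
#' A tabulated polar-grid density whose amplitude marginal decays
#' exponentially (gamma-shaped mass at short amplitudes, strength
#' `short_amplitude_weight`) and whose angle marginal is bimodal at 0 and
#' 180 degrees with a trough near +/-90 (strength `forward_backward_weight`,
#' via 1 + w cos^2 theta). Zero weights give the uniform density.
#'
#' @param short_amplitude_weight,forward_backward_weight non-negative bias
#'   strengths.
#' @param amp_max largest tabulated amplitude (grid units).
#' @param n_amp,n_angle numbers of amplitude / angle bins.
#' @return a \linkS4class{BiasDistribution} (masses summing to 1).
#' @export
makeBiasDistribution <- function(short_amplitude_weight = 1,
                                 forward_backward_weight = 1,
                                 amp_max = 40, n_amp = 20L, n_angle = 24L) {
  if (short_amplitude_weight < 0 || forward_backward_weight < 0)
    stop("bias weights must be >= 0")
  amp_breaks <- seq(0, amp_max, length.out = n_amp + 1L)
  angle_breaks <- seq(-180, 180, length.out = n_angle + 1L)
  amp_mid <- (head(amp_breaks, -1L) + tail(amp_breaks, -1L)) / 2
  ang_mid <- (head(angle_breaks, -1L) + tail(angle_breaks, -1L)) / 2
  amp_d <- exp(-short_amplitude_weight * amp_mid / (amp_max / 8))
  ang_d <- 1 + forward_backward_weight * cos(ang_mid * pi / 180)^2
  den <- outer(amp_d, ang_d)
  new("BiasDistribution", density = den / sum(den),
      amp_breaks = amp_breaks, angle_breaks = angle_breaks)
}
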