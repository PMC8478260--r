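## Trial simulator: full flicker trials under the SPRT model, the three
## matched control models, false-alarm threshold calibration and parameter
## sweeps.

# per-bin stimulus code over the trial: 0 = blank, 1 = image A, 2 = image A'
stimulus_schedule <- function(params) {
  ti <- params@tau_img; tb <- params@tau_blank
  cyc <- c(rep(1L, ti), rep(0L, tb), rep(2L, ti), rep(0L, tb))
  if (!length(cyc)) return(integer(params@trial_bins))
  rep_len(cyc, params@trial_bins)
}

# regions whose pixel block intersects the ground-truth change mask
change_regions <- function(pair, grid) {
  which(region_means(pair@mask + 0, grid) > 0)
}

## The common trial loop. mode: "sprt" (also control 3 via temperature),
## "control1" (instantaneous posterior odds vs calibrated threshold),
## "control2" (one-bin difference of the log posterior odds vs threshold).
## `schedule`: imposed fixation durations in bins (recycled); when given,
## fixations end on schedule instead of at the no-change bound.
simulate_trial <- function(pair, params, seed, bias = NULL, patch_px = 12L,
                           cache = NULL, trace_regions = integer(),
                           mode = "sprt", control_threshold = NA_real_,
                           schedule = NULL) {
  d <- dim(pair@a)
  grid <- partitionGrid(d[2L], d[1L], patch_px)
  N <- nRegions(grid)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  stim <- stimulus_schedule(params)
  es <- c(TRUE, diff(stim) != 0) & stim > 0   # first bin of an image epoch
  hit_set <- change_regions(pair, grid)
  logP <- log(params@prior_odds)
  w <- params@noise_half_width
  trace <- if (length(trace_regions))
    lapply(trace_regions, function(r) numeric(params@trial_bins)) else list()
  names(trace) <- as.character(trace_regions)

  withr::with_seed(seed, {
    f <- regionIndex(grid, max(1L, grid@n_rows %/% 2L),
                     max(1L, grid@n_cols %/% 2L))
    prev <- NULL
    fix_onset <- 1L
    E <- numeric(N)
    rm <- fixationRateMaps(pair, f, grid, params, cache)
    gam <- decayField(f, params@gamma, params@beta_decay, grid)
    X <- numeric(N); Y <- numeric(N); m <- 0L; q <- 0L
    state <- 0L  # 0 idle, 1 first-image, 2 post-first blank, 3 second-image
    sched_i <- 1L
    prev_odds <- NA_real_   # previous evaluated-bin log posterior odds
    max_stat <- -Inf
    scan <- list()
    outcome <- "miss"; detection_bin <- NA_real_; det_region <- NA_integer_

    for (b in seq_len(params@trial_bins)) {
      img <- stim[b]
      evaluated <- FALSE
      stat <- NA_real_
      if (img > 0L) {
        if (es[b]) {
          if (state == 2L || state == 1L) { state <- 3L; Y[] <- 0; q <- 0L }
          else { X[] <- 0; Y[] <- 0; m <- 0L; q <- 0L; state <- 1L }
        } else if (state == 0L) { state <- 1L }
        lam <- if (img == 1L) rm$lam_a else rm$lam_ap
        sp <- rpois(N, lam)
        if (state == 1L) { X <- X + sp; m <- m + 1L }
        else if (state == 3L && m >= 1L) {
          Y <- Y + sp; q <- q + 1L
          z <- Y - X
          lhat <- pmax((X + Y) / (m + q), 1e-6)
          lg <- logLikRatio(z, lhat, params@mu_f, m, q)
          lg_orig <- lg[rm$proj]
          pm <- if (params@prior_scope == "all") 1 else
            as.numeric(seq_len(N) == f)
          ## accumulation noise is drawn per neural population (CVR-space
          ## region) and projected alongside the likelihood, so regions the
          ## current fixation cannot resolve share one noisy evidence stream
          W <- runif(N, -w, w)[rm$proj]
          E <- (1 - gam) * E + lg_orig + logP * pm + W
          evaluated <- TRUE
          if (mode != "sprt") {
            odds <- lg_orig[f] + logP
            stat <- if (mode == "control1") odds else odds - prev_odds
            prev_odds <- odds
            if (is.finite(stat)) max_stat <- max(max_stat, stat)
          }
        }
      } else {
        if (state == 1L) state <- 2L
        else if (state == 3L) {
          X[] <- 0; Y[] <- 0; m <- 0L; q <- 0L; state <- 0L
        }
      }
      if (!evaluated) E <- (1 - gam) * E

      for (r in names(trace)) trace[[r]][b] <- E[as.integer(r)]

      ## change signal
      decided <- FALSE
      if (mode == "sprt") {
        if (params@check_all_regions && any(E >= params@f_c)) {
          det_region <- which.max(E); decided <- TRUE
        } else if (E[f] >= params@f_c) { det_region <- f; decided <- TRUE }
      } else if (is.finite(stat) && stat >= control_threshold) {
        det_region <- f; decided <- TRUE
      }
      if (decided) {
        outcome <- if (det_region %in% hit_set) "hit" else "false_alarm"
        detection_bin <- b
        scan[[length(scan) + 1L]] <- c(f, fix_onset, b - fix_onset + 1L)
        fix_onset <- NA_integer_
        break
      }

      ## fixation termination
      t_fix <- b - fix_onset + 1L
      ended <- if (!is.null(schedule)) {
        t_fix >= schedule[(sched_i - 1L) %% length(schedule) + 1L]
      } else {
        E[f] <= thresholdSchedule(params@f_n, params@zeta, t_fix)
      }
      if (ended && b < params@trial_bins) {
        scan[[length(scan) + 1L]] <- c(f, fix_onset, t_fix)
        sched_i <- sched_i + 1L
        p <- softmaxProbabilities(E, params@temperature)
        if (!is.null(bias)) p <- applySaccadeBias(p, f, prev, bias, grid)
        nxt <- sample.int(N, 1L, prob = p)
        prev <- f; f <- nxt
        fix_onset <- b + 1L
        if (params@reset_on_fixation) E[f] <- 0
        rm <- fixationRateMaps(pair, f, grid, params, cache)
        gam <- decayField(f, params@gamma, params@beta_decay, grid)
        X[] <- 0; Y[] <- 0; m <- 0L; q <- 0L; state <- 0L
        prev_odds <- NA_real_
      }
    }
    if (!is.na(fix_onset))   # trial ended mid-fixation (timeout)
      scan[[length(scan) + 1L]] <-
        c(f, fix_onset, params@trial_bins - fix_onset + 1L)
    sp <- do.call(rbind, scan)
    rc <- regionRowCol(grid, sp[, 1L])
    scanpath <- data.frame(region = sp[, 1L], row = rc[, "row"],
                           col = rc[, "col"], onset_bin = sp[, 2L],
                           duration_bins = sp[, 3L])
    list(outcome = outcome, detection_bin = detection_bin,
         scanpath = scanpath, trace = trace, max_stat = max_stat,
         grid = grid)
  })
}

#' Simulate one flicker change-detection trial
#'
#' Runs the full model loop: per time bin, the stimulus schedule determines
#' the image on screen; Poisson spikes are drawn from the fixation's
#' CVR+saliency rate maps; during second-image bins of each cycle the
#' change/no-change log-likelihood ratio is computed for every region,
#' projected back to original image space and accumulated as leaky noisy
#' evidence; the dual bounds at the fixated region either signal the change
#' (F_c) or terminate the fixation (decaying F_n), in which case the biased
#' clipped-Taylor softmax selects the next fixation and the foveated maps
#' are recomputed there. The trial ends at detection or after `trial_bins`.
#' Fully reproducible from `seed`.
#'
#' @param pair an \linkS4class{ImagePair} (equal-sized images).
#' @param params a \linkS4class{ModelParams}.
#' @param seed integer seed; the entire trial is run under it.
#' @param bias optional \linkS4class{BiasDistribution} imposed on saccades.
#' @param patch_px grid patch size (default 12 px).
#' @param cache optional environment memoising per-fixation rate maps
#'   (reusable across trials of the same pair).
#' @param trace_regions optional region indices whose per-bin evidence is
#'   recorded in the result's `trace` slot.
#' @return a \linkS4class{TrialResult}. A detection in a region intersecting
#'   the ground-truth change mask is a "hit"; any other change signal
#'   (including any signal on a catch pair) is a "false_alarm"; no signal is
#'   a "miss".
#' @export
runTrial <- function(pair, params, seed, bias = NULL, patch_px = 12L,
                     cache = NULL, trace_regions = integer()) {
  validObject(pair); validObject(params)
  res <- simulate_trial(pair, params, seed, bias, patch_px, cache,
                        trace_regions, mode = "sprt")
  new("TrialResult", outcome = res$outcome,
      detection_bin = res$detection_bin, scanpath = res$scanpath,
      seed = as.numeric(seed), trace = res$trace)
}

# emergent gaze statistics of a scanpath: mean fixation duration (bins) and
# saccade-amplitude variance (grid units squared)
scanpath_stats <- function(scanpath) {
  amp <- if (nrow(scanpath) > 1L)
    sqrt(diff(scanpath$col)^2 + diff(scanpath$row)^2) else numeric()
  c(mean_fd_bins = mean(scanpath$duration_bins),
    var_sa_grid = if (length(amp) > 1L) var(amp) else NA_real_)
}

#' Success rate of a set of trials
#'
#' @param results list of \linkS4class{TrialResult} objects.
#' @return named vector: `success` (proportion of hits) and `sem` (binomial
#'   standard error).
#' @export
successRate <- function(results) {
  if (!length(results)) stop("empty result list")
  p <- mean(vapply(results, function(r) r@outcome == "hit", logical(1)))
  c(success = p, sem = sqrt(p * (1 - p) / length(results)))
}

#' Parameter sweep over seeded trials
#'
#' Re-runs the model while one parameter takes each value in `values` and
#' all others stay at their `params` defaults, with trial seeds paired
#' across values. Sweepable parameters: `gamma`, `T` (temperature), `mu_f`,
#' `fmf`, `prior_odds`, `zeta`, and `blank_fraction` (the blank share of a
#' fixed 50-bin image+blank interval). Alongside the success rate, the
#' emergent gaze statistics are recorded: mean fixation duration (bins) and
#' saccade-amplitude variance (grid units squared).
#'
#' @param param one of the names above.
#' @param values numeric vector of parameter values (may be empty).
#' @param pairs list of \linkS4class{ImagePair} objects, cycled over trials.
#' @param params baseline \linkS4class{ModelParams}.
#' @param n_trials seeded trials per value (default 20).
#' @param seed base seed; trial k of every value uses the same derived seed.
#' @param bias optional \linkS4class{BiasDistribution}.
#' @param patch_px grid patch size.
#' @param caches optional list of rate-map cache environments, one per pair,
#'   reusable across sweeps of the same image set.
#' @return data.frame: parameter, value, success, sem, mean_fd_bins,
#'   var_sa_grid, n.
#' @export
runSweep <- function(param, values, pairs, params, n_trials = 20L,
                     seed = 1L, bias = NULL, patch_px = 12L,
                     caches = NULL) {
  known <- c("gamma", "T", "mu_f", "fmf", "prior_odds", "zeta",
             "blank_fraction")
  if (!param %in% known)
    stop(sprintf("unknown sweep parameter '%s'", param))
  if (!length(pairs)) stop("image set must be non-empty")
  out <- data.frame(parameter = character(), value = numeric(),
                    success = numeric(), sem = numeric(),
                    mean_fd_bins = numeric(), var_sa_grid = numeric(),
                    n = integer())
  if (is.null(caches))
    caches <- lapply(pairs, function(p) new.env(parent = emptyenv()))
  for (v in values) {
    pv <- params
    if (param == "gamma") pv@gamma <- v
    else if (param == "T") pv@temperature <- v
    else if (param == "mu_f") pv@mu_f <- v
    else if (param == "fmf") pv@fmf <- v
    else if (param == "prior_odds") pv@prior_odds <- v
    else if (param == "zeta") pv@zeta <- v
    else if (param == "blank_fraction") {
      tb <- as.integer(round(50 * v))
      pv@tau_blank <- tb; pv@tau_img <- 50L - tb
    }
    validObject(pv)
    hits <- logical(n_trials); fd <- numeric(n_trials); sa <- numeric(n_trials)
    for (k in seq_len(n_trials)) {
      pi <- (k - 1L) %% length(pairs) + 1L
      tr_seed <- (as.integer(seed) + 7919L * k + 131L * pi) %% 2147483647L
      res <- runTrial(pairs[[pi]], pv, tr_seed, bias = bias,
                      patch_px = patch_px, cache = caches[[pi]])
      hits[k] <- res@outcome == "hit"
      st <- scanpath_stats(res@scanpath)
      fd[k] <- st["mean_fd_bins"]; sa[k] <- st["var_sa_grid"]
    }
    p <- mean(hits)
    out <- rbind(out, data.frame(
      parameter = param, value = v, success = p,
      sem = sqrt(p * (1 - p) / n_trials),
      mean_fd_bins = mean(fd, na.rm = TRUE),
      var_sa_grid = mean(sa, na.rm = TRUE), n = n_trials))
  }
  out
}

#' Run one of the three control models
#'
#' Control 1 forces gamma = 1 (no memory) and signals change when the
#' instantaneous log posterior odds at the fixated region crosses a
#' calibrated threshold. Control 2 signals change when the one-bin first
#' difference of the log posterior odds at the fixated region crosses a
#' calibrated threshold. Control 3 is the full model with temperature 10^4
#' (a random searcher). All controls follow the fixation-duration schedule
#' of a paired run of the main model with the same seed, so fixation timing
#' is identically matched.
#'
#' @param control_id 1, 2 or 3.
#' @param pair an \linkS4class{ImagePair}.
#' @param params baseline \linkS4class{ModelParams}.
#' @param seed integer seed (shared with the paired main-model run).
#' @param calibrated_threshold required for controls 1 and 2 (see
#'   [calibrateThreshold()]).
#' @param bias optional \linkS4class{BiasDistribution}.
#' @param patch_px grid patch size.
#' @param cache optional rate-map cache.
#' @return a \linkS4class{TrialResult}.
#' @export
runControl <- function(control_id, pair, params, seed,
                       calibrated_threshold = NA_real_, bias = NULL,
                       patch_px = 12L, cache = NULL) {
  if (!control_id %in% 1:3) stop("control_id must be 1, 2 or 3")
  if (control_id %in% 1:2 && is.na(calibrated_threshold))
    stop("controls 1 and 2 require a calibrated threshold")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  main <- simulate_trial(pair, params, seed, bias, patch_px, cache)
  schedule <- main$scanpath$duration_bins
  pv <- params
  mode <- "sprt"
  if (control_id == 1L) { pv@gamma <- 1; mode <- "control1" }
  if (control_id == 2L) mode <- "control2"
  if (control_id == 3L) pv@temperature <- 1e4
  res <- simulate_trial(pair, pv, seed, bias, patch_px, cache,
                        mode = mode, control_threshold = calibrated_threshold,
                        schedule = schedule)
  new("TrialResult", outcome = res$outcome,
      detection_bin = res$detection_bin, scanpath = res$scanpath,
      seed = as.numeric(seed), trace = list(max_stat = res$max_stat))
}

#' Calibrate a control-model detection threshold on catch pairs
#'
#' Runs the control on catch trials (with detection disabled) and returns
#' the smallest threshold whose empirical false-alarm rate does not exceed
#' `max_false_alarm_rate`. The candidate grid is the set of observed
#' per-trial statistic maxima (plus one value above all of them); because
#' the false-alarm rate is non-increasing in the threshold, this grid search
#' is exact.
#'
#' @param control_id 1 or 2.
#' @param catch_pairs list of catch \linkS4class{ImagePair}s.
#' @param max_false_alarm_rate the bound (proportion, e.g. 1e-4).
#' @param params baseline \linkS4class{ModelParams}.
#' @param seeds integer vector, one trial per seed per pair.
#' @param bias,patch_px as in [runControl()].
#' @return the threshold, with the observed maxima as attribute `"maxima"`.
#' @export
calibrateThreshold <- function(control_id, catch_pairs,
                               max_false_alarm_rate, params, seeds,
                               bias = NULL, patch_px = 12L) {
  if (!control_id %in% 1:2) stop("only controls 1 and 2 are calibrated")
  maxima <- numeric()
  for (pair in catch_pairs) {
    cache <- new.env(parent = emptyenv())
    for (s in seeds) {
      main <- simulate_trial(pair, params, s, bias, patch_px, cache)
      pv <- params
      mode <- if (control_id == 1L) "control1" else "control2"
      if (control_id == 1L) pv@gamma <- 1
      res <- simulate_trial(pair, pv, s, bias, patch_px, cache, mode = mode,
                            control_threshold = Inf,
                            schedule = main$scanpath$duration_bins)
      maxima <- c(maxima, res$max_stat)
    }
  }
  if (!length(maxima) || all(!is.finite(maxima)))
    stop("calibration produced no usable catch-trial statistics")
  cand <- sort(c(unique(maxima[is.finite(maxima)]),
                 max(maxima[is.finite(maxima)]) + 1))
  far <- vapply(cand, function(thr) mean(maxima >= thr), numeric(1))
  ok <- which(far <= max_false_alarm_rate)
  if (!length(ok)) stop("false-alarm bound unreachable in the search range; ",
                        "observed rates: ", paste(round(far, 4),
                                                  collapse = ", "))
  thr <- cand[min(ok)]
  attr(thr, "maxima") <- maxima
  thr
}
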