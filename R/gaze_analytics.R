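## Gaze analytics: feature extraction with boxplot outlier removal, feature
## selection scores (Fisher, information gain, AUC change), density-filtered
## fixation clustering with x-means BIC selection, scanpath strings and edit
## distances, saccade probability matrices, fixation maps and
## change-proximity summaries.

#' Boxplot-rule outlier removal
#'
#' Drops values above q3 + w * IQR or below q1 - w * IQR, with quartiles by
#' linear interpolation (type 7). Fewer than 4 values pass through with a
#' warning. w = 1.5 covers ~99.3% of normal data.
#'
#' @param values numeric vector.
#' @param w whisker multiplier.
#' @return the filtered vector.
#' @export
removeOutliers <- function(values, w = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    warning("fewer than 4 values; returning unchanged")
    return(values)
  }
  qs <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2L] - qs[1L]
  values[values >= qs[1L] - w * iqr & values <= qs[2L] + w * iqr]
}

#' Fisher score of a feature for a two-class problem
#'
#' Squared deviations of the two class means from the grand mean, over the
#' sum of the unbiased within-class variances. A zero denominator with
#' separated means signals infinite separation (returns Inf with a warning).
#'
#' @param values numeric feature vector.
#' @param labels two-level class labels (factor, character or logical).
#' @return the Fisher score.
#' @export
fisherScore <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  a <- values[labels == levels(labels)[1L]]
  b <- values[labels == levels(labels)[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each class needs at least 2 samples")
  gm <- mean(values)
  num <- (mean(a) - gm)^2 + (mean(b) - gm)^2
  den <- var(a) + var(b)
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero within-class variance: infinite separation")
    return(Inf)
  }
  num / den
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature for binary labels
#'
#' IG = E(Y) - min over split points (midpoints of adjacent sorted distinct
#' feature values) of the size-weighted entropies of the two sides, in bits.
#' A constant feature has zero gain.
#'
#' @param values numeric feature vector.
#' @param labels two-level class labels.
#' @return information gain in bits.
#' @export
informationGain <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) > 2L) stop("binary labels required")
  ey <- entropy2(table(labels) / length(labels))
  u <- sort(unique(values))
  if (length(u) < 2L) return(0)
  div <- (head(u, -1L) + tail(u, -1L)) / 2
  child <- vapply(div, function(d) {
    hi <- values > d
    (sum(hi) * entropy2(table(labels[hi]) / sum(hi)) +
       sum(!hi) * entropy2(table(labels[!hi]) / sum(!hi))) / length(values)
  }, numeric(1))
  ey - min(child)
}

#' Rank (Mann-Whitney) estimator of the AUC
#'
#' @param scores classifier scores.
#' @param labels two-level labels; the second factor level is "positive".
#' @return the area under the ROC curve.
#' @export
mannWhitneyAUC <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  pos <- labels == levels(labels)[2L]
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Ridge-regularised linear discriminant classifier (default contract)
#'
#' A minimal classifier honouring the pluggable contract of [aucChange()]:
#' given training features and labels it returns scores on held-out rows,
#' via the discriminant direction (S_w + ridge I)^-1 (mu_2 - mu_1).
#'
#' @param train_x,train_y training features (matrix) and two-level labels.
#' @param test_x held-out feature matrix.
#' @param ridge regularisation, as a fraction of the mean pooled variance.
#' @return numeric scores for the rows of `test_x`.
#' @export
ridgeLdaClassifier <- function(train_x, train_y, test_x, ridge = 0.1) {
  train_y <- as.factor(train_y)
  x1 <- train_x[train_y == levels(train_y)[1L], , drop = FALSE]
  x2 <- train_x[train_y == levels(train_y)[2L], , drop = FALSE]
  sw <- (crossprod(scale(x1, scale = FALSE)) +
           crossprod(scale(x2, scale = FALSE))) /
    max(nrow(train_x) - 2L, 1L)
  lam <- ridge * mean(diag(sw)) + 1e-8
  w <- solve(sw + diag(lam, ncol(train_x)), colMeans(x2) - colMeans(x1))
  drop(test_x %*% w)
}

#' Change in cross-validated AUC when one feature is removed
#'
#' Fits the classifier with all features and with feature `feature` removed,
#' under the same seeded cross-validation folds, scoring held-out rows; AUC
#' is the rank estimator. A positive value means the feature carried
#' information the remaining features do not.
#'
#' @param features numeric matrix (rows = samples), >= 2 columns.
#' @param labels two-level labels.
#' @param feature column index (or name) to remove.
#' @param classifier any function(train_x, train_y, test_x) -> scores;
#'   default [ridgeLdaClassifier()].
#' @param folds number of cross-validation folds.
#' @param seed integer seed fixing the fold assignment.
#' @return AUC(all features) - AUC(all minus `feature`).
#' @export
aucChange <- function(features, labels, feature,
                      classifier = ridgeLdaClassifier, folds = 5L,
                      seed = 1L) {
  features <- as.matrix(features)
  if (ncol(features) < 2L) stop("need at least two features")
  labels <- as.factor(labels)
  n <- nrow(features)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_scores <- function(x) {
    s <- numeric(n)
    for (fo in seq_len(folds)) {
      te <- fold == fo
      s[te] <- classifier(x[!te, , drop = FALSE], labels[!te],
                          x[te, , drop = FALSE])
    }
    s
  }
  keep <- setdiff(seq_len(ncol(features)),
                  if (is.character(feature))
                    match(feature, colnames(features)) else feature)
  mannWhitneyAUC(cv_scores(features), labels) -
    mannWhitneyAUC(cv_scores(features[, keep, drop = FALSE]), labels)
}

#' Per-trial gaze feature table
#'
#' Computes the eight summary features (mean and variance of fixation
#' duration, saccade amplitude, saccade duration and saccade peak speed)
#' per subject and trial from an event-stream gaze log. On hit trials the
#' trailing fixations inside the change region (the >= 3 s detection dwell)
#' are stripped first; each metric then passes through the boxplot outlier
#' rule within the trial.
#'
#' @param logs gaze-log data.frame (see [makeGazeLogs()] / [readGazeLogs()]).
#' @param outlier_w whisker multiplier for [removeOutliers()].
#' @return data.frame with subject_id, trial_id, image_id, group (if
#'   present), and mu_fd, var_fd, mu_sa, var_sa, mu_sd, var_sd, mu_sps,
#'   var_sps.
#' @export
computeGazeFeatures <- function(logs, outlier_w = 1.5) {
  key <- interaction(logs$subject_id, logs$trial_id, drop = TRUE)
  out <- lapply(split(logs, key), function(tr) {
    fix <- tr[tr$event_type == "fixation", ]
    sac <- tr[tr$event_type == "saccade", ]
    if (nrow(fix) && !is.na(tr$outcome[1L]) && tr$outcome[1L] == "hit" &&
        is.finite(tr$change_x_px[1L])) {
      d <- sqrt((fix$x_px - tr$change_x_px[1L])^2 +
                  (fix$y_px - tr$change_y_px[1L])^2)
      inreg <- d <= tr$change_r_px[1L]
      drop_n <- 0L
      while (drop_n < nrow(fix) && inreg[nrow(fix) - drop_n]) drop_n <- drop_n + 1L
      if (drop_n > 0L) fix <- fix[seq_len(nrow(fix) - drop_n), , drop = FALSE]
    }
    f <- function(x) suppressWarnings(removeOutliers(x, outlier_w))
    fd <- f(fix$duration_ms); sa <- f(sac$amplitude_deg)
    sd_ <- f(sac$duration_ms); sps <- f(sac$peak_speed_deg_s)
    data.frame(subject_id = tr$subject_id[1L], trial_id = tr$trial_id[1L],
               image_id = tr$image_id[1L],
               group = if ("group" %in% names(tr)) tr$group[1L] else NA,
               mu_fd = mean(fd), var_fd = var(fd),
               mu_sa = mean(sa), var_sa = var(sa),
               mu_sd = mean(sd_), var_sd = var(sd_),
               mu_sps = mean(sps), var_sps = var(sps))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# uniform reference lattice of n points on a width x height frame
uniform_lattice <- function(n, width, height) {
  nx <- max(1L, round(sqrt(n * width / height)))
  ny <- ceiling(n / nx)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  g <- g[seq_len(n), ]
  cbind(x = (g$ix - 0.5) * width / nx, y = (g$iy - 0.5) * height / ny)
}

#' Fixation density relative to a uniform reference
#'
#' rho(x_i) is the inverse mean distance from x_i to the other fixation
#' points within radius r, divided by the same quantity computed at the
#' nearest point of a uniform lattice of equal cardinality. rho < 1 marks
#' points in regions sampled more sparsely than uniform. A point with no
#' neighbours within r has rho = 0; a reference point with no within-r
#' lattice neighbours falls back to its nearest lattice neighbour distance.
#'
#' @param points n x 2 matrix of (x, y) coordinates, n >= 2.
#' @param r neighbourhood radius (same units as the coordinates).
#' @param width_px,height_px frame size (defaults to the coordinate maxima).
#' @return numeric vector of densities.
#' @export
fixationDensity <- function(points, r = 40,
                            width_px = max(points[, 1L]),
                            height_px = max(points[, 2L])) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  U <- uniform_lattice(n, width_px, height_px)
  dU <- as.matrix(dist(U)); diag(dU) <- Inf
  inv_mean_within <- function(drow) {
    nb <- drow[drow <= r]
    if (!length(nb)) NA_real_ else 1 / mean(nb)
  }
  invU <- apply(dU, 1L, inv_mean_within)
  invU[is.na(invU)] <- 1 / apply(dU, 1L, min)[is.na(invU)]
  dX <- as.matrix(dist(points)); diag(dX) <- Inf
  vapply(seq_len(n), function(i) {
    ix <- inv_mean_within(dX[i, ])
    if (is.na(ix)) return(0)
    iu <- invU[which.min(sqrt((U[, 1L] - points[i, 1L])^2 +
                                (U[, 2L] - points[i, 2L])^2))]
    ix / iu
  }, numeric(1))
}

# kmeans++ seeding
kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, 2L)
  centers[1L, ] <- points[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((points - matrix(centers[1L, ], n, 2L, byrow = TRUE))^2)
    for (j in 2:k) {
      pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- points[sample.int(n, 1L, prob = pr), ]
      d2 <- pmin(d2, rowSums((points -
                                matrix(centers[j, ], n, 2L, byrow = TRUE))^2))
    }
  }
  centers
}

# x-means style spherical-Gaussian BIC of a k-means fit
xmeans_bic <- function(fit, n, m = 2L) {
  k <- nrow(fit$centers)
  sig2 <- max(fit$tot.withinss / max(n - k, 1L), 1e-12)
  ll <- sum(fit$size * log(pmax(fit$size, 1) / n)) -
    n * m / 2 * log(2 * pi * sig2) - (n - k) / 2
  p <- (k - 1L) + m * k + 1L
  ll - p / 2 * log(n)
}

# smooth a BIC profile with a bi-exponential (rise-and-decay) fit; falls
# back to a smoothing spline, then to the raw profile
smooth_bic <- function(k, bic) {
  sc <- max(abs(bic))
  y <- bic / sc
  fit <- tryCatch({
    f <- minpack.lm::nlsLM(
      y ~ c0 + A * (exp(-k / t1) - exp(-k / t2)),
      start = list(c0 = max(y), A = -2 * (max(y) - min(y)),
                   t1 = max(k), t2 = max(k) / 5),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    predict(f)
  }, error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(predict(smooth.spline(k, y, df = min(6, length(k) - 1)),
                            k)$y,
                    error = function(e) y)
  fit * sc
}

#' Cluster fixation points with density filtering and BIC-selected k-means
#'
#' Points with fixation density below 1 (sparser than uniform sampling) are
#' grouped into a single "sparse" cluster (label 0). The remaining points
#' are k-means clustered for each candidate k with kmeans++ initialisation
#' (several restarts, best-BIC restart kept) and scored with the x-means
#' spherical-Gaussian BIC; the profile is smoothed with a bi-exponential fit
#' (for candidate ranges of at least 8 values) and the k at the fitted peak
#' is selected. Deterministic given `seed`.
#'
#' @param points n x 2 matrix of fixation coordinates (px).
#' @param r density radius (px); pass `density_floor = -Inf` to skip the
#'   sparse filter.
#' @param k_max largest candidate k (default 50; capped at n - 1).
#' @param n_restarts kmeans++ restarts per k.
#' @param density_floor density threshold for the sparse cluster
#'   (default 1).
#' @param width_px,height_px frame size for the density reference lattice.
#' @param seed integer seed.
#' @return a \linkS4class{ClusterModel}.
#' @export
clusterFixations <- function(points, r = 40, k_max = 50L, n_restarts = 5L,
                             density_floor = 1,
                             width_px = max(points[, 1L]),
                             height_px = max(points[, 2L]), seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  rho <- if (is.finite(density_floor) && density_floor > -Inf && n >= 2L)
    fixationDensity(points, r, width_px, height_px) else rep(Inf, n)
  sparse <- rho < density_floor
  core <- points[!sparse, , drop = FALSE]
  nc <- nrow(core)
  if (nc < 1L) stop("no points left after density filtering")
  withr::with_seed(seed, {
    ks <- seq_len(min(k_max, nc))
    prof <- lapply(ks, function(k) {
      best <- NULL
      for (rst in seq_len(n_restarts)) {
        init <- kmeanspp_init(core, k)
        fit <- tryCatch(suppressWarnings(
          kmeans(core, centers = init, iter.max = 50L)),
          error = function(e) NULL)
        if (is.null(fit)) next
        b <- xmeans_bic(fit, nc)
        if (is.null(best) || b > best$bic) best <- list(fit = fit, bic = b)
      }
      best
    })
    ok <- !vapply(prof, is.null, logical(1))
    ks <- ks[ok]; prof <- prof[ok]
    bic <- vapply(prof, function(p) p$bic, numeric(1))
    sm <- if (length(ks) >= 8L) smooth_bic(ks, bic) else bic
    kb <- which.max(sm)
    fit <- prof[[kb]]$fit
    cl <- integer(n)
    cl[!sparse] <- fit$cluster
    new("ClusterModel", centers = fit$centers, cluster = cl,
        bic = data.frame(k = ks, bic = bic, smoothed = sm),
        k = as.integer(nrow(fit$centers)))
  })
}

cluster_chars <- function() c(letters, LETTERS)

#' Encode a scanpath as a string of cluster labels
#'
#' Each fixation is assigned its nearest cluster centre; fixations that are
#' training points of the model keep their stored assignment (so sparse
#' points keep the sparse label, written as "."). Order is preserved.
#'
#' @param fixations data.frame with x_px, y_px (fixation rows of a gaze
#'   log), or an n x 2 matrix.
#' @param model a \linkS4class{ClusterModel}.
#' @param train_points optional matrix of the points the model was fitted
#'   on, enabling stored-assignment reuse.
#' @return a \linkS4class{ScanString}.
#' @export
encodeScanpath <- function(fixations, model, train_points = NULL) {
  pts <- if (is.data.frame(fixations))
    cbind(fixations$x_px, fixations$y_px) else as.matrix(fixations)
  lab <- vapply(seq_len(nrow(pts)), function(i) {
    if (!is.null(train_points)) {
      hit <- which(abs(train_points[, 1L] - pts[i, 1L]) < 1e-9 &
                     abs(train_points[, 2L] - pts[i, 2L]) < 1e-9)
      if (length(hit)) return(model@cluster[hit[1L]])
    }
    which.min((model@centers[, 1L] - pts[i, 1L])^2 +
                (model@centers[, 2L] - pts[i, 2L])^2)
  }, integer(1))
  chars <- ifelse(lab == 0L, ".", cluster_chars()[pmax(lab, 1L)])
  new("ScanString", labels = lab, string = paste(chars, collapse = ""))
}

#' Normalised Levenshtein distance between two scanpath strings
#'
#' Minimal number of insertions, deletions and substitutions (unit costs,
#' dynamic programming) divided by the longer string's length. Two empty
#' strings have distance 0 by convention.
#'
#' @param s1,s2 \linkS4class{ScanString} objects or character scalars.
#' @return a value in [0, 1].
#' @examples
#' editDistanceNormalized("kitten", "sitting")  # 3/7
#' @export
editDistanceNormalized <- function(s1, s2) {
  a <- if (is(s1, "ScanString")) s1@string else s1
  b <- if (is(s2, "ScanString")) s2@string else s2
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  n <- length(ca); m <- length(cb)
  if (n == 0L && m == 0L) return(0)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1, cur[j] + 1,
                         prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[m + 1L] / max(n, m)
}

# cumulative fixation duration per cluster across labelled scanpaths
cluster_durations <- function(scanpaths) {
  all <- do.call(rbind, scanpaths)
  all <- all[all$label > 0L, , drop = FALSE]
  rowsum(all$duration_ms, all$label)
}

# transition counts between group indices; saccades touching group NA are
# excluded; columns (origins) normalised to 1 where non-empty
transition_matrix <- function(scanpaths, group_of, ngroups) {
  M <- matrix(0, ngroups, ngroups)
  for (sp in scanpaths) {
    g <- group_of[match(sp$label, as.integer(names(group_of)))]
    for (k in seq_len(nrow(sp) - 1L)) {
      from <- g[k]; to <- g[k + 1L]
      if (!is.na(from) && !is.na(to)) M[to, from] <- M[to, from] + 1
    }
  }
  cs <- colSums(M)
  flagged <- cs == 0
  M[, !flagged] <- sweep(M[, !flagged, drop = FALSE], 2L, cs[!flagged], "/")
  attr(M, "empty_domains") <- which(flagged)
  M
}

#' Saccade probability matrix between fixation-duration domains
#'
#' Clusters are ranked by cumulative fixation duration and grouped into four
#' quartile "domains" (domain 1 = most fixated; ties broken by cluster
#' index). Entry (i, j) is the probability that a saccade starting in domain
#' j lands in domain i; columns sum to 1 where the domain has outgoing
#' saccades (empty domains give zero columns, flagged in the
#' `"empty_domains"` attribute). Saccades touching the sparse cluster are
#' excluded.
#'
#' @param scanpaths list of data.frames with columns `label` (cluster index,
#'   0 = sparse) and `duration_ms`, one per trial/subject, in fixation
#'   order.
#' @return a 4 x 4 column-stochastic matrix.
#' @export
saccadeMatrixDomains <- function(scanpaths) {
  dur <- cluster_durations(scanpaths)
  qs <- quantile(dur[, 1L], c(0.75, 0.5, 0.25), type = 7, names = FALSE)
  dom <- 4L - findInterval(dur[, 1L], sort(c(qs)), left.open = FALSE)
  dom <- clamp(dom, 1L, 4L)
  names(dom) <- rownames(dur)
  transition_matrix(scanpaths, dom, 4L)
}

#' Saccade probability matrix among the top-k most-fixated clusters
#'
#' As [saccadeMatrixDomains()], restricted to the `k` clusters with the
#' highest cumulative fixation duration; saccades touching any other
#' cluster are excluded. Rows/columns are in rank order (1 = most fixated).
#'
#' @inheritParams saccadeMatrixDomains
#' @param k number of top clusters (default 10).
#' @return a k x k column-stochastic matrix.
#' @export
saccadeMatrixTopk <- function(scanpaths, k = 10L) {
  dur <- cluster_durations(scanpaths)
  cl <- as.integer(rownames(dur))
  o <- order(-dur[, 1L], cl)
  top <- cl[o][seq_len(min(k, length(cl)))]
  rank_of <- rep(NA_integer_, length(cl))
  rank_of[match(top, cl)] <- seq_along(top)
  names(rank_of) <- rownames(dur)
  transition_matrix(scanpaths, rank_of, length(top))
}

#' Tiled fixation map and its correlation across maps
#'
#' `fixationMap` bins fixations into a tiles[1] x tiles[2] (rows x columns)
#' 2-D histogram; `mapCorrelation` is the Pearson correlation of two maps'
#' vectorised tiles (NA with a warning if either map is constant).
#'
#' @param fixations data.frame with x_px, y_px, or an n x 2 matrix.
#' @param width_px,height_px frame size.
#' @param tiles c(rows, cols), default c(13, 18).
#' @return `fixationMap`: integer matrix of counts (sums to the number of
#'   fixations).
#' @export
fixationMap <- function(fixations, width_px, height_px, tiles = c(13L, 18L)) {
  pts <- if (is.data.frame(fixations))
    cbind(fixations$x_px, fixations$y_px) else as.matrix(fixations)
  if (any(pts[, 1L] < 0 | pts[, 1L] > width_px |
            pts[, 2L] < 0 | pts[, 2L] > height_px))
    stop("coordinates out of bounds")
  r <- clamp(ceiling(pts[, 2L] / height_px * tiles[1L]), 1L, tiles[1L])
  c_ <- clamp(ceiling(pts[, 1L] / width_px * tiles[2L]), 1L, tiles[2L])
  m <- matrix(0L, tiles[1L], tiles[2L])
  for (i in seq_along(r)) m[r[i], c_[i]] <- m[r[i], c_[i]] + 1L
  m
}

#' @rdname fixationMap
#' @param mapA,mapB two fixation maps of identical dimensions.
#' @export
mapCorrelation <- function(mapA, mapB) {
  if (!identical(dim(mapA), dim(mapB))) stop("map dimensions differ")
  if (sd(mapA) == 0 || sd(mapB) == 0) {
    warning("constant map: correlation undefined")
    return(NA_real_)
  }
  cor(as.vector(mapA), as.vector(mapB))
}

#' Fixation counts and durations in annuli around the change location
#'
#' Fixations are binned by distance to the change centre in concentric
#' annuli of width `bin_px` (annulus 1 covers [0, bin_px)). Counts sum to
#' the number of fixations; proportions normalise counts and durations
#' within the trial/image.
#'
#' @param fixations data.frame with x_px, y_px, duration_ms.
#' @param center change-region centre c(x, y), px.
#' @param bin_px annulus width (default 50 px).
#' @return data.frame: annulus, r_lo, r_hi, count, duration_ms, count_prop,
#'   duration_prop.
#' @export
changeProximityProfile <- function(fixations, center, bin_px = 50) {
  d <- sqrt((fixations$x_px - center[1L])^2 +
              (fixations$y_px - center[2L])^2)
  ann <- floor(d / bin_px) + 1L
  k <- max(ann)
  cnt <- tabulate(ann, k)
  dur <- numeric(k)
  agg <- rowsum(fixations$duration_ms, ann)
  dur[as.integer(rownames(agg))] <- agg
  data.frame(annulus = seq_len(k), r_lo = (seq_len(k) - 1L) * bin_px,
             r_hi = seq_len(k) * bin_px, count = cnt, duration_ms = dur,
             count_prop = cnt / sum(cnt), duration_prop = dur / sum(dur))
}

#' Latency metrics relative to the change region
#'
#' Times are measured from trial start by accumulating event durations in
#' stream order. Time to first fixation is the onset of the first fixation
#' whose centre falls within `radius` of the change centre; time to detect
#' is the onset of the final fixation on hit trials (the start of the
#' detection dwell). Both are NA, with a flag, when undefined.
#'
#' @param trial_log event rows of one trial (fixations and saccades, in
#'   order), with duration_ms and outcome columns.
#' @param center change centre c(x, y), px.
#' @param radius change-region radius, px.
#' @return list(time_to_first_s, time_to_detect_s, ever_in_region).
#' @export
latencyMetrics <- function(trial_log, center, radius) {
  onset <- cumsum(c(0, head(trial_log$duration_ms, -1L))) / 1000
  fix <- trial_log$event_type == "fixation"
  d <- sqrt((trial_log$x_px - center[1L])^2 +
              (trial_log$y_px - center[2L])^2)
  inreg <- fix & !is.na(d) & d <= radius
  t_first <- if (any(inreg)) onset[which(inreg)[1L]] else NA_real_
  hit <- !is.na(trial_log$outcome[1L]) && trial_log$outcome[1L] == "hit"
  t_detect <- if (hit && any(fix)) onset[max(which(fix))] else NA_real_
  list(time_to_first_s = t_first, time_to_detect_s = t_detect,
       ever_in_region = any(inreg))
}

#' Split a gaze log into labelled scanpaths
#'
#' Convenience builder for the saccade-matrix functions: splits an event
#' log by subject and trial, keeps fixation rows in order, and attaches the
#' cluster label of each fixation under `model`.
#'
#' @param logs gaze-log data.frame.
#' @param model a \linkS4class{ClusterModel}.
#' @param train_points optional training-point matrix (see
#'   [encodeScanpath()]).
#' @return list of data.frames with columns label and duration_ms.
#' @export
labeledScanpaths <- function(logs, model, train_points = NULL) {
  key <- interaction(logs$subject_id, logs$trial_id, drop = TRUE)
  lapply(split(logs, key), function(tr) {
    fix <- tr[tr$event_type == "fixation", ]
    ss <- encodeScanpath(fix, model, train_points)
    data.frame(label = ss@labels, duration_ms = fix$duration_ms)
  })
}
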