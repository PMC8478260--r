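test_that("boxplot outlier rule drops exactly the out-of-whisker values", {
  expect_equal(removeOutliers(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))
  # direct quartile computation: q1 = 2, q3 = 4 -> upper fence 2 + 1.5 * 97
  x <- c(1, 2, 3, 4, 100)
  qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  expect_true(100 > qs[2] + 1.5 * diff(qs))
  expect_equal(removeOutliers(x), c(1, 2, 3, 4))
  expect_equal(removeOutliers(rep(7, 10)), rep(7, 10))
  expect_warning(removeOutliers(c(1, 2)), "fewer")
})

test_that("Fisher score matches hand arithmetic and degenerates sensibly", {
  # classes {1,2,3} vs {4,5,6}: grand mean 3.5, class means 2 and 5,
  # within-class variances 1 each -> (2.25 + 2.25) / 2 = 2.25
  expect_equal(fisherScore(c(1, 2, 3, 4, 5, 6),
                           rep(c("a", "b"), each = 3)), 2.25)
  # identical class distributions: class means equal the grand mean
  expect_equal(fisherScore(rep(c(1, 2), 4), rep(c("a", "b"), each = 4)), 0)
  # score grows as jitter shrinks
  set.seed(3)
  sc <- vapply(c(1, 0.3, 0.1), function(s) {
    fisherScore(c(rnorm(30, 0, s), rnorm(30, 1, s)),
                rep(c("a", "b"), each = 30))
  }, numeric(1))
  expect_true(all(diff(sc) > 0))
  expect_warning(f <- fisherScore(c(0, 0, 1, 1), c("a", "a", "b", "b")),
                 "infinite")
  expect_identical(f, Inf)
})

test_that("information gain matches the exhaustive split-point oracle", {
  # feature (1,2,3,4), labels (0,0,1,1): perfect split at 2.5 -> 1 bit
  expect_equal(informationGain(1:4, c(0, 0, 1, 1)), 1)
  expect_equal(informationGain(rep(2, 6), rep(c(0, 1), 3)), 0)
  # exhaustive oracle on random data
  set.seed(5)
  x <- rnorm(24); y <- rep(c(0, 1), 12)
  ent <- function(l) { p <- table(l) / length(l); p <- p[p > 0]
                       -sum(p * log2(p)) }
  u <- sort(unique(x)); best <- Inf
  for (d in (head(u, -1) + tail(u, -1)) / 2) {
    hi <- x > d
    best <- min(best, (sum(hi) * ent(y[hi]) + sum(!hi) * ent(y[!hi])) /
                  length(x))
  }
  expect_equal(informationGain(x, y), ent(y) - best)
})

test_that("rank AUC and the drop-one-feature AUC change behave per contract", {
  set.seed(9)
  # random scores: AUC near 1/2 within binomial tolerance
  a <- mannWhitneyAUC(runif(400), rep(c("a", "b"), 200))
  expect_lt(abs(a - 0.5), 3 * sqrt(1 / 12 * (1 / 200 + 1 / 200)))
  # perfectly separated scores
  expect_equal(mannWhitneyAUC(c(1, 2, 3, 7, 8, 9),
                              rep(c("a", "b"), each = 3)), 1)
  # synthetic two-class table: one informative feature among noise
  n <- 120
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(info = c(rnorm(n / 2, 0), rnorm(n / 2, 1.5)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  expect_gt(aucChange(X, y, "info", seed = 2), 0.1)
  # removing a duplicated feature changes nothing appreciable
  X2 <- cbind(X, dup = X[, "info"] + rnorm(n, 0, 1e-6))
  expect_lt(abs(aucChange(X2, y, "dup", seed = 2)), 0.08)
  expect_error(aucChange(X[, 1, drop = FALSE], y, 1), "two features")
})

test_that("fixation density compares against the uniform lattice reference", {
  # points placed exactly on the lattice have density 1
  U <- gazeSPRT:::uniform_lattice(48, 400, 300)
  rho <- fixationDensity(U, r = 80, width_px = 400, height_px = 300)
  expect_equal(rho, rep(1, 48))
  # a tight cluster has density > 1; an isolated point < 1
  set.seed(2)
  pts <- rbind(cbind(runif(19, 195, 205), runif(19, 145, 155)),
               c(30, 30))
  rho2 <- fixationDensity(pts, r = 40, width_px = 400, height_px = 300)
  expect_true(all(rho2[1:19] > 1))
  expect_lt(rho2[20], 1)
  # scale invariance: scaling coordinates, radius and frame together
  rho3 <- fixationDensity(pts * 3, r = 120, width_px = 1200,
                          height_px = 900)
  expect_equal(rho3, rho2, tolerance = 1e-10)
  expect_error(fixationDensity(matrix(1, 1, 2)), "at least 2")
})

test_that("BIC-selected clustering recovers planted structure deterministically", {
  set.seed(4)
  blob <- function(cx, cy, n, s) cbind(rnorm(n, cx, s), rnorm(n, cy, s))
  # two well-separated tight blobs -> k = 2 (BIC oracle over k in 1..5)
  pts <- rbind(blob(100, 100, 40, 3), blob(320, 240, 40, 3))
  cm <- clusterFixations(pts, k_max = 5, density_floor = -Inf, seed = 7,
                         width_px = 400, height_px = 300)
  expect_equal(cm@k, 2L)
  expect_equal(max(cm@bic$bic), cm@bic$bic[cm@bic$k == 2])
  # all points coincident -> k = 1
  cm1 <- clusterFixations(matrix(rep(c(50, 60), each = 30), 30),
                          k_max = 4, density_floor = -Inf, seed = 7,
                          width_px = 100, height_px = 100)
  expect_equal(cm1@k, 1L)
  # determinism
  cm2 <- clusterFixations(pts, k_max = 5, density_floor = -Inf, seed = 7,
                          width_px = 400, height_px = 300)
  expect_identical(cm@centers, cm2@centers)
  expect_identical(cm@cluster, cm2@cluster)
  # low-density points go to the sparse cluster (label 0)
  pts3 <- rbind(blob(100, 100, 60, 4), blob(320, 240, 60, 4), c(15, 290))
  cm3 <- clusterFixations(pts3, r = 60, k_max = 5, seed = 7,
                          width_px = 400, height_px = 300)
  expect_equal(cm3@cluster[121], 0L)
})

test_that("scanpath encoding assigns nearest centres and keeps order", {
  cm <- new("ClusterModel",
            centers = rbind(c(10, 10), c(100, 10)),
            cluster = c(1L, 2L), bic = data.frame(), k = 2L)
  fix <- data.frame(x_px = c(12, 98, 8, 102), y_px = c(11, 12, 9, 8))
  ss <- encodeScanpath(fix, cm)
  expect_equal(ss@labels, c(1L, 2L, 1L, 2L))
  expect_equal(ss@string, "abab")
  expect_equal(encodeScanpath(fix[1, ], cm)@string, "a")
  # exhaustive nearest-centre oracle on random points
  set.seed(6)
  rpts <- cbind(runif(40, 0, 120), runif(40, 0, 20))
  lab <- encodeScanpath(rpts, cm)@labels
  oracle <- apply(rpts, 1, function(p)
    which.min((cm@centers[, 1] - p[1])^2 + (cm@centers[, 2] - p[2])^2))
  expect_equal(lab, as.integer(oracle))
  # training points reuse their stored (possibly sparse) assignment
  tp <- rbind(c(10, 10), c(55, 15))
  cm2 <- new("ClusterModel", centers = rbind(c(10, 10), c(100, 10)),
             cluster = c(1L, 0L), bic = data.frame(), k = 2L)
  ss2 <- encodeScanpath(tp, cm2, train_points = tp)
  expect_equal(ss2@labels, c(1L, 0L))
  expect_equal(ss2@string, "a.")
})

test_that("normalised edit distance matches oracles and the metric axioms", {
  expect_equal(editDistanceNormalized("abc", "abc"), 0)
  expect_equal(editDistanceNormalized("abc", ""), 1)
  expect_equal(editDistanceNormalized("", ""), 0)
  expect_equal(editDistanceNormalized("kitten", "sitting"), 3 / 7)
  # DP equals exhaustive edit-script search for all short strings
  set.seed(12)
  alphabet <- c("a", "b", "c")
  rs <- function() paste(sample(alphabet, sample(0:6, 1), TRUE),
                         collapse = "")
  strs <- replicate(40, rs())
  for (i in seq(1, 39, by = 2)) {
    a <- strs[i]; b <- strs[i + 1]
    d_raw <- editDistanceNormalized(a, b) * max(nchar(a), nchar(b), 1)
    expect_equal(d_raw, oracle_edit(a, b), label = paste(a, b))
    # cross-check against the generalised distance in utils::adist
    expect_equal(d_raw, as.numeric(utils::adist(a, b)))
  }
  # metric axioms on random triples
  for (i in 1:25) {
    a <- rs(); b <- rs(); cc <- rs()
    dab <- editDistanceNormalized(a, b)
    expect_equal(dab, editDistanceNormalized(b, a))
    expect_equal(editDistanceNormalized(a, a), 0)
    raw <- function(x, y) editDistanceNormalized(x, y) *
      max(nchar(x), nchar(y), 1)
    expect_lte(raw(a, cc), raw(a, b) + raw(b, cc))
  }
})

test_that("saccade matrices are column-stochastic with correct domain structure", {
  # path confined to one cluster -> diagonal entry 1 in its domain
  sp1 <- list(data.frame(label = rep(1L, 6), duration_ms = rep(200, 6)))
  M1 <- saccadeMatrixDomains(sp1)
  expect_equal(M1[1, 1], 1)
  expect_equal(dim(M1), c(4L, 4L))
  # alternating two-cluster path with unequal durations: off-diagonals 1
  sp2 <- list(data.frame(label = rep(c(1L, 2L), 8),
                         duration_ms = rep(c(900, 100), 8)))
  M2 <- saccadeMatrixDomains(sp2)
  expect_equal(M2[4, 1], 1)   # leaving the most-fixated domain
  expect_equal(M2[1, 4], 1)
  # column sums are 1 wherever a domain has outgoing saccades
  set.seed(8)
  sp3 <- lapply(1:5, function(i)
    data.frame(label = sample(1:12, 30, TRUE),
               duration_ms = runif(30, 50, 400)))
  M3 <- saccadeMatrixDomains(sp3)
  cs <- colSums(M3)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
  # top-k restriction: k = 1 gives the 1 x 1 matrix [1]
  expect_equal(saccadeMatrixTopk(sp1, k = 1), matrix(1, 1, 1),
               ignore_attr = TRUE)
  Mk <- saccadeMatrixTopk(sp3, k = 5)
  expect_equal(dim(Mk), c(5L, 5L))
  csk <- colSums(Mk)
  expect_true(all(abs(csk[csk > 0] - 1) < 1e-12))
})

test_that("split halves of a long stationary random path give similar top-k matrices", {
  set.seed(14)
  mk <- function() lapply(1:40, function(i)
    data.frame(label = sample(1:10, 60, TRUE,
                              prob = (10:1) / 55),
               duration_ms = rep(100, 60)))
  Ma <- saccadeMatrixTopk(mk(), k = 6)
  Mb <- saccadeMatrixTopk(mk(), k = 6)
  expect_gt(cor(as.vector(Ma), as.vector(Mb)), 0.5)
})

test_that("fixation maps conserve counts and correlate per contract", {
  set.seed(10)
  fix <- data.frame(x_px = runif(200, 0, 540), y_px = runif(200, 0, 390))
  fm <- fixationMap(fix, 540, 390)
  expect_equal(dim(fm), c(13L, 18L))
  expect_equal(sum(fm), 200)
  expect_equal(mapCorrelation(fm, fm), 1)
  # independent uniform-random maps decorrelate
  rs <- replicate(60, {
    f1 <- fixationMap(data.frame(x_px = runif(300, 0, 540),
                                 y_px = runif(300, 0, 390)), 540, 390)
    f2 <- fixationMap(data.frame(x_px = runif(300, 0, 540),
                                 y_px = runif(300, 0, 390)), 540, 390)
    mapCorrelation(f1, f2)
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(60) + 0.02)
  expect_warning(r <- mapCorrelation(fm * 0, fm), "constant")
  expect_true(is.na(r))
  expect_error(fixationMap(data.frame(x_px = 600, y_px = 10), 540, 390),
               "bounds")
})

test_that("change-proximity annuli bin exactly by floor(d / 50)", {
  fix <- data.frame(x_px = c(500, 530, 420, 500, 260),
                    y_px = rep(300, 5),
                    duration_ms = c(100, 200, 300, 400, 500))
  # distances from (500, 300): 0, 30, 80, 0, 240 -> annuli 1, 1, 2, 1, 5
  pr <- changeProximityProfile(fix, c(500, 300), 50)
  expect_equal(pr$count, c(3, 1, 0, 0, 1))
  expect_equal(sum(pr$count), 5)
  expect_equal(pr$duration_ms[1], 700)
  expect_equal(sum(pr$duration_prop), 1)
  # all fixations at the centre: all mass in annulus 1
  pr2 <- changeProximityProfile(data.frame(x_px = rep(10, 4),
                                           y_px = rep(10, 4),
                                           duration_ms = rep(50, 4)),
                                c(10, 10))
  expect_equal(pr2$count_prop[1], 1)
})

test_that("latency metrics accumulate event durations from trial start", {
  tl <- data.frame(event_type = c("fixation", "saccade", "fixation",
                                  "saccade", "fixation"),
                   x_px = c(10, NA, 300, NA, 305),
                   y_px = c(10, NA, 300, NA, 302),
                   duration_ms = c(1000, 50, 500, 50, 3200),
                   outcome = "hit")
  lm <- latencyMetrics(tl, c(302, 301), radius = 20)
  expect_equal(lm$time_to_first_s, 1.05)   # onset of the second fixation
  expect_equal(lm$time_to_detect_s, 1.6)   # onset of the final dwell
  expect_true(lm$ever_in_region)
  lm2 <- latencyMetrics(tl, c(10000, 10000), radius = 5)
  expect_true(is.na(lm2$time_to_first_s))
  expect_false(lm2$ever_in_region)
})

test_that("feature extraction strips the detection dwell and applies the outlier rule", {
  logs <- makeGazeLogs(n_subjects = 2, n_trials = 2, n_fixations = 20,
                       seed = 3)
  ft <- computeGazeFeatures(logs)
  expect_equal(nrow(ft), 8L)
  expect_true(all(is.finite(ft$mu_fd)))
  expect_true(all(c("mu_fd", "var_fd", "mu_sa", "var_sa", "mu_sd",
                    "var_sd", "mu_sps", "var_sps") %in% names(ft)))
  # plant a huge trailing dwell at the change location on a hit trial
  one <- logs[logs$subject_id == logs$subject_id[1] & logs$trial_id == 1, ]
  one$outcome <- "hit"
  one$change_x_px <- one$x_px[max(which(one$event_type == "fixation"))]
  one$change_y_px <- one$y_px[max(which(one$event_type == "fixation"))]
  one$change_r_px <- 5
  last_fix <- max(which(one$event_type == "fixation"))
  one$duration_ms[last_fix] <- 60000
  ft1 <- computeGazeFeatures(one)
  # the dwell is removed, so the trial mean stays in a plausible range
  expect_lt(ft1$mu_fd, 2000)
})
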