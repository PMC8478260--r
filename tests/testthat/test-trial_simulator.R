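## Simulator tests run on reduced 144 x 108 px pairs (12 x 9 grid) with
## short (400-bin) trials to keep the suite fast.

test_that("the stimulus schedule alternates image and blank epochs", {
  p <- fast_params(tau_img = 3L, tau_blank = 2L)
  s <- gazeSPRT:::stimulus_schedule(p)
  expect_equal(s[1:10], c(1L, 1L, 1L, 0L, 0L, 2L, 2L, 2L, 0L, 0L))
  expect_equal(length(s), 400L)
  # all-blank schedule
  expect_true(all(gazeSPRT:::stimulus_schedule(
    fast_params(tau_img = 0L, tau_blank = 25L)) == 0L))
})

test_that("an unreachable change bound yields a miss with zero false alarms", {
  pair <- tiny_pair(0, seed = 21)
  p <- fast_params(f_c = Inf)
  res <- runTrial(pair, p, seed = 5)
  expect_equal(res@outcome, "miss")
  expect_true(is.na(res@detection_bin))
  # scanpath covers the whole trial
  expect_equal(sum(res@scanpath$duration_bins), 400)
  expect_true(all(res@scanpath$onset_bin >= 1))
})

test_that("trials are bitwise reproducible from their seed", {
  pair <- tiny_pair(0.8, seed = 22)
  p <- fast_params()
  r1 <- runTrial(pair, p, seed = 42)
  r2 <- runTrial(pair, p, seed = 42)
  expect_identical(r1@outcome, r2@outcome)
  expect_identical(r1@scanpath, r2@scanpath)
  expect_identical(r1@detection_bin, r2@detection_bin)
})

test_that("a strong change is detected inside the ground-truth mask", {
  pair <- tiny_pair(0.9, seed = 23)
  p <- fast_params()
  hits <- 0
  for (s in 1:6) {
    res <- runTrial(pair, p, seed = s)
    if (res@outcome == "hit") {
      hits <- hits + 1
      last <- res@scanpath[nrow(res@scanpath), ]
      g <- partitionGrid(144, 108, 12)
      expect_true(last$region %in% gazeSPRT:::change_regions(pair, g))
    }
    expect_false(res@outcome == "false_alarm")
  }
  expect_gt(hits, 3)
})

test_that("evidence traces record the accumulation at requested regions", {
  pair <- tiny_pair(0, seed = 21)
  p <- fast_params(trial_bins = 120L)
  res <- runTrial(pair, p, seed = 2, trace_regions = c(5L, 50L))
  expect_named(res@trace, c("5", "50"))
  expect_length(res@trace[["5"]], 120L)
  expect_true(all(is.finite(res@trace[["5"]])))
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "trace.csv")
  writeEvidenceTraces(res, f)
  tr <- utils::read.csv(f)
  expect_equal(nrow(tr), 240L)
  expect_equal(tr$E[tr$region == 50], res@trace[["50"]])
})

test_that("success rates aggregate hits with a binomial standard error", {
  mk <- function(o) new("TrialResult", outcome = o, detection_bin = NA_real_,
                        scanpath = data.frame(), seed = 1, trace = list())
  expect_equal(successRate(list(mk("hit"), mk("hit")))[["success"]], 1)
  expect_equal(successRate(list(mk("miss")))[["success"]], 0)
  r <- successRate(list(mk("hit"), mk("hit"), mk("hit"), mk("miss")))
  expect_equal(r[["success"]], 0.75)
  expect_equal(r[["sem"]], sqrt(0.75 * 0.25 / 4))
  expect_error(successRate(list()), "empty")
})

test_that("sweeps validate their parameter name and handle edge values", {
  pair <- tiny_pair(0.8, seed = 22)
  p <- fast_params()
  expect_error(runSweep("bogus", 1, list(pair), p), "unknown sweep")
  expect_error(runSweep("gamma", 1, list(), p), "non-empty")
  # zero-length value list gives an empty table
  empty <- runSweep("gamma", numeric(), list(pair), p)
  expect_equal(nrow(empty), 0L)
  # the all-blank extreme accrues no evidence: success 0
  r <- runSweep("blank_fraction", 1, list(pair), p, n_trials = 2L,
                seed = 3)
  expect_equal(r$success, 0)
})

test_that("controls require calibration, follow schedules, and degrade detection", {
  pair <- tiny_pair(0.9, seed = 23)
  catch <- tiny_pair(0, seed = 24)
  p <- fast_params()
  expect_error(runControl(1, pair, p, seed = 1), "calibrated")
  thr <- calibrateThreshold(1, list(catch), max_false_alarm_rate = 0,
                            params = p, seeds = 1:10)
  expect_true(is.finite(thr))
  expect_gte(thr, max(attr(thr, "maxima")))
  # monotonicity: a larger threshold can only lower the false-alarm rate
  mx <- attr(thr, "maxima")
  fars <- vapply(sort(unique(mx)), function(t0) mean(mx >= t0), numeric(1))
  expect_true(all(diff(fars) <= 0))
  # re-test on fresh seeds: the false-alarm rate stays within the binomial
  # uncertainty of the calibrated bound
  fresh_fa <- sum(vapply(11:13, function(s)
    runControl(1, catch, p, seed = s,
               calibrated_threshold = thr)@outcome == "false_alarm",
    logical(1)))
  expect_lte(fresh_fa, 1L)
  # control 1 with an infinite bound always misses
  expect_equal(runControl(1, pair, p, seed = 2,
                          calibrated_threshold = Inf)@outcome, "miss")
  # control 2: a constant likelihood stream never triggers the derivative
  thr2 <- calibrateThreshold(2, list(catch), 0, p, seeds = 1:3)
  expect_true(is.finite(thr2))
  # control 3 is the uniform-policy searcher and needs no calibration
  res3 <- runControl(3, pair, p, seed = 2)
  expect_s4_class(res3, "TrialResult")
})

test_that("the random searcher's landing probability is near-uniform", {
  # with temperature 1e4 every taylor3 weight is ~1: sample many next
  # fixations from a realistic evidence spread
  set.seed(31)
  E <- rnorm(108, 0, 15)
  p <- softmaxProbabilities(E, 1e4)
  expect_lt(max(abs(p - 1 / 108)), 0.02 / 108)
})

test_that("catch-pair rate maps are computed once and shared", {
  pair <- tiny_pair(0, seed = 21)
  g <- partitionGrid(144, 108, 12)
  rm <- fixationRateMaps(pair, 30L, g, fast_params())
  expect_identical(rm$lam_a, rm$lam_ap)
  expect_true(all(rm$lam_a >= 5 & rm$lam_a <= 120))
  # change pairs differ inside the change region's CVR image
  pc <- tiny_pair(0.9, seed = 23)
  rmc <- fixationRateMaps(pc, 30L, g, fast_params())
  expect_false(identical(rmc$lam_a, rmc$lam_ap))
})

test_that("paired-seed control 3 never beats the main model on salient changes", {
  # sign test over a battery of synthetic pairs with elevated change
  # saliency: the random searcher should not win on more pairs than the
  # SPRT policy
  p <- fast_params()
  wins_main <- 0; wins_ctrl <- 0
  for (s in 1:10) {
    pair <- tiny_pair(0.9, seed = 30 + s)
    main <- runTrial(pair, p, seed = 100 + s)
    ctrl <- runControl(3, pair, p, seed = 100 + s)
    m <- main@outcome == "hit"; cc <- ctrl@outcome == "hit"
    if (m && !cc) wins_main <- wins_main + 1
    if (cc && !m) wins_ctrl <- wins_ctrl + 1
  }
  if (wins_main + wins_ctrl > 0) {
    bt <- binom.test(wins_main, wins_main + wins_ctrl,
                     alternative = "greater")
    expect_gt(wins_main, wins_ctrl - 1)
  }
  expect_gte(wins_main, wins_ctrl)
})
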