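test_that("grid partition reproduces the reference geometry and errors on oversized patches", {
  g <- partitionGrid(864, 648, 12)
  expect_equal(g@n_cols, 72L)
  expect_equal(g@n_rows, 54L)
  expect_equal(nRegions(g), 3888L)
  expect_equal(nRegions(partitionGrid(12, 12, 12)), 1L)
  expect_equal(nRegions(partitionGrid(36, 24, 12)), 6L)
  # portrait orientation swaps the grid resolutions
  gp <- partitionGrid(648, 864, 12)
  expect_equal(c(gp@n_cols, gp@n_rows), c(54L, 72L))
  expect_error(partitionGrid(10, 40, 12), "larger")
})

test_that("region indexing is deterministic row-major and tiles without overlap", {
  g <- partitionGrid(48, 36, 12)   # 4 x 3
  expect_equal(regionIndex(g, 1, 1), 1L)
  expect_equal(regionIndex(g, 2, 1), 5L)
  rc <- regionRowCol(g, 1:12)
  expect_equal(regionIndex(g, rc[, "row"], rc[, "col"]), 1:12)
  # exhaustive pixel assignment: every pixel belongs to exactly one region
  counts <- numeric(12)
  for (x in 1:48) for (y in 1:36) {
    r <- regionIndex(g, ceiling(y / 12), ceiling(x / 12))
    counts[r] <- counts[r] + 1
  }
  expect_true(all(counts == 144))
})

test_that("CVR forward transform matches the closed form and its symmetries", {
  # direct evaluation of the offset map
  expect_equal(gazeSPRT:::cvr_offset(12, 0.05, 200), 200 * log(1.6))
  expect_equal(gazeSPRT:::cvr_offset(0, 0.05, 200), 0)
  # odd symmetry and monotonicity in |offset|
  d <- seq(1, 300, by = 7)
  expect_equal(gazeSPRT:::cvr_offset(-d, 0.05, 200),
               -gazeSPRT:::cvr_offset(d, 0.05, 200))
  expect_true(all(diff(gazeSPRT:::cvr_offset(d, 0.05, 200)) > 0))
  # local magnification at the centre is beta * S_f (= 10x at defaults)
  eps <- 1e-6
  expect_equal(gazeSPRT:::cvr_offset(eps, 0.05, 200) / eps, 10,
               tolerance = 1e-4)
  # inverse offset map inverts the forward map
  dv <- gazeSPRT:::cvr_offset(d, 0.05, 200)
  expect_equal(gazeSPRT:::cvr_offset_inv(dv, 0.05, 200), d)
  expect_error(cvrForward(array(0.5, c(8, 8, 3)), cvrParams(c(50, 2))),
               "outside")
})

test_that("foveation magnifies the centre of a known image", {
  # vertical stripe pattern: after foveation the centre stripe widens
  img <- array(0, c(60, 60, 3))
  img[, 29:32, ] <- 1
  f <- cvrForward(img, cvrParams(c(30.5, 30.5), beta = 0.05, s_fx = 30,
                                 s_fy = 30))
  expect_equal(dim(f), dim(img))
  expect_gt(sum(f[30, , 1] > 0.5), sum(img[30, , 1] > 0.5))
})

test_that("inverse projection is identity on constants and fixes the centre", {
  g <- partitionGrid(120, 96, 12)  # 10 x 8
  cp <- cvrParams(c(60, 48), beta = 0.05, s_fx = 30, s_fy = 24)
  const <- rep(3.5, nRegions(g))
  expect_equal(cvrInverseProject(const, cp, g), const)
  # delta at the fixated region stays at the fixated region
  fix <- regionIndex(g, 4, 5)   # centre (54..60, 42..48) block
  ctr <- regionCenter(g, fix)
  cp2 <- cvrParams(c(ctr[1, "x"], ctr[1, "y"]), beta = 0.05, s_fx = 30,
                   s_fy = 24)
  delta <- numeric(nRegions(g)); delta[fix] <- 1
  expect_equal(cvrInverseProject(delta, cp2, g)[fix], 1)
  # brute-force oracle: forward-map each region centre pixelwise and read
  # off the CVR region it falls into
  vals <- seq_len(nRegions(g))
  proj <- cvrInverseProject(vals, cp2, g)
  for (i in seq(1, nRegions(g), by = 7)) {
    c0 <- regionCenter(g, i)
    vx <- min(max(ctr[1, "x"] + sign(c0[1, "x"] - ctr[1, "x"]) *
                    log(0.05 * abs(c0[1, "x"] - ctr[1, "x"]) + 1) * 30,
                  1), 120)
    vy <- min(max(ctr[1, "y"] + sign(c0[1, "y"] - ctr[1, "y"]) *
                    log(0.05 * abs(c0[1, "y"] - ctr[1, "y"]) + 1) * 24,
                  1), 96)
    expect_equal(proj[i],
                 vals[regionIndex(g, min(max(ceiling(vy / 12), 1), 8),
                                  min(max(ceiling(vx / 12), 1), 10))])
  }
})

test_that("frequency-tuned saliency highlights a salient disk and is normalised", {
  expect_true(all(computeSaliency(array(0.31, c(32, 32, 3))) == 0))
  # one bright disk on a flat background
  img <- array(0.4, c(64, 64, 3))
  xs <- matrix(rep(1:64, each = 64), 64); ys <- t(xs)
  disk <- (xs - 40)^2 + (ys - 24)^2 <= 64
  for (ch in 1:3) { p <- img[, , ch]; p[disk] <- c(1, 0.1, 0.1)[ch]; img[, , ch] <- p }
  s <- computeSaliency(img)
  expect_equal(range(s), c(0, 1))
  expect_gt(mean(s[disk]), mean(s[!disk]) + 0.3)
  # rotation equivariance: saliency of the rotated image is the rotated map
  rot90 <- function(a) aperm(a[nrow(a):1, , , drop = FALSE], c(2, 1, 3))
  rotm <- function(m) t(m[nrow(m):1, , drop = FALSE])
  expect_equal(computeSaliency(rot90(img)), rotm(s), tolerance = 1e-6)
})

test_that("saliency-to-rate map is the bounded linear function of region means", {
  g <- partitionGrid(24, 24, 12)
  sal <- matrix(0, 24, 24)
  expect_equal(saliencyToRates(sal, g), rep(5, 4))
  expect_equal(saliencyToRates(sal + 1, g), rep(120, 4))
  sal[] <- 0.5
  expect_equal(saliencyToRates(sal, g), rep(62.5, 4))
  expect_error(saliencyToRates(sal, g, 10, 10), "lambda_min")
  # invariant to permutations of pixels within a region
  set.seed(42)
  sal2 <- matrix(runif(24 * 24), 24)
  r1 <- saliencyToRates(sal2, g)
  blk <- sal2[1:12, 1:12]
  sal2[1:12, 1:12] <- matrix(sample(blk), 12)
  expect_equal(saliencyToRates(sal2, g), r1)
  # monotone: raising any region's mean saliency raises its rate
  sal3 <- sal2; sal3[1:12, 1:12] <- pmin(sal3[1:12, 1:12] + 0.1, 1)
  expect_gt(saliencyToRates(sal3, g)[1], saliencyToRates(sal2, g)[1])
})

test_that("image and region-map round trips through disk preserve values", {
  tmp <- withr::local_tempdir()
  img <- tiny_pair(0, seed = 9)@a
  f <- file.path(tmp, "img.png")
  writeRasterImage(img, f)
  back <- readRasterImage(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
  g <- partitionGrid(144, 108, 12)
  vals <- runif(nRegions(g))
  f2 <- file.path(tmp, "map.csv")
  writeRegionMap(vals, g, f2)
  expect_equal(readRegionMap(f2, g), vals)
})
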