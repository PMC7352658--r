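test_that("one interior kernel integrates to unit mass", {
  cfg <- densityConfig(sigmaUm = 5, pixelSizeUm = 1)
  m <- densityMap(cbind(64, 64), c(128, 128), cfg)
  expect_lt(abs(sum(m) - 1), 1e-3)
})

test_that("the 1 mm^2 circle holds 99% of a 186 um kernel", {
  # analytic: 1 - exp(-A / (2 pi sigma^2))
  analytic <- gaussianCircleMass(1, 0.186)
  expect_equal(round(analytic, 2), 0.99)
  expect_lt(abs(analytic - 0.98995), 1e-5)
  # numeric map at 4 um/px grid resolution (sigma = 46.5 px)
  cfg <- densityConfig(sigmaUm = 186, pixelSizeUm = 4)
  ctr <- c(256, 256)
  m <- densityMap(cbind(ctr[1], ctr[2]), c(512, 512), cfg)
  rPx <- sqrt(1 / pi) * 1000 / 4        # radius of a 1 mm^2 circle
  inCircle <- outer(seq_len(512), seq_len(512), function(i, j)
    (i - ctr[1])^2 + (j - ctr[2])^2 <= rPx^2)
  expect_lt(abs(sum(m[inCircle]) - analytic), 1e-3)
})

test_that("density maps superpose linearly", {
  cfg <- densityConfig(sigmaUm = 6, pixelSizeUm = 1)
  a <- densityMap(cbind(40, 40), c(160, 160), cfg)
  b <- densityMap(cbind(120, 120), c(160, 160), cfg)
  ab <- densityMap(rbind(c(40, 40), c(120, 120)), c(160, 160), cfg)
  expect_lt(max(abs(ab - (a + b))), 1e-10)
})

test_that("an empty centroid list gives a zero map and out-of-bounds errors", {
  cfg <- densityConfig(sigmaUm = 5, pixelSizeUm = 1)
  expect_true(all(densityMap(matrix(numeric(0), 0, 2), c(32, 32), cfg) == 0))
  expect_error(densityMap(cbind(100, 10), c(32, 32), cfg), "bounds")
})

test_that("exclusion restricts the map without renormalizing", {
  cfg <- densityConfig(sigmaUm = 5, pixelSizeUm = 1)
  full <- densityMap(cbind(64, 64), c(128, 128), cfg)
  excl <- matrix(FALSE, 128, 128)
  excl[1:20, ] <- TRUE
  masked <- densityMap(cbind(64, 64), c(128, 128), cfg, exclusionMask = excl)
  expect_true(all(is.na(masked[excl])))
  expect_identical(masked[!excl], full[!excl])
})

test_that("identical numerator and denominator give a flat 100% map", {
  cfg <- densityConfig(sigmaUm = 4, pixelSizeUm = 1)
  m <- densityMap(rbind(c(40, 40), c(60, 70), c(50, 55)), c(100, 100), cfg)
  hm <- ratioHeatmap(m, m, cfg)
  expect_true(isDefined(hm))
  expect_lt(max(abs(hm@percentMap[hm@validMask] - 100)), 1e-9)
  expect_equal(hm@overallPercent, 100)
  expect_equal(hm@localRange, 0)
})

test_that("a uniform 20% field is recovered with a narrow local range", {
  set.seed(5)
  n <- 4000
  pos <- cbind(stats::runif(n, 1, 400), stats::runif(n, 1, 400))
  isDab <- stats::runif(n) < 0.2
  cfg <- densityConfig(sigmaUm = 30, pixelSizeUm = 1)
  dm <- densityMap(pos[isDab, ], c(400, 400), cfg)
  hm <- densityMap(pos, c(400, 400), cfg)   # denominator = all cells
  rh <- ratioHeatmap(dm, hm, cfg)
  expect_lt(abs(rh@overallPercent - 20), 2)
  expect_lt(rh@localRange, 25)
})

test_that("a planted spatial gradient appears in the local extremes", {
  set.seed(9)
  n <- 30000   # dense field so pixel-wise fraction noise stays small
  pos <- cbind(stats::runif(n, 1, 500), stats::runif(n, 1, 500))
  # 5% on the left plateau, rising linearly to 50% on the right plateau;
  # the plateaus cover the 2-sigma border margin excluded from summaries
  pFrac <- pmin(pmax(0.05 + 0.45 * (pos[, 2] - 80) / 340, 0.05), 0.5)
  isDab <- stats::runif(n) < pFrac
  cfg <- densityConfig(sigmaUm = 35, pixelSizeUm = 1)
  rh <- ratioHeatmap(densityMap(pos[isDab, ], c(500, 500), cfg),
                     densityMap(pos, c(500, 500), cfg), cfg)
  expect_lt(abs(rh@localMin - 5), 5)
  expect_lt(abs(rh@localMax - 50), 5)
})

test_that("a heatmap with no valid pixels is flagged undefined", {
  cfg <- densityConfig(sigmaUm = 4, pixelSizeUm = 1, hemaDensityFloor = 10)
  m <- densityMap(cbind(20, 20), c(40, 40), cfg)
  expect_warning(rh <- ratioHeatmap(m, m, cfg), "no valid")
  expect_false(isDefined(rh))
  expect_true(is.na(rh@overallPercent))
})

test_that("sigma in pixels must match sigma in micrometres", {
  expect_error(densityConfig(sigmaUm = 186, pixelSizeUm = 0.92,
                             sigmaPx = 150), "disagrees")
  cfg <- densityConfig(sigmaUm = 186, pixelSizeUm = 0.92)
  expect_equal(cfg$sigmaPx, 186 / 0.92)
})
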