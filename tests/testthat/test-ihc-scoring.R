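test_that("a planted 80/20 tile scores 20% within 2 points", {
  ref <- referenceTileScore()
  s <- ref$scored$score
  expect_true(isDefined(s))
  expect_lt(abs(percentPositive(s) - 20), 2)
})

test_that("a tile with no positive cells scores 0%", {
  tl <- simulateTile(tileConfig(nNegative = 30, nPositive = 0,
                                widthPx = 192, heightPx = 192, seed = 13))
  s <- scoreCore(tl$tile)$score
  expect_equal(percentPositive(s), 0)
})

test_that("a blank tile is flagged undefined, not scored 0", {
  tl <- simulateTile(tileConfig(nNegative = 0, nPositive = 0, noiseSd = 0,
                                widthPx = 64, heightPx = 64))
  s <- scoreCore(tl$tile)$score
  expect_false(isDefined(s))
  expect_true(is.na(percentPositive(s)))
})

test_that("scores are invariant under rotation and mirroring", {
  ref <- referenceTileScore()
  base <- ref$scored$score
  arr <- rgbArray(ref$tile$tile)
  rot90 <- array(NA_real_, c(dim(arr)[2], dim(arr)[1], 3))
  for (ch in 1:3) rot90[, , ch] <- t(arr[dim(arr)[1]:1, , ch])
  mirror <- arr[, dim(arr)[2]:1, , drop = FALSE]
  for (variant in list(rot90, mirror)) {
    tile <- new("StainedTile", rgb = variant, pixelSizeUm = 0.92)
    s <- scoreCore(tile)$score
    expect_identical(s@nDab, base@nDab)
    expect_identical(s@nHema, base@nHema)
  }
})

test_that("adding a distant positive cell never decreases the DAB count", {
  mkTile <- function(nPos) {
    hema <- matrix(0, 180, 180)
    dab <- matrix(0, 180, 180)
    centers <- cbind(c(40, 40, 140, 140, 90), c(40, 140, 40, 140, 90))
    for (i in 1:3)   # fixed negative background cells
      hema[outer(1:180, 1:180, function(r, c)
        (r - centers[i, 1] - 15)^2 + (c - centers[i, 2])^2 <= 49)] <- 0.8
    for (i in seq_len(nPos))
      dab[outer(1:180, 1:180, function(r, c)
        (r - centers[i, 1])^2 + (c - centers[i, 2])^2 <= 49)] <- 0.9
    renderConcentrations(hema, dab, quantize = FALSE)
  }
  counts <- vapply(1:5, function(k)
    scoreCore(mkTile(k))$score@nDab, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[5], 5L)
})

test_that("scoring recovers fractions across the planted range", {
  # sparse FoxP3-like regime (1%) through lymphocyte-rich (40%)
  fracs <- c(0.01, 0.05, 0.2, 0.4)
  recovered <- vapply(seq_along(fracs), function(i) {
    n <- 100
    tl <- simulateTile(tileConfig(nNegative = round(n * (1 - fracs[i])),
                                  nPositive = round(n * fracs[i]),
                                  widthPx = 360, heightPx = 360,
                                  seed = 300 + i))
    percentPositive(scoreCore(tl$tile)$score)
  }, numeric(1))
  err <- abs(recovered - 100 * fracs)
  expect_lt(mean(err), 2)
  expect_lt(err[1], 1)    # the 1% regime must stay within one point
})

test_that("the hema-denominator flag reports the raw DAB/hema ratio", {
  ref <- referenceTileScore()
  alt <- scoreCore(ref$tile$tile, denominator = "hema")$score
  base <- ref$scored$score
  expect_equal(percentPositive(alt),
               100 * base@nDab / base@nHema)
})

test_that("batch scoring returns one row per core", {
  tiles <- list(
    a = simulateTile(tileConfig(nNegative = 20, nPositive = 5,
                                widthPx = 160, heightPx = 160,
                                seed = 31))$tile,
    b = simulateTile(tileConfig(nNegative = 20, nPositive = 10,
                                widthPx = 160, heightPx = 160,
                                seed = 32))$tile)
  df <- scoreCores(tiles, marker = "CD45ro")
  expect_identical(df$coreId, c("a", "b"))
  expect_true(all(df$marker == "CD45ro"))
  expect_true(all(df$percentPositive >= 0 & df$percentPositive <= 100))
})
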