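test_that("duplicated cores correlate perfectly", {
  x <- c(10, 25, 5, 40, 18)
  sc <- data.frame(patient = rep(1:5, each = 2), coreIndex = rep(1:2, 5),
                   marker = "CD3", percent = rep(x, each = 2))
  res <- multisectorCorrelation(sc)
  expect_equal(res$r, 1)
  expect_identical(res$nPairs, 5L)
})

test_that("pooled pairs match a brute-force enumeration oracle", {
  set.seed(71)
  sc <- data.frame(patient = rep(1:8, times = c(2, 3, 2, 2, 3, 2, 2, 3)),
                   marker = "CD68")
  sc$coreIndex <- unlist(lapply(rle(sc$patient)$lengths, seq_len))
  sc$percent <- stats::runif(nrow(sc), 0, 50)
  res <- multisectorCorrelation(sc)
  # oracle: enumerate all unordered within-patient pairs directly
  xs <- ys <- numeric(0)
  for (p in unique(sc$patient)) {
    v <- sc$percent[sc$patient == p]
    for (i in seq_len(length(v) - 1)) for (j in (i + 1):length(v)) {
      xs <- c(xs, v[i]); ys <- c(ys, v[j])
    }
  }
  ct <- stats::cor.test(xs, ys)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  expect_identical(res$nPairs, length(xs))
})

test_that("zero within-patient spread gives r = 1 on planted fractions", {
  ms <- simulateMultisector(12, 2, withinPatientSd = 0, seed = 3,
                            render = FALSE)
  expect_true(all(ms$fractions[, 1] == ms$fractions[, 2]))
  sc <- data.frame(patient = rep(1:12, each = 2), coreIndex = rep(1:2, 12),
                   marker = "CD3",
                   percent = 100 * as.vector(t(ms$fractions)))
  expect_equal(multisectorCorrelation(sc)$r, 1)
})

test_that("dominant within-patient spread destroys cross-core correlation", {
  rej <- 0L
  for (rep in 1:200) {
    ms <- simulateMultisector(26, 2, betweenPatientSd = 0.005,
                              withinPatientSd = 0.15, meanFraction = 0.4,
                              seed = 5000 + rep, render = FALSE)
    sc <- data.frame(patient = rep(1:26, each = 2),
                     coreIndex = rep(1:2, 26), marker = "CD3",
                     percent = 100 * as.vector(t(ms$fractions)))
    res <- multisectorCorrelation(sc)
    if (!is.na(res$p) && res$p < 0.05) rej <- rej + 1L
  }
  # indistinguishable from zero: rejections near the 5% nominal level
  expect_lt(rej / 200, 0.12)
})

test_that("fewer than three pairs yields r without p", {
  sc <- data.frame(patient = c(1, 1, 2, 2), coreIndex = c(1, 2, 1, 2),
                   marker = "FoxP3", percent = c(1, 2, 3, 5))
  res <- multisectorCorrelation(sc)
  expect_false(is.na(res$r))
  expect_true(is.na(res$p))
})

test_that("marker cross-correlation handles exact and degenerate cases", {
  set.seed(12)
  a <- stats::runif(20, 5, 40)
  df <- data.frame(CD3 = a, CD45ro = 2 * a, CD68 = -a, FoxP3 = rep(3, 20))
  res <- markerCrossCorrelation(df)
  get <- function(m1, m2) res[res$markerA == m1 & res$markerB == m2, ]
  expect_equal(get("CD3", "CD45ro")$r, 1)
  expect_equal(get("CD3", "CD68")$r, -1)
  expect_true(is.na(get("CD3", "FoxP3")$r))  # constant marker flagged
})

test_that("independent markers show weak correlation at n = 50", {
  set.seed(77)
  df <- data.frame(A = stats::rnorm(50), B = stats::rnorm(50))
  expect_lt(abs(markerCrossCorrelation(df)$r), 0.3)
})
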