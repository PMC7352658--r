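test_that("a constant variable admits no split", {
  res <- optimalCutoff(rep(3, 20), stats::rexp(20, 0.1), rep(TRUE, 20))
  expect_false(res$admissible)
  expect_true(is.na(res$cutoff))
})

test_that("the returned split maximizes the log-rank statistic", {
  set.seed(61)
  n <- 60
  x <- stats::runif(n, 0, 20)
  t <- stats::rexp(n, 0.05 * ifelse(x > 10, 3, 1))
  res <- optimalCutoff(x, t, rep(TRUE, n), minLeaf = 5)
  expect_true(res$admissible)
  # oracle: recompute the statistic at every admissible midpoint
  ux <- sort(unique(x))
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  stats_at <- vapply(mids, function(m) {
    hi <- x > m
    if (sum(hi) < 5 || sum(!hi) < 5) return(-Inf)
    logrankTest(t, rep(TRUE, n), hi)$chi2
  }, numeric(1))
  expect_equal(res$statistic, max(stats_at))
  expect_equal(res$cutoff, mids[which.max(stats_at)])
  expect_gte(res$nLow, 5)
  expect_gte(res$nHigh, 5)
})

test_that("a planted hazard change-point is recovered", {
  set.seed(29)
  cuts <- replicate(20, {
    n <- 200
    x <- stats::runif(n, 0, 20)
    t <- stats::rexp(n, 0.05 * ifelse(x > 10, 2, 1))
    optimalCutoff(x, t, rep(TRUE, n), minLeaf = 10)$cutoff
  })
  # the cutoff distribution concentrates around the planted value 10
  expect_gt(stats::median(cuts), 7)
  expect_lt(stats::median(cuts), 13)
})

test_that("the univariable screen selects per-stratum predictors", {
  set.seed(83)
  cfg <- cohortConfig(nFemale = 80, nMale = 80, censorRate = 0.2,
                      missingRate = 0,
                      logHazard = c(ageYears = 0.08), seed = 19)
  coh <- simulateCohort(cfg)
  res <- univariableScreen(coh, c("ageYears", "cd3"))
  expect_true("ageYears" %in% res$selected)
  expect_identical(sort(unique(res$detail$stratum)),
                   c("all", "female", "male"))
  # empty candidate list stays empty
  empty <- univariableScreen(coh, character(0))
  expect_identical(empty$selected, character(0))
})

test_that("Cox recovers a strong planted binary effect", {
  set.seed(47)
  n <- 300
  x <- rep(0:1, each = n / 2)
  t <- stats::rexp(n, 0.05 * exp(log(4.4) * x))
  df <- data.frame(osMonths = t, event = TRUE, grp = x)
  res <- coxBackward(df, "grp")
  hr <- coxTerms(res)$hr
  expect_gt(hr, 3.3)
  expect_lt(hr, 5.9)
  expect_true(coxTerms(res)$ciLow <= hr & hr <= coxTerms(res)$ciHigh)
})

test_that("dichotomized coding enters the model as variable > cutoff", {
  set.seed(53)
  n <- 200
  age <- stats::runif(n, 40, 85)
  t <- stats::rexp(n, 0.04 * ifelse(age > 60, 4, 1))
  df <- data.frame(osMonths = t, event = TRUE, age = age)
  res <- coxBackward(df, "age",
                     codingMap = list(age = list(type = "dichotomized",
                                                 cutoff = 60)))
  tt <- coxTerms(res)
  expect_match(tt$coding, "dichotomized_at_60")
  expect_gt(tt$hr, 2)
})

test_that("null covariates are eliminated and elimination is deterministic", {
  set.seed(31)
  n <- 250
  x <- rep(0:1, each = n / 2)
  noise <- stats::rnorm(n)
  t <- stats::rexp(n, 0.05 * exp(1.2 * x))
  df <- data.frame(osMonths = t, event = TRUE, strong = x, noise = noise)
  a <- coxBackward(df, c("strong", "noise"))
  b <- coxBackward(df, c("strong", "noise"))
  expect_identical(coxTerms(a), coxTerms(b))
  expect_identical(a@eliminated, "noise")
  expect_identical(coxTerms(a)$variable, "strong")
})

test_that("a model with no surviving covariates is reported empty", {
  set.seed(97)
  n <- 120
  df <- data.frame(osMonths = stats::rexp(n, 0.1), event = TRUE,
                   junk = stats::rnorm(n))
  res <- coxBackward(df, "junk")
  expect_identical(nrow(coxTerms(res)), 0L)
  expect_identical(res@eliminated, "junk")
})
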