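test_that("survival-cohort filtering keeps immunocompetent chemo patients", {
  coh <- simulateCohort(cohortConfig(seed = 17))
  sub <- filterSurvivalCohort(coh)
  expect_true(all(!sub$immuneDeficient & sub$chemo))
  expect_identical(nrow(sub), sum(!coh$immuneDeficient & coh$chemo))
  # a missing flag cannot be verified and is excluded with a warning
  coh$immuneDeficient[1] <- NA
  expect_warning(sub2 <- filterSurvivalCohort(coh), "missing")
  expect_false(coh$patientId[1] %in% sub2$patientId)
  allFail <- coh
  allFail$chemo <- FALSE
  expect_error(suppressWarnings(filterSurvivalCohort(allFail)),
               "no patients")
})

test_that("uncensored KM steps by 1/n and the median is an order statistic", {
  times <- c(3, 9, 1, 7, 5)
  km <- kmFit(times, rep(TRUE, 5))
  expect_equal(km$surv, 1 - seq_len(5) / 5)
  expect_equal(km$time, sort(times))
  expect_equal(km$medianOsMonths, sort(times)[ceiling(5 / 2)])
  # equals the closed-form empirical survival without censoring
  expect_equal(km$surv, vapply(km$time,
                               function(t) mean(times > t), numeric(1)))
})

test_that("a single censored observation leaves the median undefined", {
  km <- kmFit(4.2, FALSE)
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$medianOsMonths))
})

test_that("exponential KM median approaches ln(2)/lambda", {
  set.seed(40)
  lambda <- 0.1
  t <- stats::rexp(2000, lambda)
  km <- kmFit(t, rep(TRUE, 2000))
  expect_lt(abs(km$medianOsMonths - log(2) / lambda) / (log(2) / lambda),
            0.05)
})

test_that("identical groups give a log-rank statistic of zero", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- rep(TRUE, 6)
  res <- logrankTest(c(t, t), c(e, e), rep(1:2, each = 6))
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("log-rank matches a hand-tabulated 6-subject example", {
  # groups A: deaths at 1, 3 and censored 5; B: deaths at 2, 4, 6
  times <- c(1, 3, 5, 2, 4, 6)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  group <- rep(c("A", "B"), each = 3)
  # manual tabulation over event times 1,2,3,4,6:
  # t=1: nA=3,nB=3,d=1,dA=1 -> e=0.5,  v=0.25
  # t=2: nA=2,nB=3,d=1,dA=0 -> e=0.4,  v=0.24
  # t=3: nA=2,nB=2,d=1,dA=1 -> e=0.5,  v=0.25
  # t=4: nA=1,nB=2,d=1,dA=0 -> e=1/3,  v=2/9
  # t=6: nA=0,nB=1,d=1,dA=0 -> e=0,    v=0
  oA <- 2; eA <- 0.5 + 0.4 + 0.5 + 1 / 3 + 0
  vA <- 0.25 + 0.24 + 0.25 + 2 / 9 + 0
  manualChi2 <- (oA - eA)^2 / vA
  res <- logrankTest(times, events, group)
  expect_equal(res$chi2, manualChi2, tolerance = 1e-12)
  expect_identical(res$df, 1L)
})

test_that("log-rank rejects degenerate group structures", {
  expect_error(logrankTest(1:4, rep(TRUE, 4), rep("a", 4)), "two groups")
  expect_error(logrankTest(1:4, rep(FALSE, 4), rep(c("a", "b"), 2)),
               "event")
})

test_that("log-rank type-I error is near the nominal 5% level", {
  set.seed(99)
  rej <- 0L
  nrep <- 400L
  for (i in seq_len(nrep)) {
    t <- stats::rexp(100, 0.1)
    g <- rep(1:2, each = 50)
    if (logrankTest(t, rep(TRUE, 100), g)$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / nrep, 0.02)
  expect_lt(rej / nrep, 0.08)
})
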