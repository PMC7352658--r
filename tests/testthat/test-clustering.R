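test_that("z-scoring gives mean 0 and sample SD 1 per feature", {
  coh <- simulateCohort(cohortConfig(missingRate = 0, seed = 2))
  Z <- zscoreFeatures(coh)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 2, stats::sd) - 1)), 1e-12)
  # translation invariance
  shifted <- coh
  shifted$cd3 <- shifted$cd3 + 50
  expect_equal(zscoreFeatures(shifted)[, "cd3"], Z[, "cd3"])
})

test_that("a two-point feature z-scores to +/- 1/sqrt(2) under sample SD", {
  df <- data.frame(x = c(0, 10))
  Z <- zscoreFeatures(df, "x")
  expect_equal(unname(Z[, "x"]), c(-1, 1) / sqrt(2))
})

test_that("zero-variance features are dropped with a warning", {
  df <- data.frame(a = c(1, 2, 3, 4), b = rep(5, 4))
  expect_warning(Z <- zscoreFeatures(df, c("a", "b")), "zero-variance")
  expect_identical(colnames(Z), "a")
})

test_that("Ward recovers three well-separated blobs", {
  skip_if_not_installed("mclust")
  set.seed(10)
  X <- rbind(matrix(stats::rnorm(60, 0), ncol = 2),
             matrix(stats::rnorm(60, 6), ncol = 2),
             matrix(stats::rnorm(60, c(0, 12)), ncol = 2, byrow = TRUE))
  truth <- rep(1:3, each = 30)
  res <- wardClusters(X, k = 3)
  ari <- mclust::adjustedRandIndex(assignments(res), truth)
  expect_gte(ari, 0.95)
})

test_that("duplicated rows are always co-assigned", {
  set.seed(3)
  X <- matrix(stats::rnorm(40), ncol = 4)
  XX <- rbind(X, X)
  rownames(XX) <- as.character(seq_len(nrow(XX)))
  cl <- assignments(wardClusters(XX, k = 3))
  expect_identical(unname(cl[1:10]), unname(cl[11:20]))
})

test_that("merge heights are monotone non-decreasing", {
  set.seed(8)
  X <- matrix(stats::rnorm(100), ncol = 5)
  res <- wardClusters(X, k = 2)
  expect_true(all(diff(res@linkage$height) >= -1e-12))
})

test_that("small instances match the exhaustive greedy Ward oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    X <- matrix(stats::rnorm(n * 3), ncol = 3)
    oracle <- bruteWardPartitions(X)
    for (k in 2:(n - 1)) {
      ours <- assignments(wardClusters(X, k = k))
      expect_true(samePartition(unname(ours), oracle[[n - k]]))
    }
  }
})

test_that("clustering is invariant to row and feature order", {
  set.seed(14)
  X <- matrix(stats::rnorm(30 * 4), ncol = 4)
  rownames(X) <- sprintf("p%02d", 1:30)
  base <- assignments(wardClusters(X, k = 3))
  perm <- sample(30)
  shuffled <- assignments(wardClusters(X[perm, ], k = 3))
  expect_true(samePartition(unname(base[perm]), unname(shuffled)))
  fperm <- assignments(wardClusters(X[, c(3, 1, 4, 2)], k = 3))
  expect_true(samePartition(unname(base), unname(fperm)))
})

test_that("identical group distributions give a Kruskal-Wallis H of 0", {
  df <- data.frame(patientId = sprintf("p%d", 1:6),
                   ecog = c(1, 2, 3, 1, 2, 3))
  cl <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), df$patientId)
  res <- characterizeClusters(df, cl, features = "ecog", ordinal = "ecog")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("a planted 3-SD shift is detected at n = 40", {
  set.seed(33)
  df <- data.frame(patientId = sprintf("p%02d", 1:40),
                   x = c(stats::rnorm(20, 0), stats::rnorm(20, 3)),
                   o = c(stats::rnorm(20, 0), stats::rnorm(20, 3)))
  cl <- stats::setNames(rep(1:2, each = 20L), df$patientId)
  res <- characterizeClusters(df, cl, features = c("x", "o"), ordinal = "o")
  expect_lt(res$p[res$feature == "x"], 0.01)
  expect_lt(res$p[res$feature == "o"], 0.01)
  expect_true(all(c("anova", "kruskal-wallis") %in% res$test))
})

test_that("null ANOVA p-values are close to uniform", {
  set.seed(55)
  ps <- replicate(150, {
    df <- data.frame(patientId = sprintf("p%02d", 1:30),
                     x = stats::rnorm(30))
    cl <- stats::setNames(rep(1:2, 15L), df$patientId)
    characterizeClusters(df, cl, features = "x", ordinal = character(0))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("sex-stratified clustering recovers planted structure", {
  skip_if_not_installed("mclust")
  cfg <- cohortConfig(nFemale = 40, nMale = 33,
                      clusterSpec = plantedClusterSpec(33),
                      missingRate = 0.03, seed = 101)
  coh <- simulateCohort(cfg)
  res <- sexStratifiedClustering(coh, kFemale = 3, kMale = 3, seed = 6)
  ariF <- mclust::adjustedRandIndex(
    assignments(res$female),
    coh$.cluster[match(names(assignments(res$female)), coh$patientId)])
  expect_gte(ariF, 0.9)
  # the 3-member male satellite is flagged excluded, never reassigned
  expect_identical(length(excludedClusters(res$male)), 1L)
  sizes <- table(assignments(res$male))
  expect_lt(sizes[as.character(excludedClusters(res$male))], 4)
  expect_identical(sum(sizes), 33L)
  # characterization runs on the retained clusters
  expect_gt(nrow(featureTests(res$male)), 0L)
})

test_that("stratum smaller than k errors out", {
  coh <- simulateCohort(cohortConfig(nFemale = 4, nMale = 30,
                                     missingRate = 0, seed = 3))
  expect_error(sexStratifiedClustering(coh, kFemale = 6, kMale = 2),
               "smaller than k")
})
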