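# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# one scored reference tile (80 negative / 20 positive), reused by several
# IHC tests to avoid re-rendering
referenceTileScore <- function() {
  if (is.null(.fixtures$refScore)) {
    tl <- simulateTile(tileConfig(nNegative = 80, nPositive = 20, seed = 11))
    .fixtures$refTile <- tl
    .fixtures$refScore <- scoreCore(tl$tile)
  }
  list(tile = .fixtures$refTile, scored = .fixtures$refScore)
}

# cluster spec with two well-separated (>= 2 SD in several features) planted
# clusters per sex plus a 3-member male satellite; mirrors the replication
# conditions used in the acceptance checks
plantedClusterSpec <- function(nMale = 33) {
  f <- clusteringFeatures()
  sds <- stats::setNames(rep(1, length(f)), f)
  sds[c("enhancingCm3", "edemaCm3")] <- c(4, 10)
  sds[c("ageYears", "pctDeep")] <- c(6, 8)
  base <- stats::setNames(
    c(55, 18, 0.5, 90, 1.5, 62, 1, 15, 38, 18, 1), f)
  shift <- function(ch) { m <- base; m[names(ch)] <- ch; m[f] }
  list(
    female = list(
      list(proportion = 0.275,
           mean = shift(c(ageYears = 48, enhancingCm3 = 6, edemaCm3 = 40,
                          cd3 = 5, cd45ro = 18)), sd = sds),
      list(proportion = 0.175,
           mean = shift(c(enhancingCm3 = 42, edemaCm3 = 140,
                          ageYears = 70)), sd = sds),
      list(proportion = 0.55,
           mean = shift(c(cd3 = 30, cd45ro = 60, cd68 = 30, foxp3 = 4,
                          pctDeep = 80)), sd = sds)),
    male = list(
      list(proportion = 15 / nMale,
           mean = shift(c(ageYears = 46, pctDeep = 85, enhancingCm3 = 6)),
           sd = sds),
      list(proportion = (nMale - 18) / nMale,
           mean = shift(c(enhancingCm3 = 38, edemaCm3 = 130,
                          ageYears = 70, cd3 = 25)), sd = sds),
      list(proportion = 3 / nMale,
           mean = shift(c(cd3 = 45, cd45ro = 75, cd68 = 45, foxp3 = 8)),
           sd = sds)))
}

# brute-force greedy Ward (Lance-Williams on squared Euclidean distances):
# independent oracle for small instances
bruteWardPartitions <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  ss <- function(idx) {
    if (length(idx) == 1L) return(0)
    sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
  }
  while (length(clusters) > 1L) {
    best <- NULL; bestCost <- Inf
    m <- length(clusters)
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      cost <- ss(c(clusters[[i]], clusters[[j]])) -
        ss(clusters[[i]]) - ss(clusters[[j]])
      if (cost < bestCost) { bestCost <- cost; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    lab <- integer(n)
    for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- lab
  }
  partitions   # partitions[[i]] has n - i clusters
}

# two labelings describe the same partition (up to label permutation):
# identical co-membership matrices
samePartition <- function(a, b) all(outer(a, a, "==") == outer(b, b, "=="))

# full hypergeometric enumeration oracle for the two-sided Fisher test
fisherEnumOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
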