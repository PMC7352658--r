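#' Z-score a feature set within the cohort being clustered
#'
#' Centres each feature to mean 0 and scales to sample SD 1 (ddof = 1, the
#' `stats::sd` convention), computed within the table passed in -- i.e.
#' within the stratified sub-cohort, never on a pooled table. Zero-variance
#' features carry no clustering information and are dropped with a warning.
#'
#' @param table data.frame holding the features
#' @param features character vector of feature columns
#' @return standardized numeric matrix (rows named by `patientId` when
#'   present), with attributes `center` and `scale`
#' @export
zscoreFeatures <- function(table, features = clusteringFeatures()) {
  stopifnot(all(features %in% names(table)))
  X <- as.matrix(as.data.frame(lapply(table[features], as.numeric)))
  if (anyNA(X)) stop("features contain NA: impute before z-scoring")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(X)
  Z <- sweep(sweep(X, 2L, ctr), 2L, sds, "/")
  rownames(Z) <- if ("patientId" %in% names(table)) table$patientId
                 else rownames(table)
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- sds
  Z
}

# Largest relative gap in the last merge heights picks k: the merge that
# costs disproportionately more than the previous one marks the natural cut.
gapSelectK <- function(hc, kMin = 2L, kMax = 6L) {
  n <- length(hc$height) + 1L
  kMax <- min(kMax, n - 1L)
  hts <- rev(hc$height)            # hts[k] = height of the merge k -> k-1
  ratios <- hts[kMin:kMax - 1L] / pmax(hts[kMin:kMax], .Machine$double.eps)
  (kMin:kMax)[which.max(ratios)]
}

#' Ward agglomerative clustering of a standardized feature matrix
#'
#' Bottom-up minimum-variance (Ward) merging on Euclidean distances
#' (`stats::hclust`, method "ward.D2", whose heights are on the distance
#' scale and non-decreasing), cut into `k` clusters. When `k` is NULL it is
#' chosen by the largest relative gap in the merge heights between 2 and 6
#' clusters.
#'
#' @param Z numeric matrix (rows = patients), typically from
#'   [zscoreFeatures()]
#' @param k number of clusters, or NULL for gap-based selection
#' @return a [ClusterResult-class] (excluded slot empty; see
#'   [sexStratifiedClustering()] for the size rule)
#' @export
wardClusters <- function(Z, k = NULL) {
  n <- nrow(Z)
  if (is.null(rownames(Z))) rownames(Z) <- as.character(seq_len(n))
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  if (is.null(k)) k <- gapSelectK(hc)
  if (k > n) stop("k exceeds the number of observations")
  cut <- stats::cutree(hc, k = k)
  new("ClusterResult", assignments = stats::setNames(as.integer(cut),
                                                     rownames(Z)),
      linkage = hc, k = as.integer(k), excluded = integer(0),
      featureTests = data.frame())
}

#' Test which features differ between clusters
#'
#' One-way ANOVA for numerical features and Kruskal-Wallis H-tests for
#' ordinal ones, comparing non-excluded clusters. P-values are reported
#' unadjusted (the analysis is exploratory), with a Benjamini-Hochberg
#' column alongside. Singleton clusters cannot support a variance estimate
#' and are left out of the tests.
#'
#' @param table data.frame with the feature columns
#' @param assignments named integer vector (patient -> cluster), e.g. from
#'   [assignments()]
#' @param features feature columns to test
#' @param ordinal features tested with Kruskal-Wallis instead of ANOVA
#' @param exclude cluster ids to leave out (e.g. undersized clusters)
#' @return data.frame: feature, test, statistic, p, pAdj
#' @export
characterizeClusters <- function(table, assignments,
                                 features = clusteringFeatures(),
                                 ordinal = c("ecog", "nFoci"),
                                 exclude = integer(0)) {
  ids <- if ("patientId" %in% names(table)) table$patientId
         else rownames(table)
  cl <- assignments[match(ids, names(assignments))]
  keep <- !is.na(cl) & !(cl %in% exclude)
  sizes <- table(cl[keep])
  small <- as.integer(names(sizes)[sizes < 2L])
  if (length(small)) {
    message("excluding singleton cluster(s) from tests: ",
            paste(small, collapse = ", "))
    keep <- keep & !(cl %in% small)
  }
  grp <- factor(cl[keep])
  if (nlevels(grp) < 2L) stop("need at least two non-excluded clusters")
  rows <- lapply(features, function(v) {
    x <- as.numeric(table[[v]][keep])
    if (v %in% ordinal) {
      kt <- stats::kruskal.test(x, grp)
      data.frame(feature = v, test = "kruskal-wallis",
                 statistic = unname(kt$statistic), p = kt$p.value)
    } else {
      ft <- summary(stats::aov(x ~ grp))[[1L]]
      data.frame(feature = v, test = "anova",
                 statistic = ft$`F value`[1L], p = ft$`Pr(>F)`[1L])
    }
  })
  res <- do.call(rbind, rows)
  res$pAdj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Sex-stratified cluster analysis of a multimodal cohort
#'
#' The full clustering chain run separately per sex: pooled random-forest
#' imputation (both sexes inform each other's missing entries; set
#' `imputeStratified = TRUE` to impute within stratum), within-stratum
#' z-scoring, Ward clustering cut at the per-sex k, flagging of clusters
#' below `minClusterSize` (flagged as excluded, never reassigned -- a
#' three-patient satellite cluster is too small to characterize), and
#' ANOVA / Kruskal-Wallis characterization over the retained clusters.
#'
#' @param table cohort data.frame (needs `sex` in \{female, male\} and the
#'   feature columns)
#' @param kFemale,kMale cluster counts per sex (NULL = gap-based selection);
#'   the defaults 3 and 3 correspond to three female clusters and two male
#'   clusters plus a small immune-driven satellite
#' @param minClusterSize clusters smaller than this are flagged excluded
#' @param features clustering features
#' @param imputeStratified impute per sex instead of pooled
#' @param seed seed for the imputer
#' @return list with elements `female` and `male` ([ClusterResult-class])
#'   and `imputed` (the imputed table)
#' @export
sexStratifiedClustering <- function(table, kFemale = 3L, kMale = 3L,
                                    minClusterSize = 4L,
                                    features = clusteringFeatures(),
                                    imputeStratified = FALSE, seed = 1L) {
  stopifnot(all(c("female", "male") %in% table$sex))
  imp <- if (imputeStratified) {
    parts <- split(table, table$sex)
    do.call(rbind, lapply(parts, imputeMissing, columns = NULL, seed = seed))
  } else imputeMissing(table, seed = seed)
  onesex <- function(sx, k) {
    sub <- imp[imp$sex == sx, , drop = FALSE]
    if (!is.null(k) && nrow(sub) < k)
      stop(sprintf("%s stratum smaller than k = %d", sx, k))
    Z <- zscoreFeatures(sub, features)
    res <- wardClusters(Z, k)
    sizes <- table(assignments(res))
    res@excluded <- as.integer(names(sizes)[sizes < minClusterSize])
    res@featureTests <- characterizeClusters(
      sub, assignments(res), features = intersect(features, colnames(Z)),
      exclude = res@excluded)
    res
  }
  list(female = onesex("female", kFemale), male = onesex("male", kMale),
       imputed = imp)
}
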