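#' The clustering feature set
#'
#' The eleven numerical/ordinal variables used for patient clustering:
#' deep-location percentage, the three compartment volumes, number of foci,
#' age, ECOG performance, and the four immune scores. Treatment variables are
#' deliberately absent so that clusters reflect the state at diagnosis, not
#' subsequent therapy; location variables other than deep location are
#' excluded because they are strongly interdependent and would dominate a
#' Euclidean clustering.
#'
#' @return character vector of column names
#' @export
clusteringFeatures <- function() {
  c("pctDeep", "enhancingCm3", "necroticCm3", "edemaCm3", "nFoci",
    "ageYears", "ecog", "cd3", "cd45ro", "cd68", "foxp3")
}

defaultClusterSpec <- function() {
  f <- clusteringFeatures()
  base <- c(pctDeep = 60, enhancingCm3 = 20, necroticCm3 = 0.5,
            edemaCm3 = 95, nFoci = 1.5, ageYears = 63, ecog = 1.2,
            cd3 = 15, cd45ro = 38, cd68 = 18, foxp3 = 1)
  sds <- c(pctDeep = 12, enhancingCm3 = 6, necroticCm3 = 0.4,
           edemaCm3 = 20, nFoci = 0.7, ageYears = 7, ecog = 0.6,
           cd3 = 5, cd45ro = 8, cd68 = 5, foxp3 = 0.5)
  mk <- function(shift) { m <- base; m[names(shift)] <- shift; m[f] }
  list(
    female = list(
      # young / small-lesion cluster, large-tumor cluster, immune-hot cluster
      list(proportion = 0.27,
           mean = mk(c(ageYears = 52, enhancingCm3 = 8, edemaCm3 = 40,
                       cd3 = 6, cd45ro = 20, cd68 = 10, ecog = 0.6)),
           sd = sds[f]),
      list(proportion = 0.17,
           mean = mk(c(enhancingCm3 = 45, edemaCm3 = 130, ageYears = 68)),
           sd = sds[f]),
      list(proportion = 0.56,
           mean = mk(c(cd3 = 28, cd45ro = 55, cd68 = 28, foxp3 = 2.5,
                       pctDeep = 75, ageYears = 68, ecog = 1.8)),
           sd = sds[f])),
    male = list(
      # young deep-location cluster vs large-tumor immune-rich cluster
      list(proportion = 0.27,
           mean = mk(c(ageYears = 48, pctDeep = 80, enhancingCm3 = 8,
                       edemaCm3 = 45)),
           sd = sds[f]),
      list(proportion = 0.73,
           mean = mk(c(enhancingCm3 = 32, edemaCm3 = 110, ageYears = 66,
                       cd3 = 24, cd45ro = 50, cd68 = 24)),
           sd = sds[f])))
}

#' Configuration for a synthetic multimodal cohort
#'
#' Defines the cohort the generator emulates: per-sex sample sizes (defaults
#' 41 female / 33 male), planted cluster structure over the
#' [clusteringFeatures()] set, a proportional-hazards survival mechanism
#' (event time exponential with rate h0 * exp(x' beta)), administrative
#' censoring, and MCAR missingness.
#'
#' @param nFemale,nMale per-sex sample sizes
#' @param clusterSpec list with elements `female` and `male`; each a list of
#'   clusters given as list(proportion, mean, sd) over the clustering
#'   features (proportions must sum to 1 per sex; SDs positive)
#' @param baselineHazard baseline event rate h0 per month (> 0)
#' @param logHazard named numeric vector of per-feature log-hazard
#'   coefficients applied to the named columns (empty = no covariate effect)
#' @param censorRate fraction administratively censored (approximate, in
#'   [0, 1))
#' @param missingRate fraction of entries masked missing, MCAR, in [0, 1)
#' @param seed RNG seed
#' @return validated config list of class `CohortConfig`
#' @export
cohortConfig <- function(nFemale = 41, nMale = 33,
                         clusterSpec = defaultClusterSpec(),
                         baselineHazard = 0.05, logHazard = numeric(0),
                         censorRate = 0.25, missingRate = 0.03, seed = 1L) {
  if (baselineHazard <= 0) stop("degenerate hazard: baselineHazard must be > 0")
  stopifnotScalar(censorRate, "censorRate", lo = 0, hi = 1 - 1e-9)
  stopifnotScalar(missingRate, "missingRate", lo = 0, hi = 1 - 1e-9)
  for (sx in c("female", "male")) {
    spec <- clusterSpec[[sx]]
    props <- vapply(spec, `[[`, numeric(1), "proportion")
    if (abs(sum(props) - 1) > 1e-6)
      stop(sprintf("%s cluster proportions must sum to 1", sx))
    for (cl in spec)
      if (any(cl$sd <= 0)) stop("all cluster feature SDs must be > 0")
  }
  structure(list(nFemale = as.integer(nFemale), nMale = as.integer(nMale),
                 clusterSpec = clusterSpec, baselineHazard = baselineHazard,
                 logHazard = logHazard, censorRate = censorRate,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Generate a synthetic multimodal patient cohort
#'
#' Each patient draws a planted cluster (per sex), features from the cluster's
#' Gaussian, treatment/immune-status flags at realistic prevalences, and a
#' survival time from an exponential proportional-hazards model
#' (h = h0 * exp(x' beta)); the observed time is the minimum of the event and
#' an exponential administrative censoring time whose rate is matched to the
#' requested censoring fraction. Ground truth is carried in the hidden
#' columns `.cluster` (planted cluster id) and `.eventTime` (uncensored
#' time); the MCAR missingness mask is applied afterwards to ECOG and the
#' immune scores, the variables affected in practice by cores floating off or
#' undocumented performance status.
#'
#' @param config a [cohortConfig()]
#' @return data.frame of patient records: patientId, sex, the clustering
#'   features, treatment flags (chemo, mtx, hdMtx, radio, rituximab,
#'   polyChemo, bsc), immuneDeficient, osMonths, event, and the hidden
#'   ground-truth columns
#' @examples
#' coh <- simulateCohort(cohortConfig(seed = 42))
#' table(coh$sex, coh$.cluster)
#' @export
simulateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  feats <- clusteringFeatures()
  onesex <- function(sx, n) {
    spec <- config$clusterSpec[[sx]]
    props <- vapply(spec, `[[`, numeric(1), "proportion")
    # planted proportions are honored exactly: deterministic counts via
    # rounded cumulative proportions, then a random shuffle of the order
    counts <- diff(c(0L, round(cumsum(props) * n)))
    cl <- sample(rep.int(seq_along(spec), counts))
    X <- t(vapply(cl, function(k)
      stats::rnorm(length(feats), spec[[k]]$mean[feats], spec[[k]]$sd[feats]),
      numeric(length(feats))))
    colnames(X) <- feats
    df <- as.data.frame(X)
    df$sex <- sx
    df$.cluster <- cl
    df
  }
  coh <- rbind(onesex("female", config$nFemale),
               onesex("male", config$nMale))
  n <- nrow(coh)
  # domain clipping / ordinal snapping
  coh$pctDeep <- clamp(coh$pctDeep, 0, 100)
  for (v in c("enhancingCm3", "necroticCm3", "edemaCm3"))
    coh[[v]] <- pmax(coh[[v]], 0)
  coh$nFoci <- pmax(1, round(coh$nFoci))
  coh$ageYears <- clamp(coh$ageYears, 19, 95)
  coh$ecog <- as.integer(snapToGrid(coh$ecog, 0:4))
  for (v in c("cd3", "cd45ro", "cd68", "foxp3"))
    coh[[v]] <- clamp(coh[[v]], 0, 100)
  # treatment and immune-status flags at cohort-typical prevalences
  coh$immuneDeficient <- stats::runif(n) < 0.10
  coh$chemo <- stats::runif(n) < 0.80
  coh$mtx <- coh$chemo & (stats::runif(n) < 0.92)
  coh$hdMtx <- coh$mtx & (stats::runif(n) < 0.88)
  coh$radio <- stats::runif(n) < 0.40
  coh$rituximab <- coh$chemo & (stats::runif(n) < 0.27)
  coh$polyChemo <- coh$chemo & (stats::runif(n) < 0.42)
  coh$bsc <- !coh$chemo & !coh$radio
  # proportional-hazards event times
  eta <- rep(0, n)
  if (length(config$logHazard)) {
    for (v in names(config$logHazard))
      eta <- eta + config$logHazard[[v]] * coh[[v]]
  }
  rate <- config$baselineHazard * exp(eta)
  eventTime <- stats::rexp(n, rate)
  if (config$censorRate > 0) {
    # exponential censoring with rate chosen so that
    # P(censor < event) = censorRate at the mean subject rate
    cr <- config$censorRate / (1 - config$censorRate) * mean(rate)
    censTime <- stats::rexp(n, cr)
  } else censTime <- rep(Inf, n)
  coh$osMonths <- pmin(eventTime, censTime)
  coh$event <- eventTime <= censTime
  coh$.eventTime <- eventTime
  coh$patientId <- sprintf("P%03d", seq_len(n))
  # MCAR missingness on ECOG and immune scores
  if (config$missingRate > 0) {
    maskable <- c("ecog", "cd3", "cd45ro", "cd68", "foxp3")
    for (v in maskable)
      coh[[v]][stats::runif(n) < config$missingRate] <- NA
  }
  rownames(coh) <- coh$patientId
  coh[, c("patientId", "sex", feats, "immuneDeficient", "chemo", "mtx",
          "hdMtx", "radio", "rituximab", "polyChemo", "bsc", "osMonths",
          "event", ".cluster", ".eventTime")]
}
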