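#' Configuration for one synthetic stained tile
#'
#' Describes a brightfield H-DAB tissue-core tile with known ground truth:
#' `nNegative` hematoxylin-only nuclei and `nPositive` DAB-stained cells,
#' rendered as ellipses (axis ratio at most 1.4, Gaussian-blurred edges,
#' sigma = 1 px) via Beer-Lambert mixing of the canonical H-DAB stain
#' vectors, then converted OD to RGB. The default pixel size of 0.92 um/px
#' matches a 10x-magnification core export in which a 204 px kernel spans
#' 186 um.
#'
#' @param widthPx,heightPx tile dimensions in pixels
#' @param pixelSizeUm physical pixel edge length in micrometres
#' @param nNegative,nPositive planted cell counts
#' @param meanRadiusPx,radiusSdPx nucleus equivalent-radius distribution (px)
#' @param overlapAllowance max fraction of the combined cell extent two
#'   centers may approach; 0 forbids any contact
#' @param hemaOd,dabOd per-cell stain concentration amplitudes (OD units)
#' @param noiseSd additive Gaussian noise SD in OD space (per channel)
#' @param quantize round rendered intensities to the 8-bit grid
#' @param seed RNG seed; the same config and seed give bit-identical tiles
#' @return validated config list of class `TileConfig`
#' @export
tileConfig <- function(widthPx = 320, heightPx = 320, pixelSizeUm = 0.92,
                       nNegative = 80, nPositive = 20, meanRadiusPx = 7,
                       radiusSdPx = 1, overlapAllowance = 0, hemaOd = 0.8,
                       dabOd = 0.9, noiseSd = 0.02, quantize = TRUE,
                       seed = 1L) {
  if (!isCount(nNegative) || !isCount(nPositive))
    stop("cell counts must be nonnegative integers")
  stopifnotScalar(pixelSizeUm, "pixelSizeUm", lo = 1e-6)
  stopifnotScalar(noiseSd, "noiseSd", lo = 0)
  stopifnotScalar(overlapAllowance, "overlapAllowance", lo = 0, hi = 1)
  stopifnotScalar(meanRadiusPx, "meanRadiusPx", lo = 1)
  structure(list(widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
                 pixelSizeUm = pixelSizeUm, nNegative = as.integer(nNegative),
                 nPositive = as.integer(nPositive),
                 meanRadiusPx = meanRadiusPx, radiusSdPx = radiusSdPx,
                 overlapAllowance = overlapAllowance, hemaOd = hemaOd,
                 dabOd = dabOd, noiseSd = noiseSd, quantize = quantize,
                 seed = as.integer(seed)),
            class = "TileConfig")
}

# Place n cell centers by rejection sampling. Cells i and j must keep their
# centers at least (1 - allowance) * axisFactor * (r_i + r_j) + 3 px apart
# (axisFactor covers the worst-case ellipse elongation, +3 px the blur tail),
# so allowance = 0 forbids contact between rendered nuclei.
placeCells <- function(n, radii, h, w, allowance, margin = 2) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  axisFactor <- sqrt(1.4)
  centers <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  maxTries <- 400L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop(sprintf(
        "packing error: could not place %d cells of mean radius %.1f px in a %d x %d tile",
        n, mean(radii), h, w), call. = FALSE)
    r <- radii[placed + 1L]
    cand <- c(stats::runif(1, 1 + r + margin, h - r - margin),
              stats::runif(1, 1 + r + margin, w - r - margin))
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 1L] - cand[1L])^2 +
                (centers[seq_len(placed), 2L] - cand[2L])^2)
      minSep <- (1 - allowance) * axisFactor *
        (radii[seq_len(placed)] + r) + 3
      ok <- all(d >= minSep)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  centers
}

# Rasterize one elliptical nucleus into conc (in place via return), and its
# id into lab.
stampEllipse <- function(conc, lab, center, radius, ecc, theta, amp, id) {
  a <- radius * sqrt(ecc); b <- radius / sqrt(ecc)
  rmax <- ceiling(a) + 1L
  rows <- max(1L, floor(center[1] - rmax)):min(nrow(conc), ceiling(center[1] + rmax))
  cols <- max(1L, floor(center[2] - rmax)):min(ncol(conc), ceiling(center[2] + rmax))
  dr <- rows - center[1]
  dc <- cols - center[2]
  DR <- matrix(dr, length(dr), length(dc))
  DC <- matrix(dc, length(dr), length(dc), byrow = TRUE)
  u <- (DR * cos(theta) + DC * sin(theta)) / a
  v <- (-DR * sin(theta) + DC * cos(theta)) / b
  inside <- (u^2 + v^2) <= 1
  sub <- conc[rows, cols]
  sub[inside] <- pmax(sub[inside], amp)
  conc[rows, cols] <- sub
  labSub <- lab[rows, cols]
  labSub[inside] <- id
  lab[rows, cols] <- labSub
  list(conc = conc, lab = lab)
}

#' Render a synthetic stained tile with known ground truth
#'
#' Nuclei are placed by rejection sampling under the configured overlap rule,
#' rasterized as randomly oriented ellipses at the planted stain amplitudes,
#' edge-blurred (Gaussian, sigma = 1 px), mixed into per-channel optical
#' densities through the stain matrix, perturbed by channel-wise Gaussian OD
#' noise, and converted to RGB. Marker-negative nuclei carry hematoxylin
#' only; DAB-positive cells carry DAB only, so the hematoxylin channel counts
#' exactly the negative population.
#'
#' @param config a [tileConfig()]
#' @param stains a [StainMatrix-class] used for rendering (and, if reused for
#'   deconvolution, giving an exact round trip)
#' @return list with `tile` ([StainedTile-class]) and `truth`
#'   ([TileGroundTruth-class])
#' @examples
#' tl <- simulateTile(tileConfig(nNegative = 10, nPositive = 5, seed = 3))
#' tl$truth
#' @export
simulateTile <- function(config = tileConfig(), stains = hdabStainMatrix()) {
  stopifnot(inherits(config, "TileConfig"))
  set.seed(config$seed)
  h <- config$heightPx; w <- config$widthPx
  nNeg <- config$nNegative; nPos <- config$nPositive
  n <- nNeg + nPos
  hemaConc <- matrix(0, h, w)
  dabConc <- matrix(0, h, w)
  lab <- matrix(0L, h, w)
  centers <- matrix(numeric(0), 0L, 2L)
  if (n > 0L) {
    radii <- pmax(2, stats::rnorm(n, config$meanRadiusPx, config$radiusSdPx))
    # quick feasibility check before the expensive sampling loop
    need <- sum((sqrt(1.4) * 2 * radii + 3)^2)
    if (need > 1.2 * h * w)
      stop("packing error: requested cells cannot fit the tile at the ",
           "configured overlap allowance", call. = FALSE)
    centers <- placeCells(n, radii, h, w, config$overlapAllowance)
    eccs <- stats::runif(n, 1, 1.4)
    thetas <- stats::runif(n, 0, pi)
    for (i in seq_len(n)) {
      isPos <- i > nNeg
      res <- stampEllipse(if (isPos) dabConc else hemaConc, lab,
                          centers[i, ], radii[i], eccs[i], thetas[i],
                          if (isPos) config$dabOd else config$hemaOd, i)
      lab <- res$lab
      if (isPos) dabConc <- res$conc else hemaConc <- res$conc
    }
    hemaConc <- pmax(gaussianSmooth2d(hemaConc, 1), 0)
    dabConc <- pmax(gaussianSmooth2d(dabConc, 1), 0)
  }
  od <- outer(as.vector(hemaConc), stains@hema) +
        outer(as.vector(dabConc), stains@dab)
  if (config$noiseSd > 0)
    od <- pmax(od + stats::rnorm(length(od), 0, config$noiseSd), 0)
  rgb <- array(odToRgb(od, quantize = config$quantize), c(h, w, 3L))
  tile <- new("StainedTile", rgb = rgb, pixelSizeUm = config$pixelSizeUm)
  truth <- new("TileGroundTruth",
               centersNegative = centers[seq_len(nNeg), , drop = FALSE],
               centersPositive = centers[nNeg + seq_len(nPos), , drop = FALSE],
               labelImage = lab)
  list(tile = tile, truth = truth)
}

#' Generate a multisector core set with controlled heterogeneity
#'
#' Emulates 2--3 tissue cores punched from different regions of the same
#' tumor: each patient draws a mean positive fraction (between-patient SD),
#' each core deviates from it (within-patient SD). With `withinPatientSd = 0`
#' all cores of a patient share one planted fraction; when the within-patient
#' spread dominates, cross-core correlation collapses toward zero.
#'
#' @param nPatients number of patients
#' @param coresPerPatient cores per patient (>= 2)
#' @param betweenPatientSd,withinPatientSd SDs of the planted positive
#'   fraction hierarchy (must be >= 0)
#' @param meanFraction grand-mean planted positive fraction
#' @param nCellsPerCore total cells rendered per core
#' @param seed RNG seed
#' @param render render tiles (`TRUE`) or return only planted fractions
#'   (`FALSE`; fast path for correlation studies)
#' @param baseConfig template [tileConfig()] for rendered cores
#' @return list with `fractions` (nPatients x cores matrix of planted
#'   fractions) and `sets` (per patient, a list of [simulateTile()] results;
#'   `NULL` when `render = FALSE`)
#' @export
simulateMultisector <- function(nPatients, coresPerPatient = 2,
                                betweenPatientSd = 0.08,
                                withinPatientSd = 0.03,
                                meanFraction = 0.2, nCellsPerCore = 60,
                                seed = 1L, render = TRUE,
                                baseConfig = tileConfig()) {
  if (coresPerPatient < 2) stop("coresPerPatient must be >= 2")
  if (betweenPatientSd < 0 || withinPatientSd < 0)
    stop("planted-fraction SDs must be nonnegative")
  set.seed(seed)
  patientMeans <- clamp(stats::rnorm(nPatients, meanFraction, betweenPatientSd),
                        0.005, 0.95)
  fractions <- matrix(
    clamp(rep(patientMeans, each = coresPerPatient) +
            if (withinPatientSd > 0)
              stats::rnorm(nPatients * coresPerPatient, 0, withinPatientSd)
            else 0,
          0.005, 0.95),
    nrow = nPatients, ncol = coresPerPatient, byrow = TRUE)
  sets <- NULL
  if (render) {
    coreSeeds <- matrix(sample.int(2^30, nPatients * coresPerPatient),
                        nPatients, coresPerPatient)
    sets <- lapply(seq_len(nPatients), function(p) {
      lapply(seq_len(coresPerPatient), function(k) {
        nPos <- round(fractions[p, k] * nCellsPerCore)
        cfg <- baseConfig
        cfg$nPositive <- as.integer(nPos)
        cfg$nNegative <- as.integer(nCellsPerCore - nPos)
        cfg$seed <- coreSeeds[p, k]
        simulateTile(cfg)
      })
    })
  }
  list(fractions = fractions, sets = sets)
}
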