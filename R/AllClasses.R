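#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' StainedTile: an RGB brightfield tile with physical pixel size
#'
#' The unit of IHC scoring: one tissue-core image (typically exported at 10x
#' magnification) together with the physical edge length of a pixel. Channel
#' intensities live on the 0--255 scale but are stored as doubles so that
#' continuous (unquantized) renderings can round-trip through colour
#' deconvolution exactly.
#'
#' @slot rgb numeric H x W x 3 array, values in [0, 255]
#' @slot pixelSizeUm physical edge length of one pixel in micrometres
#' @exportClass StainedTile
setClass("StainedTile",
  representation(rgb = "array", pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@rgb)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "rgb must be an H x W x 3 array")
    else if (d[1] < 1L || d[2] < 1L)
      msg <- c(msg, "image dimensions must be strictly positive")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(d) == 3L &&
        (min(object@rgb) < 0 || max(object@rgb) > 255))
      msg <- c(msg, "rgb values must lie in [0, 255]")
    if (is.null(msg)) TRUE else msg
  })

#' TileGroundTruth: planted-cell ground truth for a synthetic tile
#'
#' @slot centersNegative n x 2 matrix of (row, col) centroids of
#'   hematoxylin-only (marker-negative) nuclei; 0-row matrix when none
#' @slot centersPositive n x 2 matrix of centroids of DAB-positive cells
#' @slot labelImage integer matrix assigning each pixel its planted cell id
#'   (0 = background); negative cells carry ids 1..nNeg, positive cells follow
#' @exportClass TileGroundTruth
setClass("TileGroundTruth",
  representation(centersNegative = "matrix", centersPositive = "matrix",
                 labelImage = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@centersNegative) != 2L || ncol(object@centersPositive) != 2L)
      msg <- c(msg, "center matrices must have two columns (row, col)")
    d <- dim(object@labelImage)
    cc <- rbind(object@centersNegative, object@centersPositive)
    if (nrow(cc) > 0 &&
        (min(cc) < 1 || max(cc[, 1]) > d[1] || max(cc[, 2]) > d[2]))
      msg <- c(msg, "all centers must lie inside the image bounds")
    if (is.null(msg)) TRUE else msg
  })

#' StainMatrix: H-DAB stain optical-density vectors
#'
#' Unit-norm optical-density vectors (one per RGB channel) for hematoxylin and
#' DAB. Stain mixing is linear in OD space (Beer-Lambert), so these two
#' vectors, completed by their cross product, define the deconvolution basis.
#'
#' @slot hema unit-norm 3-vector of hematoxylin OD per RGB channel
#' @slot dab unit-norm 3-vector of DAB OD per RGB channel
#' @exportClass StainMatrix
setClass("StainMatrix",
  representation(hema = "numeric", dab = "numeric"),
  validity = function(object) {
    msg <- NULL
    for (nm in c("hema", "dab")) {
      v <- slot(object, nm)
      if (length(v) != 3L || any(v < 0))
        msg <- c(msg, sprintf("%s must be a nonnegative 3-vector", nm))
      else if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
        msg <- c(msg, sprintf("%s must be unit-normalized", nm))
    }
    if (is.null(msg)) {
      cp <- crossProd3(object@hema, object@dab)
      if (sqrt(sum(cp^2)) < 1e-6)
        msg <- c(msg, "stain vectors must be linearly independent")
    }
    if (is.null(msg)) TRUE else msg
  })

#' CellDetection: labelled cells with centroids
#'
#' @slot labelImage integer matrix of cell labels (0 = background)
#' @slot centroids n x 2 matrix of (row, col) per-label pixel means
#' @slot count number of detected cells
#' @exportClass CellDetection
setClass("CellDetection",
  representation(labelImage = "matrix", centroids = "matrix",
                 count = "integer"),
  validity = function(object) {
    msg <- NULL
    nlab <- length(setdiff(unique(as.integer(object@labelImage)), 0L))
    if (object@count != nlab || object@count != nrow(object@centroids))
      msg <- c(msg, "count must equal number of distinct labels and centroids")
    if (is.null(msg)) TRUE else msg
  })

#' ImmuneScore: percent-positive immune score for one core and marker
#'
#' percentPositive is 100 * nDab / (nDab + nHema): the DAB+ cells as a
#' percentage of all detected cells (DAB-positive plus hematoxylin-only).
#' When no cells at all are detected, the score is undefined (NA) and
#' flagged, never silently 0.
#'
#' @slot marker marker name, one of CD3, CD45ro, CD68, FoxP3 (free-form
#'   strings are accepted for non-standard panels)
#' @slot nDab number of DAB-positive cells
#' @slot nHema number of hematoxylin-positive (marker-negative) cells
#' @slot percentPositive 100 * nDab / (nDab + nHema); NA when undefined
#' @slot defined FALSE when nDab + nHema == 0
#' @exportClass ImmuneScore
setClass("ImmuneScore",
  representation(marker = "character", nDab = "integer", nHema = "integer",
                 percentPositive = "numeric", defined = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@nDab < 0L || object@nHema < 0L)
      msg <- c(msg, "cell counts must be nonnegative")
    if (object@defined) {
      if (is.na(object@percentPositive) ||
          object@percentPositive < 0 || object@percentPositive > 100)
        msg <- c(msg, "percentPositive must lie in [0, 100] when defined")
    } else if (!is.na(object@percentPositive)) {
      msg <- c(msg, "undefined scores must carry NA percentPositive")
    }
    if (is.null(msg)) TRUE else msg
  })

#' SegmentationCase: co-registered tumor compartments and atlas labels
#'
#' Compartment codes: 0 background, 1 enhancing tumor, 2 necrosis,
#' 3 edema/non-enhancing tumor. The atlas volume must live on the identical
#' voxel grid (registration is a precondition, not performed here).
#'
#' @slot compartments 3D integer array of compartment codes
#' @slot voxelSpacingMm 3-vector of voxel edge lengths in mm
#' @slot atlas 3D integer array of atlas region codes (0 = uncovered)
#' @slot regionNames named character vector mapping atlas code (name) to a
#'   region class: frontal, parietal, temporal, occipital, one of the deep
#'   sub-structures, or other
#' @slot laterality named character vector mapping atlas code to
#'   left / right / midline
#' @exportClass SegmentationCase
setClass("SegmentationCase",
  representation(compartments = "array", voxelSpacingMm = "numeric",
                 atlas = "array", regionNames = "character",
                 laterality = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@compartments)) != 3L)
      msg <- c(msg, "compartments must be a 3D array")
    if (!identical(dim(object@compartments), dim(object@atlas)))
      msg <- c(msg, "compartments and atlas must share one voxel grid")
    if (length(object@voxelSpacingMm) != 3L || any(object@voxelSpacingMm <= 0))
      msg <- c(msg, "voxelSpacingMm must be a positive 3-vector")
    if (!all(unique(as.integer(object@compartments)) %in% 0:3))
      msg <- c(msg, "compartment codes must be in 0..3")
    if (is.null(msg)) TRUE else msg
  })

#' RatioHeatmap: pixel-wise percent-positive map with summaries
#'
#' @slot percentMap per-pixel 100 * dabDensity / hemaDensity (NA off-support)
#' @slot validMask logical matrix: denominator above floor, not excluded, and
#'   far enough from the border that zero-padding does not bias the densities
#' @slot overallPercent percent over valid pixels from pooled densities
#' @slot localMin,localMax,localRange summary statistics over valid pixels
#' @slot defined FALSE when no valid pixels exist
#' @exportClass RatioHeatmap
setClass("RatioHeatmap",
  representation(percentMap = "matrix", validMask = "matrix",
                 overallPercent = "numeric", localMin = "numeric",
                 localMax = "numeric", localRange = "numeric",
                 defined = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@percentMap), dim(object@validMask)))
      msg <- c(msg, "percentMap and validMask must share dimensions")
    if (object@defined &&
        !isTRUE(all.equal(object@localRange, object@localMax - object@localMin)))
      msg <- c(msg, "localRange must equal localMax - localMin")
    if (is.null(msg)) TRUE else msg
  })

#' ClusterResult: sex-stratified Ward clustering of a patient cohort
#'
#' @slot assignments named integer vector, patient id -> cluster id
#' @slot linkage hclust object holding merge order and heights
#' @slot k number of clusters the tree was cut at
#' @slot excluded integer ids of clusters below the minimum size (kept in
#'   assignments, flagged here, never reassigned)
#' @slot featureTests data.frame of per-feature test name, statistic, p-value
#'   (may have zero rows before characterization)
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(assignments = "integer", linkage = "ANY", k = "integer",
                 excluded = "integer", featureTests = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (is.null(names(object@assignments)))
      msg <- c(msg, "assignments must be named by patient id")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' CoxResult: a backward-eliminated Cox proportional-hazards model
#'
#' Terms report the hazard ratio (exp of the partial-likelihood coefficient),
#' its Wald 95 percent confidence interval and p-value, together with the
#' coding used for the variable (dichotomized at a survival-tree cutoff, or
#' continuous per unit increase). Eliminated variables are recorded in drop
#' order.
#'
#' @slot terms data.frame with columns variable, coding, hr, ciLow, ciHigh, p
#' @slot eliminated character vector of dropped variables, in drop order
#' @slot fit the final survival::coxph fit (NULL when no term survives)
#' @slot n number of subjects; nEvents number of observed events
#' @exportClass CoxResult
setClass("CoxResult",
  representation(terms = "data.frame", eliminated = "character",
                 fit = "ANY", n = "integer", nEvents = "integer"),
  validity = function(object) {
    msg <- NULL
    tt <- object@terms
    if (nrow(tt)) {
      if (any(tt$hr <= 0)) msg <- c(msg, "hazard ratios must be positive")
      if (any(tt$ciLow > tt$hr | tt$hr > tt$ciHigh))
        msg <- c(msg, "each CI must bracket its hazard ratio")
    }
    if (is.null(msg)) TRUE else msg
  })
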