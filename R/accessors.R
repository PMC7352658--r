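#' Accessors for the core data classes
#'
#' Slot access goes through these accessors, never through `@`.
#'
#' @param x an object of the documented class
#' @param ... ignored
#' @return the slot value (see each method)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("rgbArray", "StainedTile", function(x) x@rgb)

#' @rdname accessors
#' @export
setMethod("pixelSize", "StainedTile", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("labelImage", "CellDetection", function(x) x@labelImage)

#' @rdname accessors
#' @export
setMethod("labelImage", "TileGroundTruth", function(x) x@labelImage)

#' @rdname accessors
#' @export
setMethod("centroids", "CellDetection", function(x, ...) x@centroids)

#' @rdname accessors
#' @param which for ground truth: "negative", "positive" or "all"
#' @export
setMethod("centroids", "TileGroundTruth",
  function(x, which = c("all", "negative", "positive"), ...) {
    which <- match.arg(which)
    switch(which,
      negative = x@centersNegative,
      positive = x@centersPositive,
      all = rbind(x@centersNegative, x@centersPositive))
  })

#' @rdname accessors
#' @export
setMethod("cellCount", "CellDetection", function(x) x@count)

#' @rdname accessors
#' @export
setMethod("percentPositive", "ImmuneScore", function(x) x@percentPositive)

#' @rdname accessors
#' @export
setMethod("isDefined", "ImmuneScore", function(x) x@defined)

#' @rdname accessors
#' @export
setMethod("isDefined", "RatioHeatmap", function(x) x@defined)

#' @rdname accessors
#' @export
setMethod("assignments", "ClusterResult", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("excludedClusters", "ClusterResult", function(x) x@excluded)

#' @rdname accessors
#' @export
setMethod("featureTests", "ClusterResult", function(x) x@featureTests)

#' @rdname accessors
#' @export
setMethod("coxTerms", "CoxResult", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("compartments", "SegmentationCase", function(x) x@compartments)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "SegmentationCase", function(x) x@voxelSpacingMm)

#' @rdname accessors
#' @export
setMethod("atlasVolume", "SegmentationCase", function(x) x@atlas)

setMethod("show", "StainedTile", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("StainedTile: %d x %d px (%.3g um/px, %.0f x %.0f um)\n",
              d[1], d[2], object@pixelSizeUm,
              d[1] * object@pixelSizeUm, d[2] * object@pixelSizeUm))
})

setMethod("show", "TileGroundTruth", function(object) {
  cat(sprintf("TileGroundTruth: %d negative + %d positive planted cells\n",
              nrow(object@centersNegative), nrow(object@centersPositive)))
})

setMethod("show", "CellDetection", function(object) {
  cat(sprintf("CellDetection: %d cells\n", object@count))
})

setMethod("show", "ImmuneScore", function(object) {
  if (object@defined)
    cat(sprintf("ImmuneScore [%s]: %.2f%% positive (%d DAB+ / %d hema+)\n",
                object@marker, object@percentPositive, object@nDab,
                object@nHema))
  else
    cat(sprintf("ImmuneScore [%s]: undefined (no cells detected)\n",
                object@marker))
})

setMethod("show", "SegmentationCase", function(object) {
  d <- dim(object@compartments)
  cat(sprintf(
    "SegmentationCase: %d x %d x %d voxels @ %s mm; %d tumor voxels\n",
    d[1], d[2], d[3], paste(object@voxelSpacingMm, collapse = "x"),
    sum(object@compartments > 0L)))
})

setMethod("show", "RatioHeatmap", function(object) {
  if (object@defined)
    cat(sprintf(
      "RatioHeatmap: overall %.1f%%, local range %.1f%% (%.1f-%.1f%%), %d valid px\n",
      object@overallPercent, object@localRange, object@localMin,
      object@localMax, sum(object@validMask)))
  else
    cat("RatioHeatmap: undefined (no valid pixels)\n")
})

setMethod("show", "ClusterResult", function(object) {
  tab <- table(object@assignments)
  cat(sprintf("ClusterResult: k = %d (sizes: %s)%s\n", object@k,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              if (length(object@excluded))
                sprintf("; excluded small clusters: %s",
                        paste(object@excluded, collapse = ", ")) else ""))
})

setMethod("show", "CoxResult", function(object) {
  cat(sprintf("CoxResult: %d subjects, %d events\n", object@n, object@nEvents))
  if (nrow(object@terms)) {
    for (i in seq_len(nrow(object@terms)))
      with(object@terms[i, ], cat(sprintf(
        "  %s [%s]: HR %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
        variable, coding, hr, ciLow, ciHigh, p)))
  } else cat("  (no terms retained)\n")
  if (length(object@eliminated))
    cat("  eliminated:", paste(object@eliminated, collapse = " > "), "\n")
})
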