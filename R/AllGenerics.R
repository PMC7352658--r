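#' @export
setGeneric("rgbArray", function(x) standardGeneric("rgbArray"))
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @export
setGeneric("centroids", function(x, ...) standardGeneric("centroids"))
#' @export
setGeneric("cellCount", function(x) standardGeneric("cellCount"))
#' @export
setGeneric("percentPositive", function(x) standardGeneric("percentPositive"))
#' @export
setGeneric("isDefined", function(x) standardGeneric("isDefined"))
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @export
setGeneric("excludedClusters", function(x) standardGeneric("excludedClusters"))
#' @export
setGeneric("featureTests", function(x) standardGeneric("featureTests"))
#' @export
setGeneric("coxTerms", function(x) standardGeneric("coxTerms"))
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setGeneric("atlasVolume", function(x) standardGeneric("atlasVolume"))
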