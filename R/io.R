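#' Read and write stained tiles
#'
#' Tiles are exchanged as 8-bit RGB TIFF (or PNG, chosen by file extension).
#' The physical pixel size is not stored in these formats and travels as an
#' explicit argument.
#'
#' @param tile a [StainedTile-class]
#' @param path output path ending in .tiff/.tif or .png
#' @return `writeTile` returns the path invisibly; `readTile` returns a
#'   [StainedTile-class]
#' @export
writeTile <- function(tile, path) {
  stopifnot(is(tile, "StainedTile"))
  arr <- rgbArray(tile) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  else if (ext == "png") png::writePNG(arr, path)
  else stop("unsupported tile format: .", ext)
  invisible(path)
}

#' @rdname writeTile
#' @param pixelSizeUm pixel size to attach on read
#' @export
readTile <- function(path, pixelSizeUm = 0.92) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported tile format: .", ext)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  new("StainedTile", rgb = arr[, , 1:3, drop = FALSE] * 255,
      pixelSizeUm = pixelSizeUm)
}

#' Write tile ground truth as centroid CSV plus 16-bit label TIFF
#'
#' @param truth a [TileGroundTruth-class]
#' @param csvPath centroid table destination (columns type, row, col)
#' @param labelTiffPath optional label-image destination (16-bit TIFF)
#' @return invisible csvPath
#' @export
writeGroundTruth <- function(truth, csvPath, labelTiffPath = NULL) {
  cn <- centroids(truth, "negative")
  cp <- centroids(truth, "positive")
  df <- rbind(
    if (nrow(cn)) data.frame(type = "negative", row = cn[, 1], col = cn[, 2]),
    if (nrow(cp)) data.frame(type = "positive", row = cp[, 1], col = cp[, 2]))
  if (is.null(df)) df <- data.frame(type = character(0), row = numeric(0),
                                    col = numeric(0))
  utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(labelTiffPath))
    tiff::writeTIFF(labelImage(truth) / 65535, labelTiffPath,
                    bits.per.sample = 16L)
  invisible(csvPath)
}

#' Write and read a segmentation case as NIfTI plus a JSON region map
#'
#' Compartment codes: 0 background, 1 enhancing, 2 necrosis, 3 edema. The
#' atlas volume shares the voxel grid; region and laterality maps go into
#' one JSON file keyed by atlas code.
#'
#' @param case a [SegmentationCase-class]
#' @param segPath,atlasPath NIfTI destinations (.nii or .nii.gz)
#' @param regionsJsonPath JSON destination for the code maps
#' @return invisible segPath
#' @export
writeSegmentationCase <- function(case, segPath, atlasPath, regionsJsonPath) {
  stopifnot(is(case, "SegmentationCase"))
  sp <- voxelSpacing(case)
  writeVol <- function(vol, path) {
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
  }
  writeVol(compartments(case), segPath)
  writeVol(atlasVolume(case), atlasPath)
  jsonlite::write_json(
    list(regionNames = as.list(case@regionNames),
         laterality = as.list(case@laterality)),
    regionsJsonPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(segPath)
}

#' @rdname writeSegmentationCase
#' @export
readSegmentationCase <- function(segPath, atlasPath, regionsJsonPath) {
  seg <- RNifti::readNifti(segPath)
  atlas <- RNifti::readNifti(atlasPath)
  sp <- RNifti::pixdim(seg)[1:3]
  maps <- jsonlite::read_json(regionsJsonPath, simplifyVector = TRUE)
  new("SegmentationCase",
      compartments = array(as.integer(round(seg)), dim(seg)),
      voxelSpacingMm = as.numeric(sp),
      atlas = array(as.integer(round(atlas)), dim(atlas)),
      regionNames = unlist(maps$regionNames),
      laterality = unlist(maps$laterality))
}

#' Write a density or ratio heatmap as 32-bit float TIFF
#'
#' NA pixels (excluded/invalid) are stored as -1, which no density or
#' percentage can attain.
#'
#' @param map numeric matrix
#' @param path destination .tiff path
#' @return invisible path
#' @export
writeHeatmapTiff <- function(map, path) {
  m <- map
  m[is.na(m)] <- -1
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
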