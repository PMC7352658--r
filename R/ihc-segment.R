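#' Segmentation parameters for IHC cell detection
#'
#' Phansalkar defaults are the original publication's values (radius 15 px,
#' k = 0.25, p = 2, q = 10); the minimum object area of 20 px at 0.92 um/px
#' corresponds to ~17 um^2, below any nucleus, so it removes debris only.
#'
#' @param phansalkarRadiusPx local-window radius in pixels
#' @param phansalkarK,phansalkarP,phansalkarQ Phansalkar threshold constants
#' @param minCellAreaPx smallest object (pixels) kept after watershed
#' @param neighborMin minimum number of positive 8-neighbors a pixel needs to
#'   survive background filtering (default 2)
#' @param connectivity pixel connectivity for labelling, 4 or 8
#' @param minStainOd absolute stain-concentration floor (OD units): pixels
#'   at or below it never count as positive, so relative (Otsu/Phansalkar)
#'   thresholds cannot hallucinate objects out of noise on an unstained
#'   channel
#' @return a validated parameter list of class `SegmentationParams`
#' @export
segmentationParams <- function(phansalkarRadiusPx = 15, phansalkarK = 0.25,
                               phansalkarP = 2.0, phansalkarQ = 10,
                               minCellAreaPx = 20, neighborMin = 2,
                               connectivity = 8, minStainOd = 0.1) {
  stopifnotScalar(phansalkarRadiusPx, "phansalkarRadiusPx", lo = 1)
  stopifnotScalar(minCellAreaPx, "minCellAreaPx", lo = 1)
  stopifnotScalar(neighborMin, "neighborMin", lo = 0, hi = 8)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(phansalkarRadiusPx = phansalkarRadiusPx,
                 phansalkarK = phansalkarK, phansalkarP = phansalkarP,
                 phansalkarQ = phansalkarQ, minCellAreaPx = minCellAreaPx,
                 neighborMin = neighborMin, connectivity = connectivity,
                 minStainOd = minStainOd),
            class = "SegmentationParams")
}

# Phansalkar local threshold on an image normalized to [0, 1]:
#   t = m * (1 + p * exp(-q * m) + k * (s / r - 1)),  r = 0.5
# with m, s the local mean and SD over a disc window. Designed for
# low-contrast stained images; the p*exp(-q*m) term lowers the threshold in
# dim regions.
phansalkarMask <- function(x01, radius, k, p, q) {
  brush <- EBImage::makeBrush(2L * ceiling(radius) + 1L, shape = "disc")
  brush <- brush / sum(brush)
  m <- fftConvolve2d(x01, brush)
  s2 <- fftConvolve2d(x01^2, brush) - m^2
  s <- sqrt(pmax(s2, 0))
  thr <- m * (1 + p * exp(-q * m) + k * (s / 0.5 - 1))
  x01 > thr
}

#' Threshold a stain-concentration map into a positive-pixel mask
#'
#' Dual automatic thresholding: a pixel is kept only if it passes both the
#' Phansalkar local threshold and the Otsu global threshold (AND combination:
#' an OR would reduce to whichever threshold is looser). The map is scaled by
#' its maximum to [0, 1] before thresholding; a constant map leaves Otsu
#' undefined and yields an empty mask with a warning.
#'
#' @param odMap single-channel nonnegative stain concentration matrix
#' @param params a [segmentationParams()] list
#' @return logical matrix of positive pixels
#' @export
segmentPositive <- function(odMap, params = segmentationParams()) {
  stopifnot(is.matrix(odMap), min(odMap) >= 0)
  rng <- range(odMap)
  if (diff(rng) < .Machine$double.eps^0.5) {
    warning("constant map: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(odMap), ncol(odMap)))
  }
  x01 <- odMap / rng[2]
  otsuThr <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1))
  local <- phansalkarMask(x01, params$phansalkarRadiusPx, params$phansalkarK,
                          params$phansalkarP, params$phansalkarQ)
  # the absolute floor keeps relative thresholds from hallucinating objects
  # out of noise on a channel that carries no stain at all
  local & (x01 > otsuThr) & (odMap > params$minStainOd)
}

# Count of positive 8-neighbors for every pixel, by shifted sums (border
# pixels see out-of-image neighbors as negative).
neighborCount8 <- function(mask) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  n <- matrix(0, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    n <- n + m[(2:(nrow(mask) + 1L)) + dr, (2:(ncol(mask) + 1L)) + dc]
  }
  n
}

#' Remove positively stained background pixels
#'
#' A single pass keeping only pixels with at least `neighborMin` positive
#' 8-neighbors (default 2). Isolated stained pixels -- typically background
#' chromogen speckle -- are removed; the output is always a subset of the
#' input mask.
#'
#' @param mask logical matrix
#' @param params a [segmentationParams()] list (uses `neighborMin`)
#' @return logical matrix
#' @export
filterBackground <- function(mask, params = segmentationParams()) {
  stopifnot(is.matrix(mask))
  mask & (neighborCount8(mask) >= params$neighborMin)
}

#' Split touching cells by watershed and extract centroids
#'
#' Watershed on the negated Euclidean distance transform of the mask, seeded
#' by h-maxima of the distance map with h = 0.3 * max(distance). Objects
#' smaller than `minCellAreaPx` are discarded. Centroids are per-label pixel
#' means in (row, col).
#'
#' @param mask logical matrix (after background filtering)
#' @param params a [segmentationParams()] list
#' @return a [CellDetection-class]
#' @export
splitTouching <- function(mask, params = segmentationParams()) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "integer"
  if (!any(mask == 1L))
    return(new("CellDetection", labelImage = mask * 0L,
               centroids = matrix(numeric(0), 0L, 2L), count = 0L))
  dm <- EBImage::distmap(EBImage::Image(mask))
  h <- 0.3 * max(dm)
  ext <- if (params$connectivity == 8) 1L else 1L
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = h, ext = ext))
  storage.mode(lab) <- "integer"
  # size filter, then relabel 1..n
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$minCellAreaPx)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  n <- length(keep)
  if (n == 0L)
    return(new("CellDetection", labelImage = lab,
               centroids = matrix(numeric(0), 0L, 2L), count = 0L))
  idx <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[lab > 0L]
  cent <- cbind(tapply(idx[, 1L], lv, mean), tapply(idx[, 2L], lv, mean))
  dimnames(cent) <- NULL
  new("CellDetection", labelImage = lab, centroids = cent, count = n)
}
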