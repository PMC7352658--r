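#' Default synthetic brain atlas layout
#'
#' Partitions a voxel grid into four lobar slabs per hemisphere along the
#' first (anterior-posterior) axis, with a central "deep" box (periventricular
#' code) overriding the lobar codes, mirroring how merged lobar + deep
#' atlases assign deep structures priority. Codes 1-4: left frontal,
#' parietal, temporal, occipital; 5-8: the right-sided counterparts; 9: deep
#' (midline).
#'
#' @param shape integer 3-vector of voxel grid dimensions
#' @return list with `atlas` (3D integer array), `regionNames` and
#'   `laterality` (named character vectors keyed by atlas code)
#' @export
defaultAtlasLayout <- function(shape) {
  atlas <- array(0L, shape)
  xb <- round(seq(0, shape[1], length.out = 5L))
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  mid <- shape[2] / 2
  for (i in 1:4) {
    xs <- (xb[i] + 1L):xb[i + 1L]
    atlas[xs, 1:floor(mid), ] <- i            # left
    atlas[xs, (floor(mid) + 1L):shape[2], ] <- i + 4L  # right
  }
  ctr <- round(shape / 2)
  half <- pmax(2L, round(shape / 6))
  atlas[(ctr[1] - half[1]):(ctr[1] + half[1]),
        (ctr[2] - half[2]):(ctr[2] + half[2]),
        (ctr[3] - half[3]):(ctr[3] + half[3])] <- 9L
  regionNames <- c(`1` = "frontal", `2` = "parietal", `3` = "temporal",
                   `4` = "occipital", `5` = "frontal", `6` = "parietal",
                   `7` = "temporal", `8` = "occipital",
                   `9` = "periventricular")
  laterality <- c(`1` = "left", `2` = "left", `3` = "left", `4` = "left",
                  `5` = "right", `6` = "right", `7` = "right", `8` = "right",
                  `9` = "midline")
  list(atlas = atlas, regionNames = regionNames, laterality = laterality)
}

#' Generate a synthetic tumor segmentation with co-registered atlas
#'
#' Plants spherical foci of given compartment (1 enhancing, 2 necrosis,
#' 3 edema) into a label volume. Ground truth is attached as attributes:
#' `trueVoxelCounts` (per compartment), `trueVolumesCm3`, and `trueFoci`
#' (the number of connected groups of planted enhancing spheres, merging
#' spheres whose centre distance is below the sum of their radii --
#' overlapping same-compartment foci merge in the rendered volume and are
#' counted once).
#'
#' @param shapeVoxels integer 3-vector
#' @param voxelSpacingMm numeric 3-vector of voxel edges in mm
#' @param plantedFoci list of foci, each list(center = voxel-index 3-vector,
#'   radiusMm = scalar, compartment = 1:3)
#' @param atlasLayout a list as returned by [defaultAtlasLayout()]; defaults
#'   to that layout on the same grid
#' @param seed unused placeholder for interface symmetry (the construction is
#'   deterministic); kept so pipelines can thread one seed everywhere
#' @return a [SegmentationCase-class] with ground-truth attributes
#' @examples
#' sc <- simulateSegmentationCase(
#'   plantedFoci = list(list(center = c(32, 32, 32), radiusMm = 10,
#'                           compartment = 1)))
#' attr(sc, "trueVolumesCm3")
#' @export
simulateSegmentationCase <- function(shapeVoxels = c(64L, 64L, 64L),
                                     voxelSpacingMm = c(1, 1, 1),
                                     plantedFoci = list(),
                                     atlasLayout = NULL, seed = 1L) {
  shapeVoxels <- as.integer(shapeVoxels)
  stopifnot(length(shapeVoxels) == 3L, all(voxelSpacingMm > 0))
  if (is.null(atlasLayout)) atlasLayout <- defaultAtlasLayout(shapeVoxels)
  comp <- array(0L, shapeVoxels)
  idx <- list(seq_len(shapeVoxels[1]), seq_len(shapeVoxels[2]),
              seq_len(shapeVoxels[3]))
  for (f in plantedFoci) {
    ctr <- f$center; rMm <- f$radiusMm
    rVox <- rMm / voxelSpacingMm
    if (any(ctr - rVox < 0.5) || any(ctr + rVox > shapeVoxels + 0.5))
      stop("planted focus does not fit inside the volume")
    # voxel centre inside the sphere (physical distance)
    dx2 <- ((idx[[1]] - ctr[1]) * voxelSpacingMm[1])^2
    dy2 <- ((idx[[2]] - ctr[2]) * voxelSpacingMm[2])^2
    dz2 <- ((idx[[3]] - ctr[3]) * voxelSpacingMm[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rMm^2
    comp[inside] <- as.integer(f$compartment)
  }
  vc <- vapply(1:3, function(k) sum(comp == k), numeric(1))
  names(vc) <- c("enhancing", "necrotic", "edema")
  voxVol <- prod(voxelSpacingMm)
  # geometric merge count of planted enhancing foci
  enh <- Filter(function(f) f$compartment == 1, plantedFoci)
  nf <- length(enh)
  if (nf > 0L) {
    parent <- seq_len(nf)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nf > 1L) for (i in 1:(nf - 1L)) for (j in (i + 1L):nf) {
      d <- sqrt(sum(((enh[[i]]$center - enh[[j]]$center) * voxelSpacingMm)^2))
      if (d < enh[[i]]$radiusMm + enh[[j]]$radiusMm) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    nf <- length(unique(vapply(seq_len(nf), find, integer(1))))
  }
  case <- new("SegmentationCase", compartments = comp,
              voxelSpacingMm = as.numeric(voxelSpacingMm),
              atlas = atlasLayout$atlas,
              regionNames = atlasLayout$regionNames,
              laterality = atlasLayout$laterality)
  attr(case, "trueVoxelCounts") <- vc
  attr(case, "trueVolumesCm3") <- vc * voxVol / 1000
  attr(case, "trueFoci") <- nf
  case
}
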