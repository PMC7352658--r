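#' Compartment volumes in cubic centimetres
#'
#' Volume = voxel count x voxel volume (mm^3), converted to cm^3. A warning
#' is raised when the voxel grid is strongly anisotropic (max/min spacing
#' ratio above 5), where simple voxel counting becomes a poor volume
#' estimate.
#'
#' @param case a [SegmentationCase-class]
#' @return named numeric vector: enhancingCm3, necroticCm3, edemaCm3
#' @export
compartmentVolumes <- function(case) {
  stopifnot(is(case, "SegmentationCase"))
  sp <- voxelSpacing(case)
  if (max(sp) / min(sp) > 5)
    warning("strongly anisotropic voxels (max/min spacing > 5): ",
            "volumes may be inaccurate")
  voxVol <- prod(sp)
  comp <- compartments(case)
  v <- vapply(1:3, function(k) sum(comp == k) * voxVol / 1000, numeric(1))
  names(v) <- c("enhancingCm3", "necroticCm3", "edemaCm3")
  v
}

# neighbor offsets for 6/18/26-connectivity in 3D
connectivityOffsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  nrm <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1, "18" = nrm <= 2, "26" = rep(TRUE, nrow(off)),
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(off[keep, ])
}

# 3D connected-component labelling by iterative minimum-label propagation
# over the chosen neighborhood; converges in O(component diameter) sweeps.
labelComponents3d <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  if (all(lab == 0)) return(list(labels = lab, n = 0L))
  offs <- connectivityOffsets(connectivity)
  padded <- array(Inf, d + 2L)
  repeat {
    padded[] <- Inf
    padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- ifelse(mask, lab, Inf)
    best <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- padded[(2:(d[1] + 1L)) + offs[i, 1L],
                   (2:(d[2] + 1L)) + offs[i, 2L],
                   (2:(d[3] + 1L)) + offs[i, 3L]]
      best <- pmin(best, ifelse(mask & is.finite(sh), sh, best))
    }
    if (all(best == lab)) break
    lab <- best
  }
  ids <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], ids)
  list(labels = lab, n = length(ids))
}

#' Count enhancing tumor foci
#'
#' Number of connected components of the enhancing compartment, i.e. groups
#' of interconnected enhancing voxels (unifocal versus multifocal disease).
#' 26-connectivity is the default; 6- and 18-connectivity are available, and
#' the two differ exactly when components touch only diagonally.
#'
#' @param case a [SegmentationCase-class]
#' @param connectivity 6, 18 or 26
#' @return integer focus count
#' @export
countFoci <- function(case, connectivity = 26) {
  stopifnot(is(case, "SegmentationCase"))
  labelComponents3d(compartments(case) == 1L, connectivity)$n
}

deepRegionNames <- function() {
  c("corpus callosum", "periventricular", "basal ganglia", "thalamus",
    "brainstem", "cerebellum")
}

#' Location percentages of the main tumor mass
#'
#' For every voxel of the main tumor mass (enhancing + necrosis by default:
#' the tumor proper, excluding edema; `massDefinition = "enhancing"` narrows
#' to enhancing only) the co-registered atlas code is looked up and
#' classified as frontal, parietal, temporal, occipital, deep (corpus
#' callosum, periventricular regions, basal ganglia, thalamus, brainstem, or
#' cerebellum) or other (atlas does not cover the voxel). Percentages are of
#' the tumor-mass voxel count; when the atlas fully covers the mass the
#' lobar + deep percentages partition 100. `pctLeft` comes from the
#' laterality map in the same way.
#'
#' @param case a [SegmentationCase-class]
#' @param massDefinition "enhancing_necrosis" (default) or "enhancing"
#' @return named numeric vector pctFrontal, pctParietal, pctTemporal,
#'   pctOccipital, pctDeep, pctOther, pctLeft; all NA (with a warning) for an
#'   empty tumor mass
#' @export
locationPercentages <- function(case,
                                massDefinition = c("enhancing_necrosis",
                                                   "enhancing")) {
  stopifnot(is(case, "SegmentationCase"))
  massDefinition <- match.arg(massDefinition)
  comp <- compartments(case)
  mask <- if (massDefinition == "enhancing") comp == 1L
          else comp == 1L | comp == 2L
  out <- c(pctFrontal = NA_real_, pctParietal = NA_real_,
           pctTemporal = NA_real_, pctOccipital = NA_real_,
           pctDeep = NA_real_, pctOther = NA_real_, pctLeft = NA_real_)
  nTot <- sum(mask)
  if (nTot == 0L) {
    warning("empty tumor mass: location percentages undefined")
    return(out)
  }
  codes <- atlasVolume(case)[mask]
  region <- rep("other", nTot)
  known <- as.character(codes) %in% names(case@regionNames)
  region[known] <- unname(case@regionNames[as.character(codes[known])])
  region[region %in% deepRegionNames()] <- "deep"
  pct <- function(cls) 100 * sum(region == cls) / nTot
  side <- rep("other", nTot)
  knownSide <- as.character(codes) %in% names(case@laterality)
  side[knownSide] <- unname(case@laterality[as.character(codes[knownSide])])
  c(pctFrontal = pct("frontal"), pctParietal = pct("parietal"),
    pctTemporal = pct("temporal"), pctOccipital = pct("occipital"),
    pctDeep = pct("deep"), pctOther = pct("other"),
    pctLeft = 100 * sum(side == "left") / nTot)
}

#' Extract the full MR feature row for one case
#'
#' @param case a [SegmentationCase-class]
#' @param connectivity connectivity for [countFoci()]
#' @param massDefinition passed to [locationPercentages()]
#' @return one-row data.frame with compartment volumes, nFoci and location
#'   percentages
#' @export
mriFeatures <- function(case, connectivity = 26,
                        massDefinition = "enhancing_necrosis") {
  v <- compartmentVolumes(case)
  p <- suppressWarnings(locationPercentages(case, massDefinition))
  cbind(as.data.frame(as.list(v)),
        nFoci = countFoci(case, connectivity),
        as.data.frame(as.list(p)))
}
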