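#' Canonical H-DAB stain matrix
#'
#' The classical hematoxylin/DAB optical-density vectors (unit-normalized):
#' hematoxylin ~ (0.650, 0.704, 0.286), DAB ~ (0.269, 0.568, 0.778). These are
#' the standard published pair for brightfield H-DAB deconvolution; the
#' synthetic renderer uses the same matrix, which makes render/deconvolve an
#' exact round trip.
#'
#' @param hema,dab optional replacement OD 3-vectors (normalized internally)
#' @return a [StainMatrix-class] object
#' @examples
#' hdabStainMatrix()
#' @export
hdabStainMatrix <- function(hema = c(0.650, 0.704, 0.286),
                            dab = c(0.269, 0.568, 0.778)) {
  new("StainMatrix", hema = unitVec(hema), dab = unitVec(dab))
}

# 3x3 OD matrix whose rows are hema, dab and their (unit) cross product.
stainBasis <- function(stains) {
  third <- unitVec(crossProd3(stains@hema, stains@dab))
  rbind(stains@hema, stains@dab, third)
}

#' Convert RGB intensities to per-channel optical density
#'
#' OD = -log10((I + 1) / 256). The +1 offset and I0 = 256 avoid log(0) at
#' I = 0 and give OD ~ 0 for pure white (I = 255).
#'
#' @param rgb numeric array of intensities in [0, 255]
#' @return array of the same shape holding ODs
#' @export
rgbToOd <- function(rgb) -log10((rgb + 1) / 256)

#' Convert optical densities back to RGB intensities
#'
#' Inverse of [rgbToOd()]. With `quantize = TRUE` intensities are rounded to
#' the 8-bit grid (what a scanner delivers); `quantize = FALSE` keeps the
#' continuous values so that deconvolution recovers the input concentrations
#' to machine precision.
#'
#' @param od numeric array of optical densities
#' @param quantize round to integer 8-bit intensities (default TRUE)
#' @return array of intensities in [0, 255]
#' @export
odToRgb <- function(od, quantize = TRUE) {
  i <- 256 * 10^(-od) - 1
  i <- clamp(i, 0, 255)
  if (quantize) round(i) else i
}

#' Unmix hematoxylin and DAB stain concentrations
#'
#' Colour deconvolution in optical-density space: per-pixel OD (computed with
#' [rgbToOd()]) is projected onto the stain basis by the inverse of the
#' 3 x 3 stain matrix (hema, DAB, and their unit cross product as a residual
#' channel). Negative concentrations, which arise from noise, are clipped
#' to zero.
#'
#' @param tile a [StainedTile-class]
#' @param stains a [StainMatrix-class] (default: canonical H-DAB vectors)
#' @return list with matrices `hema` and `dab` of per-pixel stain
#'   concentrations (OD units)
#' @examples
#' tile <- simulateTile(tileConfig(nNegative = 5, nPositive = 2, seed = 1))$tile
#' maps <- deconvolveStains(tile)
#' range(maps$dab)
#' @export
deconvolveStains <- function(tile, stains = hdabStainMatrix()) {
  stopifnot(is(tile, "StainedTile"), is(stains, "StainMatrix"))
  M <- stainBasis(stains)
  if (abs(det(M)) < 1e-8)
    stop("stain vectors are collinear: deconvolution matrix is singular")
  od <- rgbToOd(rgbArray(tile))
  d <- dim(od)
  flat <- matrix(od, d[1] * d[2], 3L)          # pixels x channels
  conc <- flat %*% solve(M)                    # OD = C %*% M  =>  C = OD M^-1
  conc[conc < 0] <- 0
  list(hema = matrix(conc[, 1L], d[1], d[2]),
       dab  = matrix(conc[, 2L], d[1], d[2]))
}

#' Render stain-concentration maps to an RGB tile
#'
#' Beer-Lambert mixing: per-channel OD = cHema * vHema + cDab * vDab, then
#' OD to RGB via [odToRgb()]. The exact inverse of [deconvolveStains()] when
#' `quantize = FALSE`.
#'
#' @param hemaConc,dabConc matrices of stain concentrations (OD units)
#' @param stains a [StainMatrix-class]
#' @param pixelSizeUm physical pixel size attached to the tile
#' @param quantize round to the 8-bit intensity grid
#' @return a [StainedTile-class]
#' @export
renderConcentrations <- function(hemaConc, dabConc, stains = hdabStainMatrix(),
                                 pixelSizeUm = 0.92, quantize = TRUE) {
  stopifnot(identical(dim(hemaConc), dim(dabConc)))
  d <- dim(hemaConc)
  od <- outer(as.vector(hemaConc), stains@hema) +
        outer(as.vector(dabConc), stains@dab)
  rgb <- array(odToRgb(od, quantize = quantize), dim = c(d[1], d[2], 3L))
  new("StainedTile", rgb = rgb, pixelSizeUm = pixelSizeUm)
}
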