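#' Score one tissue core: percent positively stained cells
#'
#' The full scoring chain for one core: colour deconvolution into hematoxylin
#' and DAB concentration maps, dual Phansalkar/Otsu thresholding per channel,
#' neighbor-based background filtering, watershed splitting of touching
#' cells, then the score 100 * nDab / (nDab + nHema). The neighbor filter is
#' applied to the thresholded mask before watershed labelling because it acts
#' on pixels, not objects.
#'
#' With zero detected cells in both channels the score is flagged undefined
#' (NA), never reported as 0. `denominator = "hema"` switches to the raw
#' DAB+/hema+ cell ratio (in percent) for panels where every cell carries
#' counterstain.
#'
#' @param tile a [StainedTile-class]
#' @param stains a [StainMatrix-class]
#' @param params a [segmentationParams()] list
#' @param marker marker name recorded in the score (CD3, CD45ro, CD68, FoxP3)
#' @param denominator "all" (default; DAB+ cells over all detected cells) or
#'   "hema" (DAB+ over hematoxylin+ cells)
#' @return list with `score` ([ImmuneScore-class]), `dab` and `hema`
#'   ([CellDetection-class] per channel)
#' @examples
#' tl <- simulateTile(tileConfig(nNegative = 40, nPositive = 10, seed = 7))
#' res <- scoreCore(tl$tile, marker = "CD3")
#' percentPositive(res$score)
#' @export
scoreCore <- function(tile, stains = hdabStainMatrix(),
                      params = segmentationParams(), marker = "CD3",
                      denominator = c("all", "hema")) {
  denominator <- match.arg(denominator)
  maps <- deconvolveStains(tile, stains)
  detect <- lapply(maps, function(m) {
    mask <- suppressWarnings(segmentPositive(m, params))
    splitTouching(filterBackground(mask, params), params)
  })
  nDab <- cellCount(detect$dab)
  nHema <- cellCount(detect$hema)
  defined <- (nDab + nHema) > 0L &&
    !(denominator == "hema" && nHema == 0L)
  pct <- if (!defined) NA_real_
         else if (denominator == "all") 100 * nDab / (nDab + nHema)
         else 100 * nDab / nHema
  score <- new("ImmuneScore", marker = marker, nDab = nDab, nHema = nHema,
               percentPositive = pct, defined = defined)
  list(score = score, dab = detect$dab, hema = detect$hema)
}

#' Score a batch of cores into a tidy table
#'
#' @param tiles named list of [StainedTile-class] objects (names become
#'   core ids)
#' @param ... passed on to [scoreCore()]
#' @return data.frame with columns coreId, marker, nDab, nHema,
#'   percentPositive
#' @export
scoreCores <- function(tiles, ...) {
  stopifnot(length(tiles) > 0L)
  ids <- names(tiles)
  if (is.null(ids)) ids <- sprintf("core%02d", seq_along(tiles))
  rows <- lapply(seq_along(tiles), function(i) {
    s <- scoreCore(tiles[[i]], ...)$score
    data.frame(coreId = ids[i], marker = s@marker, nDab = s@nDab,
               nHema = s@nHema, percentPositive = s@percentPositive,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
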