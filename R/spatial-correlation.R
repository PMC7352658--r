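pearsonWithP <- function(x, y) {
  n <- length(x)
  if (n < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  p <- if (n >= 3L) {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tstat), df = n - 2)
  } else NA_real_
  c(r = r, p = p, n = n)
}

#' Correlate immune scores across multisector cores
#'
#' For every marker, all unordered within-patient core pairs (ordered by core
#' index, first member = lower index) are pooled across patients, and the
#' Pearson correlation of the paired scores with its two-sided p-value (t
#' distribution, nPairs - 2 df) quantifies how well one randomly placed core
#' predicts another from the same tumor. Patients contributing fewer than two
#' cores are skipped; with fewer than three pairs r is reported but p is
#' undefined.
#'
#' @param scores data.frame with columns patient, coreIndex, marker, percent
#' @return data.frame with one row per marker: marker, r, p, nPairs
#' @examples
#' sc <- data.frame(patient = rep(1:5, each = 2), coreIndex = rep(1:2, 5),
#'                  marker = "CD3", percent = runif(10, 5, 40))
#' multisectorCorrelation(sc)
#' @export
multisectorCorrelation <- function(scores) {
  stopifnot(all(c("patient", "coreIndex", "marker", "percent") %in%
                colnames(scores)))
  out <- lapply(split(scores, scores$marker), function(sm) {
    xs <- ys <- numeric(0)
    for (pd in split(sm, sm$patient)) {
      pd <- pd[order(pd$coreIndex), ]
      m <- nrow(pd)
      if (m < 2L) next
      for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
        xs <- c(xs, pd$percent[i]); ys <- c(ys, pd$percent[j])
      }
    }
    st <- pearsonWithP(xs, ys)
    data.frame(marker = sm$marker[1L], r = st[["r"]], p = st[["p"]],
               nPairs = as.integer(st[["n"]]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-correlate different markers scored on the same cores
#'
#' Pairwise Pearson correlations (with two-sided t-based p-values) between
#' marker columns measured on the same tissue cores. A constant marker has
#' no defined correlation and is flagged with NA.
#'
#' @param scores data.frame or matrix: rows = cores, columns = markers
#' @return data.frame markerA, markerB, r, p, n for all unordered pairs
#' @export
markerCrossCorrelation <- function(scores) {
  scores <- as.data.frame(scores)
  mk <- colnames(scores)
  if (nrow(scores) < 3L) stop("need at least 3 cores")
  rows <- list()
  for (i in seq_along(mk)[-length(mk)]) for (j in (i + 1L):length(mk)) {
    ok <- stats::complete.cases(scores[[i]], scores[[j]])
    st <- pearsonWithP(scores[[i]][ok], scores[[j]][ok])
    rows[[length(rows) + 1L]] <- data.frame(
      markerA = mk[i], markerB = mk[j], r = st[["r"]], p = st[["p"]],
      n = as.integer(st[["n"]]), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
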