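#' Iterative random-forest imputation of single missing entries
#'
#' Chained-equation imputation with a random-forest learner: missing entries
#' are initialized at the column mean (ordinal: snapped median), then each
#' incomplete column in turn is regressed on all the other columns with a
#' ranger forest fitted on its observed rows, and its missing entries are
#' replaced by predictions. Cycles repeat until the largest change, in units
#' of the column SD, drops below `tol` or `maxIter` is reached. Ordinal
#' columns are snapped back onto their grids at the end. Observed entries are
#' never altered; a complete table is returned unchanged. The forest seed and
#' single-threaded fitting make the result deterministic for a fixed seed.
#'
#' @param table data.frame to impute
#' @param columns numeric/ordinal columns to impute (default: all numeric
#'   columns with any NA)
#' @param ordinal named list of ordinal grids, e.g. list(ecog = 0:4)
#' @param seed RNG seed
#' @param maxIter maximum number of imputation cycles
#' @param tol convergence tolerance (change / column SD)
#' @param numTrees forest size per column and cycle
#' @return the table with missing entries filled in
#' @export
imputeMissing <- function(table, columns = NULL,
                          ordinal = list(ecog = 0:4), seed = 1L,
                          maxIter = 10L, tol = 1e-3, numTrees = 100L) {
  stopifnot(is.data.frame(table))
  numCols <- names(table)[vapply(table, is.numeric, logical(1))]
  if (is.null(columns))
    columns <- numCols[vapply(table[numCols], anyNA, logical(1))]
  if (!length(columns)) return(table)
  allMissing <- columns[vapply(table[columns], function(x) all(is.na(x)),
                               logical(1))]
  if (length(allMissing))
    stop("column(s) entirely missing, cannot impute: ",
         paste(allMissing, collapse = ", "))
  highMiss <- columns[colMeans(is.na(table[columns])) >= 0.5]
  if (length(highMiss))
    stop("column(s) with >= 50% missingness: ",
         paste(highMiss, collapse = ", "))
  predictors <- setdiff(numCols, character(0))
  obsMask <- !is.na(table[predictors])
  work <- table
  # mean initialization
  for (v in columns) {
    mu <- mean(work[[v]], na.rm = TRUE)
    work[[v]][is.na(work[[v]])] <- mu
  }
  # least-missing columns first: their early refits feed the worse ones
  columns <- columns[order(colSums(!obsMask[, columns, drop = FALSE]))]
  sds <- vapply(work[columns], stats::sd, numeric(1))
  sds[sds == 0] <- 1
  set.seed(seed)
  colSeeds <- stats::setNames(sample.int(2^30, length(columns)), columns)
  for (iter in seq_len(maxIter)) {
    delta <- 0
    for (v in columns) {
      miss <- !obsMask[, v]
      others <- setdiff(predictors, v)
      fit <- ranger::ranger(
        x = work[!miss, others, drop = FALSE], y = work[[v]][!miss],
        num.trees = numTrees, seed = colSeeds[[v]] + iter,
        num.threads = 1L)
      pred <- stats::predict(
        fit, data = work[miss, others, drop = FALSE],
        num.threads = 1L)$predictions
      delta <- max(delta, max(abs(pred - work[[v]][miss]) / sds[[v]]))
      work[[v]][miss] <- pred
    }
    if (delta < tol) break
  }
  for (v in intersect(names(ordinal), columns)) {
    miss <- !obsMask[, v]
    work[[v]][miss] <- snapToGrid(work[[v]][miss], ordinal[[v]])
  }
  # a snapped ordinal column that came in as integer goes out as integer
  for (v in columns)
    if (is.integer(table[[v]]) && all(work[[v]] == round(work[[v]])))
      work[[v]] <- as.integer(work[[v]])
  work
}
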