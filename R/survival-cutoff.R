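#' Survival-optimal cutoff by exhaustive split search
#'
#' The recursive-partitioning idea reduced to its first split: every midpoint
#' between consecutive sorted unique values of the variable is scanned
#' (ascending), splits leaving fewer than `minLeaf` subjects on either side
#' are discarded, and the split maximizing the log-rank statistic is
#' returned (on ties, the first one encountered in the ascending scan).
#' The resulting statistic is maximally selected: its nominal chi-square
#' p-value is anti-conservative and is reported for ranking only, not as a
#' calibrated significance level.
#'
#' @param x numeric/ordinal variable
#' @param times follow-up times
#' @param events event indicators
#' @param minLeaf minimum group size on each side of the split
#' @return list of class `CutoffResult`: `cutoff`, `statistic`, `p`
#'   (nominal), `nLow`, `nHigh`, `admissible`; when no admissible split
#'   exists (e.g. a constant variable) `admissible` is FALSE and the other
#'   fields are NA
#' @export
optimalCutoff <- function(x, times, events, minLeaf = 5L) {
  stopifnot(length(x) == length(times))
  ok <- !is.na(x)
  x <- x[ok]; times <- times[ok]; events <- events[ok]
  ux <- sort(unique(x))
  none <- structure(list(cutoff = NA_real_, statistic = NA_real_,
                         p = NA_real_, nLow = NA_integer_,
                         nHigh = NA_integer_, admissible = FALSE),
                    class = "CutoffResult")
  if (length(ux) < 2L || sum(events) < 1L) return(none)
  mids <- (ux[-1L] + ux[-length(ux)]) / 2
  best <- none
  for (m in mids) {
    hi <- x > m
    nLow <- sum(!hi); nHigh <- sum(hi)
    if (nLow < minLeaf || nHigh < minLeaf) next
    if (sum(events[hi]) + sum(events[!hi]) < 1L) next
    lr <- tryCatch(logrankTest(times, events, hi), error = function(e) NULL)
    if (is.null(lr)) next
    if (!isTRUE(best$admissible) || lr$chi2 > best$statistic)
      best <- structure(list(cutoff = m, statistic = lr$chi2, p = lr$p,
                             nLow = nLow, nHigh = nHigh, admissible = TRUE),
                        class = "CutoffResult")
  }
  best
}

#' @export
print.CutoffResult <- function(x, ...) {
  if (x$admissible)
    cat(sprintf(
      "Optimal cutoff %.4g (log-rank chi2 %.3g, nominal p %.3g; n %d/%d)\n",
      x$cutoff, x$statistic, x$p, x$nLow, x$nHigh))
  else cat("No admissible split\n")
  invisible(x)
}

#' Univariable survival screen across sex strata
#'
#' For each candidate variable and each stratum (female, male, all), the
#' stratum's own optimal cutoff is determined with [optimalCutoff()] and the
#' log-rank p at that cutoff is recorded. A variable is selected when its p
#' falls below `alpha` in any stratum. The cutoff-selected p-values are
#' maximally selected and therefore inflated; the screen is deliberately
#' permissive (candidate selection for multivariable modelling), and no
#' multiplicity correction is applied.
#'
#' @param table cohort data.frame with `sex`, `osMonths`, `event`
#' @param variables candidate variable names
#' @param alpha selection threshold (default 0.1)
#' @param minLeaf passed to [optimalCutoff()]
#' @return list: `selected` (character), `detail` (data.frame variable,
#'   stratum, cutoff, chi2, p), `cutoffs` (nested list
#'   cutoffs[[stratum]][[variable]])
#' @export
univariableScreen <- function(table, variables, alpha = 0.1, minLeaf = 5L) {
  strata <- list(female = table[table$sex == "female", ],
                 male = table[table$sex == "male", ],
                 all = table)
  detail <- list()
  cutoffs <- list()
  for (sx in names(strata)) {
    sub <- strata[[sx]]
    cutoffs[[sx]] <- list()
    for (v in variables) {
      co <- optimalCutoff(sub[[v]], sub$osMonths, sub$event, minLeaf)
      cutoffs[[sx]][[v]] <- co
      detail[[length(detail) + 1L]] <- data.frame(
        variable = v, stratum = sx,
        cutoff = co$cutoff, chi2 = co$statistic, p = co$p,
        stringsAsFactors = FALSE)
    }
  }
  detail <- if (length(detail)) do.call(rbind, detail)
            else data.frame(variable = character(0), stratum = character(0),
                            cutoff = numeric(0), chi2 = numeric(0),
                            p = numeric(0))
  sel <- unique(detail$variable[!is.na(detail$p) & detail$p < alpha])
  list(selected = sel, detail = detail, cutoffs = cutoffs)
}
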