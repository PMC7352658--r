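#' Restrict a cohort to the homogeneous survival-analysis subset
#'
#' Keeps patients with an intact immune status who received first-line
#' chemotherapy (immuneDeficient == FALSE and chemo == TRUE); patients with
#' either flag missing cannot be verified to qualify and are excluded with a
#' warning.
#'
#' @param table cohort data.frame with logical columns `immuneDeficient` and
#'   `chemo`
#' @return the filtered data.frame
#' @export
filterSurvivalCohort <- function(table) {
  stopifnot(all(c("immuneDeficient", "chemo") %in% names(table)))
  flagNA <- is.na(table$immuneDeficient) | is.na(table$chemo)
  if (any(flagNA))
    warning(sum(flagNA), " row(s) with missing immune/chemotherapy flag ",
            "excluded")
  keep <- !flagNA & !table$immuneDeficient & table$chemo
  if (!any(keep)) stop("no patients pass the survival-cohort filter")
  table[keep, , drop = FALSE]
}

#' Kaplan-Meier product-limit curve
#'
#' Wraps `survival::survfit`. The median is the earliest time at which the
#' survival curve reaches 0.5 or below; when the curve never crosses 0.5
#' (e.g. a single censored observation, or few events) the median is
#' undefined ("not reached") and reported as NA.
#'
#' @param times follow-up times (months), >= 0
#' @param events logical/0-1 event indicator (TRUE = death observed)
#' @return list of class `SurvivalCurve`: `time`, `surv`, `nRisk`,
#'   `medianOsMonths`, `fit` (the survfit object)
#' @export
kmFit <- function(times, events) {
  stopifnot(all(times >= 0), length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
                 medianOsMonths = if (is.na(med)) NA_real_ else med,
                 fit = fit),
            class = "SurvivalCurve")
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, median OS %s\n",
              x$fit$n, sum(x$fit$n.event),
              if (is.na(x$medianOsMonths)) "not reached"
              else sprintf("%.3g months", x$medianOsMonths)))
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Standard log-rank statistic (`survival::survdiff`, rho = 0), referred to
#' a chi-square distribution with (number of groups - 1) degrees of freedom.
#'
#' @param times follow-up times
#' @param events event indicators
#' @param group group membership (factor or coercible)
#' @return list: `chi2`, `df`, `p`
#' @export
logrankTest <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (any(table(group) == 0L)) stop("empty group")
  if (sum(events) < 1L) stop("need at least one event")
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ group)
  df <- nlevels(group) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
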