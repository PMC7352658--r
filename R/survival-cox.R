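#' Backward-eliminated Cox proportional-hazards model
#'
#' Fits a Cox model (partial likelihood, Efron tie handling) on the given
#' variables, then iteratively removes the term with the highest Wald
#' p-value while that p is at or above `retentionAlpha` (default 0.1, under
#' which a term with p = 0.091 is retained). Variables can enter either
#' dichotomized at a survival-tree cutoff (coding
#' `list(type = "dichotomized", cutoff = v)`, reported as variable > cutoff)
#' or continuous per unit increase (the default). Hazard ratios are
#' exp(coefficient) with Wald 95 percent confidence intervals.
#'
#' @param table data.frame with `osMonths`, `event` and the variables
#' @param variables candidate variable names, in entry order (elimination is
#'   deterministic given this order and the data)
#' @param retentionAlpha drop terms while their p >= this value
#' @param codingMap named list of codings; variables absent from the map are
#'   entered continuous
#' @return a [CoxResult-class]
#' @examples
#' coh <- simulateCohort(cohortConfig(seed = 5,
#'   logHazard = c(ageYears = 0.04)))
#' coxBackward(coh, c("ageYears", "cd3"))
#' @export
coxBackward <- function(table, variables, retentionAlpha = 0.1,
                        codingMap = list()) {
  stopifnot(all(variables %in% names(table)),
            all(c("osMonths", "event") %in% names(table)))
  codeOf <- function(v) {
    cm <- codingMap[[v]]
    if (is.null(cm) || identical(cm$type, "continuous"))
      list(label = "continuous_per_unit", x = as.numeric(table[[v]]))
    else if (identical(cm$type, "dichotomized"))
      list(label = sprintf("dichotomized_at_%.4g", cm$cutoff),
           x = as.numeric(table[[v]] > cm$cutoff))
    else stop("unknown coding type for ", v)
  }
  codes <- lapply(variables, codeOf)
  names(codes) <- variables
  X <- as.data.frame(lapply(codes, `[[`, "x"))
  names(X) <- variables
  dat <- cbind(data.frame(.time = table$osMonths,
                          .event = as.integer(table$event)), X)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  nEvents <- sum(dat$.event)
  current <- variables
  eliminated <- character(0)
  fit <- NULL
  while (length(current)) {
    if (nEvents < 5 * length(current))
      warning(sprintf("only %d events for %d terms (< 5 per term)",
                      nEvents, length(current)))
    fm <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", current), collapse = " + ")))
    fit <- survival::coxph(fm, data = dat, ties = "efron")
    if (!fit$iter < 100 && is.na(fit$loglik[2L]))
      stop("Cox model failed to converge for terms: ",
           paste(current, collapse = ", "))
    sm <- summary(fit)
    if (any(abs(stats::coef(fit)) > 15))
      warning("possible separation: |coefficient| > 15 for ",
              paste(current[abs(stats::coef(fit)) > 15], collapse = ", "))
    ps <- sm$coefficients[, "Pr(>|z|)"]
    worst <- which.max(ps)
    if (ps[worst] >= retentionAlpha) {
      eliminated <- c(eliminated, current[worst])
      current <- current[-worst]
      fit <- NULL
    } else break
  }
  if (is.null(fit) || !length(current)) {
    terms <- data.frame(variable = character(0), coding = character(0),
                        hr = numeric(0), ciLow = numeric(0),
                        ciHigh = numeric(0), p = numeric(0))
    return(new("CoxResult", terms = terms, eliminated = eliminated,
               fit = NULL, n = nrow(dat), nEvents = as.integer(nEvents)))
  }
  sm <- summary(fit)
  cf <- sm$coefficients
  ci <- sm$conf.int
  terms <- data.frame(
    variable = current,
    coding = vapply(codes[current], `[[`, character(1), "label"),
    hr = unname(cf[, "exp(coef)"]),
    ciLow = unname(ci[, "lower .95"]),
    ciHigh = unname(ci[, "upper .95"]),
    p = unname(cf[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  new("CoxResult", terms = terms, eliminated = eliminated, fit = fit,
      n = nrow(dat), nEvents = as.integer(nEvents))
}
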