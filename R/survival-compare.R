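defaultVariableTypes <- function() {
  list(
    numeric = c("ageYears", "enhancingCm3", "necroticCm3", "edemaCm3",
                "pctDeep", "cd3", "cd45ro", "cd68", "foxp3"),
    ordinal = c("ecog", "nFoci"),
    nominal = c("immuneDeficient", "chemo", "mtx", "hdMtx", "radio",
                "rituximab", "polyChemo", "bsc"))
}

mwTest <- function(x, g) {
  xs <- split(x, g)
  useExact <- max(lengths(xs)) <= 20L && !any(duplicated(x))
  stats::wilcox.test(xs[[1L]], xs[[2L]], exact = useExact,
                     correct = !useExact)
}

#' Female-versus-male comparison table
#'
#' Per-variable comparison of the two sexes in Table-1 style: two-sample
#' t-tests for numerical variables (mean +/- SD descriptives), Mann-Whitney
#' U tests for ordinal variables (median and IQR; exact enumeration for
#' small untied samples, normal approximation with continuity correction
#' otherwise), and two-sided Fisher's exact tests on the 2 x 2 count table
#' for nominal variables (n and percent).
#'
#' @param table cohort data.frame with a `sex` column in \{female, male\}
#' @param types list with elements `numeric`, `ordinal`, `nominal` naming
#'   the columns of each kind; defaults to the packaged cohort dictionary,
#'   intersected with the columns present
#' @return data.frame: variable, type, female, male (formatted
#'   descriptives), statistic, p
#' @examples
#' coh <- simulateCohort(cohortConfig(seed = 2))
#' head(cohortCompare(coh))
#' @export
cohortCompare <- function(table, types = defaultVariableTypes()) {
  stopifnot("sex" %in% names(table))
  sex <- factor(table$sex, levels = c("female", "male"))
  if (any(table(sex) == 0L)) stop("both sexes must be present")
  types <- lapply(types, intersect, names(table))
  fmtNum <- function(x) sprintf("%.1f +/- %.1f", mean(x, na.rm = TRUE),
                                stats::sd(x, na.rm = TRUE))
  fmtOrd <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.3g (IQR %.3g-%.3g)", q[2L], q[1L], q[3L])
  }
  fmtNom <- function(x) sprintf("%d (%.1f%%)", sum(x, na.rm = TRUE),
                                100 * mean(x, na.rm = TRUE))
  rows <- list()
  addRow <- function(v, ty, fF, fM, stat, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = v, type = ty, female = fF, male = fM,
      statistic = stat, p = p, stringsAsFactors = FALSE)
  for (v in types$numeric) {
    x <- as.numeric(table[[v]])
    tt <- stats::t.test(x ~ sex)
    addRow(v, "numeric", fmtNum(x[sex == "female"]), fmtNum(x[sex == "male"]),
           unname(tt$statistic), tt$p.value)
  }
  for (v in types$ordinal) {
    x <- as.numeric(table[[v]])
    ok <- !is.na(x)
    wt <- mwTest(x[ok], sex[ok])
    addRow(v, "ordinal", fmtOrd(x[sex == "female"]), fmtOrd(x[sex == "male"]),
           unname(wt$statistic), wt$p.value)
  }
  for (v in types$nominal) {
    x <- as.logical(table[[v]])
    tab <- table(factor(x, levels = c(TRUE, FALSE)), sex)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    addRow(v, "nominal", fmtNom(x[sex == "female"]), fmtNom(x[sex == "male"]),
           NA_real_, ft$p.value)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Two-sided Fisher's exact test from 2 x 2 counts
#'
#' Convenience wrapper for recomputing printed cohort-table p-values from
#' counts: `fisherFromCounts(13, 41, 3, 33)` tests 13/41 females versus
#' 3/33 males.
#'
#' @param aPos,aN positives and total in group A
#' @param bPos,bN positives and total in group B
#' @return two-sided p-value
#' @export
fisherFromCounts <- function(aPos, aN, bPos, bN) {
  stats::fisher.test(matrix(c(aPos, aN - aPos, bPos, bN - bPos), 2L),
                     alternative = "two.sided")$p.value
}
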