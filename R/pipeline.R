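cohortSchema <- function() {
  list(
    character = c("patientId", "sex"),
    logical = c("immuneDeficient", "chemo", "mtx", "hdMtx", "radio",
                "rituximab", "polyChemo", "bsc"),
    numeric = c("pctDeep", "enhancingCm3", "necroticCm3", "edemaCm3",
                "ageYears", "cd3", "cd45ro", "cd68", "foxp3", "osMonths"),
    integerish = c("nFoci", "ecog"),
    event = "event")
}

#' Validate a cohort table against the column dictionary
#'
#' Checks presence and type of every documented cohort column and enforces
#' the value domains (sex in female/male, ECOG on the 0-4 grid, percentages
#' in [0, 100], nonnegative volumes and follow-up times, age above 18).
#' Violations are collected per column with the offending rows named --
#' nothing is silently coerced.
#'
#' @param x a data.frame or a path to a cohort CSV
#' @return list with `ok` (logical), `errors` (character vector, empty when
#'   valid) and `table` (the typed table, or NULL when unreadable)
#' @export
validateCohortSchema <- function(x) {
  if (is.character(x)) {
    tab <- tryCatch(utils::read.csv(x, stringsAsFactors = FALSE),
                    error = function(e) NULL)
    if (is.null(tab))
      return(list(ok = FALSE, errors = paste("cannot read CSV:", x),
                  table = NULL))
  } else tab <- as.data.frame(x)
  sch <- cohortSchema()
  errors <- character(0)
  addErr <- function(msg) errors <<- c(errors, msg)
  rowsOf <- function(bad) paste(utils::head(which(bad), 5L), collapse = ", ")
  needed <- unlist(sch, use.names = FALSE)
  missing <- setdiff(needed, names(tab))
  if (length(missing)) addErr(paste("missing column(s):",
                                    paste(missing, collapse = ", ")))
  chk <- function(v, bad, what) {
    if (v %in% names(tab) && any(bad, na.rm = TRUE))
      addErr(sprintf("column %s: %s at row(s) %s", v, what, rowsOf(bad)))
  }
  if ("sex" %in% names(tab))
    chk("sex", !tab$sex %in% c("female", "male"), "sex not female/male")
  for (v in intersect(sch$logical, names(tab)))
    chk(v, !is.logical(tab[[v]]) & !tab[[v]] %in% c(TRUE, FALSE, 0, 1),
        "not logical")
  for (v in intersect(c(sch$numeric, sch$integerish), names(tab)))
    if (!is.numeric(tab[[v]])) addErr(sprintf("column %s: not numeric", v))
  numOk <- function(v) v %in% names(tab) && is.numeric(tab[[v]])
  if (numOk("ecog")) chk("ecog", !(tab$ecog %in% 0:4) & !is.na(tab$ecog),
                         "ECOG outside 0-4")
  if (numOk("nFoci")) chk("nFoci", tab$nFoci < 0 | tab$nFoci != round(tab$nFoci),
                          "focus count not a nonnegative integer")
  for (v in intersect(c("pctDeep", "cd3", "cd45ro", "cd68", "foxp3"),
                      names(tab)))
    if (numOk(v)) chk(v, tab[[v]] < 0 | tab[[v]] > 100,
                      "percentage outside [0, 100]")
  for (v in intersect(c("enhancingCm3", "necroticCm3", "edemaCm3",
                        "osMonths"), names(tab)))
    if (numOk(v)) chk(v, tab[[v]] < 0, "negative value")
  if (numOk("ageYears")) chk("ageYears", tab$ageYears <= 18,
                             "age must exceed 18")
  list(ok = length(errors) == 0L, errors = errors, table = tab)
}

stageHash <- function(...) {
  # content key for stage caching: serialize the stage inputs to a tempfile
  # and take its md5
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(...), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-to-report analysis pipeline
#'
#' Executes the stages in dependency order -- synthetic data generation, IHC
#' scoring, multisector correlation, MR feature extraction, sex-stratified
#' clustering, cohort comparison and survival modelling -- and writes one
#' output file per stage plus a final `report.json` into `outDir`. Each
#' stage's inputs are hashed; an unchanged stage whose output file already
#' exists is reused rather than recomputed, and a failing stage halts its
#' downstream stages (marked "skipped" in the report). The global seed fans
#' out deterministically per stage, so one seed fixes every stochastic
#' output.
#'
#' @param config named list (or path to a YAML file) with optional entries:
#'   `seed` (default 1), `outDir` (default tempdir), `stages` (character
#'   subset of synth, ihc, spatial, mri, cluster, compare, survive),
#'   `cohort` (list of [cohortConfig()] arguments), `nTiles` (IHC demo tile
#'   count), `kFemale`, `kMale`, `screenAlpha`, `retentionAlpha`
#' @return the report as a list (also written to `report.json`)
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (is.null(config$outDir)) file.path(tempdir(), "pcnsl-run")
            else config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  allStages <- c("synth", "ihc", "spatial", "mri", "cluster", "compare",
                 "survive")
  stages <- if (is.null(config$stages)) allStages
            else match.arg(config$stages, allStages, several.ok = TRUE)
  for (p in c(config$exclusionMaskPath))
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", p)
  report <- list(parameters = config, seed = seed, stages = list())
  failed <- FALSE

  runStage <- function(name, inputs, fun) {
    outFile <- file.path(outDir, paste0(name, ".rds"))
    keyFile <- file.path(outDir, paste0(name, ".key"))
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    key <- stageHash(name, inputs, seed)
    if (file.exists(outFile) && file.exists(keyFile) &&
        identical(readLines(keyFile, warn = FALSE), key)) {
      out <- readRDS(outFile)
      report$stages[[name]] <<- c(list(status = "cached", file = basename(outFile)),
                                  out$summary)
      return(out$value)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
      return(NULL)
    }
    saveRDS(res, outFile)
    writeLines(key, keyFile)
    report$stages[[name]] <<- c(list(status = "ok", file = basename(outFile)),
                                res$summary)
    res$value
  }

  cohortArgs <- if (is.null(config$cohort)) list() else config$cohort
  cohort <- NULL
  if ("synth" %in% stages) {
    cohort <- runStage("synth", cohortArgs, function() {
      cfg <- do.call(cohortConfig,
                     c(cohortArgs, list(seed = deriveSeed(seed, "synth"))))
      coh <- simulateCohort(cfg)
      utils::write.csv(coh, file.path(outDir, "cohort.csv"),
                       row.names = FALSE)
      list(value = coh, summary = list(n = nrow(coh)))
    })
  }
  if ("ihc" %in% stages && !is.null(cohort)) {
    nTiles <- if (is.null(config$nTiles)) 3L else as.integer(config$nTiles)
    runStage("ihc", nTiles, function() {
      tiles <- lapply(seq_len(nTiles), function(i)
        simulateTile(tileConfig(
          nNegative = 60L, nPositive = 8L * i,
          seed = deriveSeed(seed, paste0("ihc", i))))$tile)
      names(tiles) <- sprintf("demo%02d", seq_len(nTiles))
      sc <- scoreCores(tiles)
      utils::write.csv(sc, file.path(outDir, "ihc_scores.csv"),
                       row.names = FALSE)
      list(value = sc,
           summary = list(meanPercent = mean(sc$percentPositive)))
    })
  }
  if ("spatial" %in% stages && !is.null(cohort)) {
    runStage("spatial", cohortArgs, function() {
      ms <- simulateMultisector(26, 2, seed = deriveSeed(seed, "spatial"),
                                render = FALSE)
      scores <- data.frame(
        patient = rep(seq_len(26), each = 2L),
        coreIndex = rep(1:2, 26),
        marker = "CD3",
        percent = 100 * as.vector(t(ms$fractions)))
      mr <- multisectorCorrelation(scores)
      utils::write.csv(mr, file.path(outDir, "multisector.csv"),
                       row.names = FALSE)
      list(value = mr, summary = list(r = mr$r[1L]))
    })
  }
  mri <- NULL
  if ("mri" %in% stages && !is.null(cohort)) {
    mri <- runStage("mri", list(), function() {
      case <- simulateSegmentationCase(
        plantedFoci = list(list(center = c(20, 32, 32), radiusMm = 8,
                                compartment = 1),
                           list(center = c(45, 32, 32), radiusMm = 6,
                                compartment = 3)))
      feats <- mriFeatures(case)
      utils::write.csv(feats, file.path(outDir, "mri_features.csv"),
                       row.names = FALSE)
      list(value = feats, summary = list(nFoci = feats$nFoci))
    })
  }
  clus <- NULL
  if ("cluster" %in% stages && !is.null(cohort)) {
    clus <- runStage("cluster",
                     list(config$kFemale, config$kMale), function() {
      res <- sexStratifiedClustering(
        cohort,
        kFemale = if (is.null(config$kFemale)) 3L else config$kFemale,
        kMale = if (is.null(config$kMale)) 3L else config$kMale,
        seed = deriveSeed(seed, "cluster"))
      out <- list(
        female = list(assignments = as.list(assignments(res$female)),
                      excluded = excludedClusters(res$female)),
        male = list(assignments = as.list(assignments(res$male)),
                    excluded = excludedClusters(res$male)))
      jsonlite::write_json(out, file.path(outDir, "clusters.json"),
                           auto_unbox = TRUE)
      list(value = res,
           summary = list(kFemale = res$female@k, kMale = res$male@k))
    })
  }
  if ("compare" %in% stages && !is.null(cohort)) {
    runStage("compare", list(), function() {
      cmp <- cohortCompare(imputeOrDrop(cohort))
      utils::write.csv(cmp, file.path(outDir, "cohort_compare.csv"),
                       row.names = FALSE)
      list(value = cmp, summary = list(nVariables = nrow(cmp)))
    })
  }
  if ("survive" %in% stages && !is.null(cohort)) {
    runStage("survive", list(config$screenAlpha, config$retentionAlpha),
             function() {
      tab <- if (!is.null(clus)) clus$imputed
             else imputeMissing(cohort, seed = deriveSeed(seed, "impute"))
      surv <- filterSurvivalCohort(tab)
      screen <- univariableScreen(
        surv, clusteringFeatures(),
        alpha = if (is.null(config$screenAlpha)) 0.1
                else config$screenAlpha)
      cox <- if (length(screen$selected))
        coxBackward(surv, screen$selected,
                    retentionAlpha = if (is.null(config$retentionAlpha)) 0.1
                                     else config$retentionAlpha)
      else NULL
      km <- kmFit(surv$osMonths, surv$event)
      out <- list(
        n = nrow(surv), medianOsMonths = km$medianOsMonths,
        screened = screen$selected,
        cox = if (!is.null(cox)) coxTerms(cox))
      jsonlite::write_json(out, file.path(outDir, "survival.json"),
                           auto_unbox = TRUE, digits = 6)
      utils::write.csv(screen$detail,
                       file.path(outDir, "univariable_screen.csv"),
                       row.names = FALSE)
      list(value = out, summary = out[c("n", "medianOsMonths")])
    })
  }
  report$outDir <- outDir
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 6, null = "null",
                       force = TRUE)
  invisible(report)
}

# comparisons tolerate NA; imputation is only needed for modelling stages
imputeOrDrop <- function(tab) tab
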