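## End-to-end pipeline: simulate/load -> preprocess -> FC -> kernels ->
## variance component fits -> jackknife inference -> report.

#' Read a pipeline configuration file
#'
#' YAML (or JSON) values override the defaults of [defaultCohortConfig()].
#'
#' @param path configuration file.
#' @return configuration list.
#' @export
readConfig <- function(path) {
  loaded <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(defaultCohortConfig(), loaded)
  if (!is.null(loaded$networkSizes))
    cfg$networkSizes <- unlist(loaded$networkSizes)
  cfg
}

.stageTimer <- function() {
  t0 <- proc.time()[["elapsed"]]
  function() round(proc.time()[["elapsed"]] - t0, 2)
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort generation (or loading), motion censoring, nuisance
#' regression, static and dynamic FC estimation, similarity kernels,
#' single- and two-kernel variance component fits, jackknife comparisons
#' (overall, per measure, category contrasts and interaction), the
#' network-block restricted fits and the block-pair contribution analysis,
#' and writes `report.json`, `manifest.json` and flat result tables under
#' `outDir`.
#'
#' @param config configuration list (see [defaultCohortConfig()]) or a path
#'   accepted by [readConfig()].
#' @param outDir output directory.
#' @param cohortDir optional existing cohort bundle; when NULL a synthetic
#'   cohort is generated under `outDir/cohort` from `config`.
#' @param censoring apply motion censoring (FALSE mirrors the uncensored
#'   control analysis).
#' @param regressGlobal regress the global mean signal (FALSE mirrors the
#'   no-global-signal-regression control analysis).
#' @param measures optional subset of measure names to analyse.
#' @param contributionLevel `"network"` or `"subnetwork"` blocks for the
#'   contribution analysis.
#' @param verbose log stage progress to stderr.
#' @return (invisibly) the report list.
#' @export
runAll <- function(config = defaultCohortConfig(), outDir,
                   cohortDir = NULL, censoring = TRUE, regressGlobal = TRUE,
                   measures = NULL, contributionLevel = "network",
                   verbose = TRUE) {
  if (is.character(config)) config <- readConfig(config)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  say <- function(...) if (verbose) message("[fcvcm] ", ...)
  timings <- list()

  ## stage 1: cohort --------------------------------------------------------
  tm <- .stageTimer()
  if (is.null(cohortDir)) {
    cohortDir <- file.path(outDir, "cohort")
    say("generating synthetic cohort (seed ", config$seed, ")")
    buildCohort(config, cohortDir, verbose = FALSE)
  }
  cohort <- loadCohort(cohortDir)
  parc <- cohort$parcellation
  timings$cohort <- tm()
  say("cohort ready: ", length(cohort$runs), " subjects (",
      timings$cohort, "s)")

  ## stage 2: preprocessing and FC -----------------------------------------
  tm <- .stageTimer()
  pp <- lapply(cohort$runs, .subjectPreprocess, censoring = censoring,
               regressGlobal = regressGlobal)
  used <- which(!vapply(pp, is.null, logical(1)))
  if (length(used) < length(pp))
    say(length(pp) - length(used), " subject(s) dropped: all runs failed QC")
  fcStatic <- lapply(pp[used], `[[`, "static")
  fcDynamic <- lapply(pp[used], `[[`, "dynamic")
  r2 <- vapply(pp[used], function(x) modelR2(x$dynamic), numeric(1))
  censFrac <- vapply(pp[used], `[[`, numeric(1), "censoredFraction")
  timings$fc <- tm()
  say("FC estimated: mean AR R2 = ", round(mean(r2), 3), " (", timings$fc, "s)")

  ## stage 3: kernels -------------------------------------------------------
  tm <- .stageTimer()
  kDyn <- fcSimilarityKernel(fcDynamic)
  kStat <- fcSimilarityKernel(fcStatic)
  FD <- similarityMatrix(kDyn)
  FS <- similarityMatrix(kStat)
  timings$kernels <- tm()

  ## stage 4: behavior ------------------------------------------------------
  tm <- .stageTimer()
  bm <- cohort$behavior[, used]
  bmp <- prepareBehavior(bm)
  if (!is.null(measures)) bmp <- bmp[measures, ]
  Y <- behaviorValues(bmp)
  categories <- unname(measureCategories(bmp))
  timings$behavior <- tm()

  ## stage 5: variance component fits --------------------------------------
  tm <- .stageTimer()
  fitStat <- fitVCM(Y, list(static = FS))
  fitDyn <- fitVCM(Y, list(dynamic = FD))
  fitComb <- fitVCM(Y, list(dynamic = FD,
                            static = FS))
  timings$fits <- tm()
  say(sprintf("M(static) = %.3f, M(dynamic) = %.3f, M(combined) = %.3f (%ss)",
              fitStat@M, fitDyn@M, fitComb@M, timings$fits))

  ## stage 6: jackknife inference ------------------------------------------
  tm <- .stageTimer()
  cmpDS <- jackknifeCompare(Y, FD, FS,
                            categories = categories)
  cmpCD <- jackknifeCompare(Y, list(FD, FS),
                            FD, categories = categories)
  cmpCS <- jackknifeCompare(Y, list(FD, FS),
                            FS, categories = categories)
  ranking <- rankMeasures(cmpDS)
  timings$inference <- tm()
  say(sprintf("dynamic vs static: dM = %.3f (z = %.2f, p = %.3g) (%ss)",
              cmpDS@overall$estimate, cmpDS@overall$z, cmpDS@overall$p,
              timings$inference))

  ## stage 7: network-block fits -------------------------------------------
  tm <- .stageTimer()
  nets <- unique(networkLabels(parc))
  blocks <- list()
  for (a in seq_along(nets)) for (b in a:length(nets)) {
    within <- a == b
    kS <- fcSimilarityKernel(fcStatic, parc,
                             block = if (within) "within" else "between",
                             networks = if (within) nets[a] else nets[c(a, b)])
    kD <- fcSimilarityKernel(fcDynamic, parc,
                             block = if (within) "within" else "between",
                             networks = if (within) nets[a] else nets[c(a, b)])
    blocks[[length(blocks) + 1L]] <- data.frame(
      netA = nets[a], netB = nets[b],
      type = if (within) "within" else "between",
      M_static = fitVCM(Y, kS)@M, M_dynamic = fitVCM(Y, kD)@M)
  }
  blocks <- do.call(rbind, blocks)
  timings$blocks <- tm()
  say("network-block fits done (", timings$blocks, "s)")

  ## stage 8: block-pair contributions (dynamic FC, task measures) ---------
  tm <- .stageTimer()
  dec <- blockDecompositionKernels(fcDynamic, parc, level = contributionLevel)
  taskMeasures <- which(categories == "task")
  contributions <- blockContributions(
    Y, dec, measures = if (length(taskMeasures)) taskMeasures else NULL)
  timings$contributions <- tm()

  report <- list(
    nSubjects = length(used),
    config = config,
    qc = list(meanCensoredFraction = mean(censFrac),
              subjectsDropped = length(pp) - length(used),
              arR2 = list(mean = mean(r2), sd = stats::sd(r2))),
    varianceExplained = list(static = varianceExplained(fitStat),
                             dynamic = varianceExplained(fitDyn),
                             combined = varianceExplained(fitComb)),
    comparisons = list(
      dynamic_vs_static = c(cmpDS@overall,
                            list(contrasts = cmpDS@contrasts)),
      combined_vs_dynamic = cmpCD@overall,
      combined_vs_static = cmpCS@overall),
    ranking = ranking,
    blocks = blocks,
    contributions = contributions,
    truth = groundTruth(bm),
    timings = timings)

  jsonlite::write_json(report[setdiff(names(report), "timings")],
                       file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                       dataframe = "rows")
  jsonlite::write_json(list(config = config,
                            package = "fcvcm",
                            version = as.character(utils::packageVersion("fcvcm")),
                            timings = timings),
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  reportTables(report, outDir)
  invisible(report)
}

#' Write flat result tables from a pipeline report
#'
#' Produces TSV tables mirroring the figures' content: the overall
#' variance-explained bars, the per-measure ranking, the network-block
#' grid, the combined-model comparison, and the FDR-surviving block-pair
#' contribution edge list.
#'
#' @param report list returned by [runAll()].
#' @param dir output directory.
#' @return (invisibly) the vector of written paths.
#' @export
reportTables <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ve <- report$varianceExplained
  paths <- character(0)
  w <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(data.frame(model = c("static", "dynamic", "combined"),
               M = c(ve$static$M, ve$dynamic$M, ve$combined$M)),
    "overall_variance_explained.tsv")
  perMeasure <- data.frame(measure = names(ve$static$Mi),
                           Mi_static = unname(ve$static$Mi),
                           Mi_dynamic = unname(ve$dynamic$Mi),
                           Mi_combined = unname(ve$combined$Mi))
  w(perMeasure, "per_measure_variance_explained.tsv")
  w(report$ranking, "ranking.tsv")
  w(report$blocks, "network_blocks.tsv")
  w(report$contributions[report$contributions$significant, , drop = FALSE],
    "contribution_edges.tsv")
  invisible(paths)
}
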