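## Cohort bundle: default configuration, generation to disk, and loading.

#' Default synthetic cohort configuration
#'
#' Desk-scale cohort preserving the structure of a large resting-state
#' study at roughly one tenth per axis: 120 subjects, 40 ROIs in 8 networks
#' (two subnetworks each), 2 runs of 600 frames, and 24 behavioral measures
#' (10 task, 10 self-reported, 4 unclassified). Task measures load
#' preferentially on the dynamic-FC kernel; self-reported measures load
#' equally on both kernels.
#'
#' @param seed root seed; all stage seeds are derived from it.
#' @return named list of generation parameters.
#' @export
defaultCohortConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    nSubjects = 120L,
    networkSizes = c(VIS = 5L, SM = 5L, DATT = 5L, SAL = 5L,
                     LIM = 5L, FP = 5L, DMN = 5L, SUB = 5L),
    subnetworksPer = 2L,
    nRuns = 2L,
    nFrames = 600L,
    burnIn = 200L,
    targetRadius = 0.90,
    individualScale = 0.10,
    nLatentFactors = 3L,
    factorScale = 0.40,
    withinCoupling = 0.10,
    asymmetry = 0.05,
    censorTarget = 0.10,
    nTask = 10L, nSelf = 10L, nUnclassified = 4L,
    load = list(task = c(dynamic = 0.45, static = 0.00),
                self = c(dynamic = 0.04, static = 0.04),
                unclassified = c(dynamic = 0.03, static = 0.03)),
    covariateEffect = 0.2
  )
}

## Shared base AR matrix: unit self-memory, small within-network coupling,
## small fixed asymmetric part; subjects perturb and rescale this.
.baseARMatrix <- function(parcellation, withinCoupling, asymmetry, seed) {
  lab <- networkLabels(parcellation)
  R <- length(lab)
  A <- diag(1, R)
  for (l in unique(lab)) {
    i <- which(lab == l)
    if (length(i) > 1L)
      A[i, i] <- A[i, i] + withinCoupling / (length(i) - 1)
  }
  diag(A) <- 1
  set.seed(seed)
  A + asymmetry * matrix(stats::rnorm(R * R), R, R) / sqrt(R)
}

.sigmaDesign <- function(config) {
  cats <- rep(c("task", "self", "unclassified"),
              c(config$nTask, config$nSelf, config$nUnclassified))
  measure <- sprintf("%s_%02d", cats, unlist(lapply(
    c(task = config$nTask, self = config$nSelf,
      unclassified = config$nUnclassified), seq_len)))
  dynL <- vapply(cats, function(cc) config$load[[cc]]["dynamic"], numeric(1))
  statL <- vapply(cats, function(cc) config$load[[cc]]["static"], numeric(1))
  if (any(dynL + statL >= 1))
    stop("per-measure kernel loadings must sum to less than 1")
  list(categories = cats, measureNames = measure,
       sigmaC = list(dynamic = diag(dynL, length(cats)),
                     static = diag(statL, length(cats))),
       sigmaE = diag(1 - dynL - statL, length(cats)))
}

.writeTSV <- function(x, path, rowNames = FALSE) {
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = rowNames, col.names = TRUE)
}

.subjectPreprocess <- function(runs, censoring = TRUE, regressGlobal = TRUE) {
  masks <- lapply(runs, function(r) {
    tr <- motionTraces(r)
    if (censoring && length(tr$fd)) computeCensorMask(tr$fd, tr$dvars)
    else allKeepMask(nrow(runData(r)))
  })
  ok <- vapply(masks, runPassesQC, logical(1))
  if (!any(ok)) return(NULL)
  runs <- runs[ok]; masks <- masks[ok]
  clean <- Map(regressNuisance, runs, masks,
               MoreArgs = list(regressGlobal = regressGlobal))
  list(static = staticFC(clean, masks), dynamic = dynamicFC(clean, masks),
       nRunsUsed = sum(ok), censoredFraction = mean(!unlist(lapply(masks, keepFrames))))
}

#' Generate a complete synthetic cohort bundle on disk
#'
#' Two-stage generation: (1) subject-specific stable AR(1) time series and
#' motion traces are simulated and run through the standard preprocessing
#' (censoring, nuisance regression, static/dynamic FC, similarity kernels);
#' (2) the behavioral matrix is drawn from the variance component model
#' conditional on those empirical kernels, so the true variance explained is
#' exact by construction. Everything is written as plain text under `dir`.
#'
#' Subject heterogeneity combines a low-rank component (a few shared
#' perturbation directions with standard-normal subject scores, scaled by
#' `factorScale`) with an idiosyncratic perturbation (`individualScale`);
#' the low-rank part is what gives the inter-subject similarity kernels a
#' realistic spread of off-diagonal values rather than a single
#' exchangeable similarity level.
#'
#' @param config configuration list, see [defaultCohortConfig()].
#' @param dir output directory (created if needed).
#' @param verbose print stage messages.
#' @return (invisibly) a list with the in-memory cohort: parcellation, per
#'   subject runs and FC, kernels, the raw [BehaviorMatrix-class] and the
#'   ground-truth list.
#' @export
buildCohort <- function(config = defaultCohortConfig(), dir, verbose = FALSE) {
  if (is.null(config$nSubjects) || config$nSubjects < 2L)
    stop("invalid config: need at least 2 subjects")
  if (config$nFrames < 20L) stop("invalid config: too few frames")
  seed <- config$seed
  for (d in c("", "timeseries", "motion"))
    if (!dir.exists(file.path(dir, d)) &&
        !dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", file.path(dir, d))

  parc <- makeParcellation(sum(config$networkSizes), config$networkSizes,
                           config$subnetworksPer)
  R <- nRoi(parc)
  baseA <- .baseARMatrix(parc, config$withinCoupling, config$asymmetry,
                         substreamSeed(seed, 1L))
  nLat <- if (is.null(config$nLatentFactors)) 0L else config$nLatentFactors
  set.seed(substreamSeed(seed, 2L))
  factorDirs <- lapply(seq_len(nLat), function(f)
    matrix(stats::rnorm(R * R), R, R) / sqrt(R))
  factorScores <- matrix(stats::rnorm(config$nSubjects * nLat),
                         config$nSubjects, nLat)
  innov <- diag(1, R)

  subjects <- sprintf("sub-%03d", seq_len(config$nSubjects))
  allRuns <- vector("list", config$nSubjects)
  fcStatic <- fcDynamic <- vector("list", config$nSubjects)
  r2 <- censFrac <- numeric(config$nSubjects)
  arSeeds <- integer(config$nSubjects)
  if (verbose) message("simulating ", config$nSubjects, " subjects x ",
                       config$nRuns, " runs of ", config$nFrames, " frames")
  for (s in seq_len(config$nSubjects)) {
    arSeeds[s] <- substreamSeed(seed, 100L + s)
    subjBase <- baseA
    if (nLat > 0L)
      subjBase <- subjBase + config$factorScale *
        Reduce(`+`, Map(`*`, factorDirs, factorScores[s, ]))
    A <- sampleSubjectAR(subjBase, config$individualScale,
                         config$targetRadius, arSeeds[s])
    runs <- vector("list", config$nRuns)
    for (r in seq_len(config$nRuns)) {
      ts <- simulateRun(A, innov, config$nFrames, burnIn = config$burnIn,
                        seed = substreamSeed(seed, 1000L + s * 10L + r),
                        runId = sprintf("run-%d", r))
      mo <- simulateMotion(config$nFrames, config$censorTarget,
                           seed = substreamSeed(seed, 5000L + s * 10L + r))
      run <- RunTimeSeries(runData(ts), fd = mo$fd, dvars = mo$dvars,
                           runId = sprintf("run-%d", r))
      .writeTSV(runData(run),
                file.path(dir, "timeseries",
                          sprintf("%s_run-%d.tsv", subjects[s], r)))
      .writeTSV(data.frame(FD = mo$fd, DVARS = mo$dvars),
                file.path(dir, "motion",
                          sprintf("%s_run-%d.tsv", subjects[s], r)))
      runs[[r]] <- run
    }
    allRuns[[s]] <- runs
    pp <- .subjectPreprocess(runs)
    if (is.null(pp)) stop("all runs discarded by QC for ", subjects[s],
                          " -- lower the censoring target")
    fcStatic[[s]] <- pp$static
    fcDynamic[[s]] <- pp$dynamic
    r2[s] <- modelR2(pp$dynamic)
    censFrac[s] <- pp$censoredFraction
  }

  if (verbose) message("building similarity kernels")
  kDyn <- fcSimilarityKernel(fcDynamic)
  kStat <- fcSimilarityKernel(fcStatic)

  if (verbose) message("drawing behavior from the variance component model")
  des <- .sigmaDesign(config)
  bm <- simulateBehavior(list(dynamic = kDyn, static = kStat), des$sigmaC,
                         des$sigmaE, seed = substreamSeed(seed, 7L),
                         categories = des$categories,
                         measureNames = des$measureNames)
  Y <- behaviorValues(bm)
  rownames(Y) <- subjects

  set.seed(substreamSeed(seed, 8L))
  covariates <- data.frame(
    age = sample(22:35, config$nSubjects, replace = TRUE),
    gender = factor(sample(c("F", "M"), config$nSubjects, replace = TRUE)),
    race = factor(sample(c("grp1", "grp2", "grp3"), config$nSubjects,
                         replace = TRUE)),
    education = sample(12:20, config$nSubjects, replace = TRUE),
    meanFD = vapply(allRuns, function(rs)
      mean(unlist(lapply(rs, function(r) motionTraces(r)$fd))), numeric(1)),
    row.names = subjects)
  if (config$covariateEffect > 0) {
    X <- stats::model.matrix(~ . - 1, data = covariates)
    X <- scale(X)
    X[, apply(X, 2, function(v) anyNA(v))] <- 0
    beta <- config$covariateEffect *
      matrix(stats::rnorm(ncol(X) * ncol(Y)), ncol(X), ncol(Y)) / sqrt(ncol(X))
    Y <- Y + X %*% beta
  }

  truth <- groundTruth(bm)
  truth$baseA <- baseA
  truth$arSeeds <- arSeeds
  truth$targetRadius <- config$targetRadius
  truth$individualScale <- config$individualScale
  truth$factorScores <- factorScores
  truth$fittedR2 <- r2
  truth$censoredFraction <- censFrac

  utils::write.csv(data.frame(subject = subjects, Y, check.names = FALSE),
                   file.path(dir, "behavior.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject = subjects, covariates,
                              check.names = FALSE),
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  .writeTSV(data.frame(measure = des$measureNames, category = des$categories),
            file.path(dir, "categories.tsv"))
  .writeTSV(data.frame(roi_id = parc@roiIds, network = parc@network,
                       subnetwork = parc@subnetwork),
            file.path(dir, "parcellation.tsv"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  jsonlite::write_json(list(config = config,
                            package = "fcvcm",
                            version = as.character(utils::packageVersion("fcvcm")),
                            subjects = subjects),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dir = dir, config = config, parcellation = parc,
                 runs = allRuns, fcStatic = fcStatic, fcDynamic = fcDynamic,
                 kernels = list(dynamic = kDyn, static = kStat),
                 behavior = BehaviorMatrix(Y, categories = des$categories,
                                           covariates = covariates,
                                           groundTruth = truth),
                 truth = truth))
}

#' Load a cohort bundle written by [buildCohort()]
#'
#' @param dir bundle directory.
#' @return list with `config`, `parcellation`, `runs` (per subject, list of
#'   [RunTimeSeries-class] with motion traces) and `behavior`
#'   (raw [BehaviorMatrix-class] with covariates and ground truth attached).
#' @export
loadCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  config <- manifest$config
  pt <- utils::read.table(file.path(dir, "parcellation.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  parc <- Parcellation(pt$roi_id, pt$network, pt$subnetwork)
  subjects <- manifest$subjects
  runs <- lapply(subjects, function(su) {
    lapply(seq_len(config$nRuns), function(r) {
      X <- as.matrix(utils::read.table(
        file.path(dir, "timeseries", sprintf("%s_run-%d.tsv", su, r)),
        header = TRUE, sep = "\t", check.names = FALSE))
      mo <- utils::read.table(
        file.path(dir, "motion", sprintf("%s_run-%d.tsv", su, r)),
        header = TRUE, sep = "\t")
      RunTimeSeries(X, fd = mo$FD, dvars = mo$DVARS,
                    runId = sprintf("run-%d", r))
    })
  })
  names(runs) <- subjects
  beh <- utils::read.csv(file.path(dir, "behavior.csv"), check.names = FALSE)
  Y <- as.matrix(beh[, -1, drop = FALSE])
  rownames(Y) <- beh$subject
  cv <- utils::read.csv(file.path(dir, "covariates.csv"))
  covariates <- cv[, -1, drop = FALSE]
  for (col in c("gender", "race"))
    if (col %in% names(covariates)) covariates[[col]] <- factor(covariates[[col]])
  rownames(covariates) <- cv$subject
  cats <- utils::read.table(file.path(dir, "categories.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  list(config = config, parcellation = parc, runs = runs,
       behavior = BehaviorMatrix(Y, categories = cats$category,
                                 covariates = covariates, groundTruth = truth))
}
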