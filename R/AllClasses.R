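#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges IRanges
#' @importFrom stats cor cov qnorm pnorm optimize rnorm runif rbinom rexp
#'   p.adjust sd lm.fit
#' @importFrom utils read.table write.table read.csv write.csv
NULL

.CATEGORY_LEVELS <- c("task", "self", "unclassified")

## ---------------------------------------------------------------------------
## Parcellation
## ---------------------------------------------------------------------------

#' Parcellation: ROI to resting-state-network assignment
#'
#' Ordered set of regions of interest (ROIs), each carrying exactly one
#' network label (e.g. VIS, SM, D-Att, Sal, Lim, FP, DMN, Sub) and optionally
#' a finer subnetwork label. The ROI order is shared by every FC matrix in an
#' analysis.
#'
#' @slot roiIds character vector of ROI identifiers (ordered).
#' @slot network character vector, one network label per ROI.
#' @slot subnetwork character vector, one subnetwork label per ROI.
#' @export
setClass("Parcellation",
  representation(roiIds = "character", network = "character",
                 subnetwork = "character"))

setValidity("Parcellation", function(object) {
  n <- length(object@roiIds)
  if (length(object@network) != n || length(object@subnetwork) != n)
    return("roiIds, network and subnetwork must have equal length")
  if (n < 2L) return("a parcellation needs at least two ROIs")
  if (anyNA(object@roiIds) || anyNA(object@network) || anyNA(object@subnetwork))
    return("labels must not contain NA")
  if (anyDuplicated(object@roiIds)) return("duplicated ROI ids")
  if (length(unique(object@network)) < 2L)
    return("labels must cover at least two networks")
  TRUE
})

#' Construct a Parcellation
#'
#' @param roiIds character vector of ROI identifiers, in matrix order.
#' @param network one network label per ROI.
#' @param subnetwork optional subnetwork label per ROI; defaults to `network`.
#' @return A [Parcellation-class] object.
#' @export
Parcellation <- function(roiIds, network, subnetwork = NULL) {
  if (is.null(subnetwork)) subnetwork <- network
  new("Parcellation", roiIds = as.character(roiIds),
      network = as.character(network), subnetwork = as.character(subnetwork))
}

setMethod("show", "Parcellation", function(object) {
  cat("Parcellation with", length(object@roiIds), "ROIs in",
      length(unique(object@network)), "networks (",
      length(unique(object@subnetwork)), "subnetworks )\n")
  print(table(factor(object@network, levels = unique(object@network))))
})

#' Number of ROIs in a parcellation
#' @param x a [Parcellation-class]
#' @export
nRoi <- function(x) length(x@roiIds)

#' Network (or subnetwork) labels of a parcellation
#' @param x a [Parcellation-class]
#' @param level `"network"` or `"subnetwork"`
#' @return character vector, one label per ROI.
#' @export
networkLabels <- function(x, level = c("network", "subnetwork")) {
  level <- match.arg(level)
  if (level == "network") x@network else x@subnetwork
}

## ---------------------------------------------------------------------------
## RunTimeSeries
## ---------------------------------------------------------------------------

#' One run of parcellated fMRI time series with its motion traces
#'
#' @slot data numeric matrix, frames x ROIs.
#' @slot fd framewise displacement per frame (mm); may be empty if unknown.
#' @slot dvars DVARS per frame (unitless); may be empty if unknown.
#' @slot runId character scalar.
#' @export
setClass("RunTimeSeries",
  representation(data = "matrix", fd = "numeric", dvars = "numeric",
                 runId = "character"))

setValidity("RunTimeSeries", function(object) {
  n <- nrow(object@data)
  if (anyNA(object@data)) return("time series contain missing values")
  if (!length(object@fd) %in% c(0L, n))
    return("fd length must equal the number of frames (or be empty)")
  if (!length(object@dvars) %in% c(0L, n))
    return("dvars length must equal the number of frames (or be empty)")
  if (length(object@fd) && anyNA(object@fd)) return("fd contains NA")
  if (length(object@dvars) && anyNA(object@dvars)) return("dvars contains NA")
  TRUE
})

#' Construct a RunTimeSeries
#'
#' @param data frames x ROIs numeric matrix.
#' @param fd,dvars per-frame motion traces (optional).
#' @param runId run identifier.
#' @return A [RunTimeSeries-class] object.
#' @export
RunTimeSeries <- function(data, fd = numeric(0), dvars = numeric(0),
                          runId = "run-1") {
  new("RunTimeSeries", data = as.matrix(data), fd = as.numeric(fd),
      dvars = as.numeric(dvars), runId = as.character(runId))
}

setMethod("show", "RunTimeSeries", function(object) {
  cat("RunTimeSeries", object@runId, ":", nrow(object@data), "frames x",
      ncol(object@data), "ROIs;",
      if (length(object@fd)) "with" else "without", "motion traces\n")
})

#' Frame data of a run
#' @param x a [RunTimeSeries-class]
#' @return frames x ROIs matrix.
#' @export
runData <- function(x) x@data

#' Motion traces of a run
#' @param x a [RunTimeSeries-class]
#' @return list with elements `fd` and `dvars`.
#' @export
motionTraces <- function(x) list(fd = x@fd, dvars = x@dvars)

## ---------------------------------------------------------------------------
## CensorMask
## ---------------------------------------------------------------------------

#' Frame censoring mask for one run
#'
#' Boolean keep-flag per frame, produced by [computeCensorMask()]. Kept frames
#' form maximal uncensored segments retrievable with [censorSegments()].
#'
#' @slot keep logical, TRUE for retained frames.
#' @slot fdThresh,dvarsThresh thresholds used.
#' @slot nBefore,nAfter,minSegment expansion and cleanup parameters used.
#' @export
setClass("CensorMask",
  representation(keep = "logical", fdThresh = "numeric",
                 dvarsThresh = "numeric", nBefore = "integer",
                 nAfter = "integer", minSegment = "integer"))

setValidity("CensorMask", function(object) {
  if (length(object@keep) == 0L) return("empty mask")
  if (anyNA(object@keep)) return("mask contains NA")
  TRUE
})

setMethod("show", "CensorMask", function(object) {
  n <- length(object@keep)
  cat(sprintf("CensorMask: %d/%d frames kept (%.1f%% censored)\n",
              sum(object@keep), n, 100 * mean(!object@keep)))
})

#' Keep-flags of a censor mask
#' @param x a [CensorMask-class]
#' @export
keepFrames <- function(x) x@keep

#' Maximal uncensored segments of a mask
#' @param x a [CensorMask-class]
#' @return An [IRanges::IRanges] of kept frame intervals.
#' @export
censorSegments <- function(x) {
  r <- rle(x@keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

#' All-keep mask of a given length
#'
#' Convenience constructor used when censoring is disabled.
#' @param n number of frames.
#' @export
allKeepMask <- function(n) {
  new("CensorMask", keep = rep(TRUE, n), fdThresh = Inf, dvarsThresh = Inf,
      nBefore = 0L, nAfter = 0L, minSegment = 1L)
}

## ---------------------------------------------------------------------------
## StaticFC / DynamicFC
## ---------------------------------------------------------------------------

#' Static functional connectivity (correlation matrix)
#'
#' Symmetric ROI x ROI Pearson correlation matrix with unit diagonal,
#' Fisher-z averaged over runs by [staticFC()].
#'
#' @slot fc correlation matrix.
#' @export
setClass("StaticFC", representation(fc = "matrix"))

setValidity("StaticFC", function(object) {
  M <- object@fc
  if (nrow(M) != ncol(M)) return("FC matrix must be square")
  if (anyNA(M)) return("FC matrix contains NA")
  if (max(abs(M - t(M))) > 1e-8) return("static FC must be symmetric")
  if (max(abs(diag(M) - 1)) > 1e-8) return("static FC must have unit diagonal")
  if (max(abs(M)) > 1 + 1e-8) return("correlations must lie in [-1, 1]")
  TRUE
})

#' Dynamic functional connectivity (first-order autoregressive model)
#'
#' The fitted model is `x_t = A x_{t-1} + e_t`; `A` is generally
#' non-symmetric. `r2` is the fraction of the Frobenius norm of the data
#' covariance not left in the innovation covariance.
#'
#' @slot A ROI x ROI coefficient matrix.
#' @slot residCov covariance of the residuals `e_t`.
#' @slot r2 model fit, `1 - ||Cov(e)||_F / ||Cov(x)||_F`.
#' @slot nPairs number of (t-1, t) frame pairs used.
#' @slot rank effective rank of the lagged predictor matrix (R minus the
#'   number of null directions, e.g. one after global-signal regression).
#' @export
setClass("DynamicFC",
  representation(A = "matrix", residCov = "matrix", r2 = "numeric",
                 nPairs = "integer", rank = "integer"),
  prototype(rank = NA_integer_))

setValidity("DynamicFC", function(object) {
  if (nrow(object@A) != ncol(object@A)) return("A must be square")
  if (!all(dim(object@residCov) == dim(object@A)))
    return("residCov must match A in dimension")
  if (object@r2 > 1 + 1e-8) return("r2 cannot exceed 1")
  if (object@nPairs <= nrow(object@A))
    return("need more frame pairs than ROIs for identification")
  TRUE
})

setMethod("show", "StaticFC", function(object) {
  cat("StaticFC:", nrow(object@fc), "x", ncol(object@fc),
      "correlation matrix\n")
})

setMethod("show", "DynamicFC", function(object) {
  cat(sprintf("DynamicFC: %d x %d AR(1) coefficient matrix, R2 = %.3f (%d frame pairs)\n",
              nrow(object@A), ncol(object@A), object@r2, object@nPairs))
})

#' Extract the connectivity matrix of an FC object
#'
#' Returns the correlation matrix of a [StaticFC-class] or the AR(1)
#' coefficient matrix of a [DynamicFC-class].
#' @param x an FC object.
#' @export
setGeneric("fcMatrix", function(x) standardGeneric("fcMatrix"))

#' @rdname fcMatrix
setMethod("fcMatrix", "StaticFC", function(x) x@fc)

#' @rdname fcMatrix
setMethod("fcMatrix", "DynamicFC", function(x) x@A)

#' Model fit of a dynamic FC model
#' @param x a [DynamicFC-class]
#' @export
modelR2 <- function(x) x@r2

#' Residual covariance of a dynamic FC model
#' @param x a [DynamicFC-class]
#' @export
residualCov <- function(x) x@residCov

## ---------------------------------------------------------------------------
## SimilarityKernel
## ---------------------------------------------------------------------------

#' Inter-subject FC similarity kernel
#'
#' Subjects x subjects matrix whose (i, j) entry is the Pearson correlation
#' between subject i's and subject j's vectorized FC patterns.
#'
#' @slot F similarity matrix (symmetric, unit diagonal, PSD up to numerical
#'   tolerance).
#' @slot mode `"static"` or `"dynamic"` (or `"custom"`).
#' @slot block description of the FC entries used (e.g. `"whole"`,
#'   `"within:DMN"`, `"between:DMN-FP"`).
#' @slot P length of the vectorized FC pattern.
#' @export
setClass("SimilarityKernel",
  representation(F = "matrix", mode = "character", block = "character",
                 P = "integer"))

setValidity("SimilarityKernel", function(object) {
  K <- object@F
  if (nrow(K) != ncol(K)) return("kernel must be square")
  if (anyNA(K)) return("kernel contains NA")
  if (max(abs(K - t(K))) > 1e-8) return("kernel must be symmetric")
  if (max(abs(diag(K) - 1)) > 1e-8) return("kernel must have unit diagonal")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(1, abs(ev[1]))
  if (min(ev) < -tol * max(1, nrow(K)))
    return("kernel is not positive semidefinite within tolerance")
  TRUE
})

setMethod("show", "SimilarityKernel", function(object) {
  cat(sprintf("SimilarityKernel (%s, %s): %d subjects, P = %d entries\n",
              object@mode, object@block, nrow(object@F), object@P))
})

#' Similarity matrix of a kernel
#' @param x a [SimilarityKernel-class]
#' @export
similarityMatrix <- function(x) x@F

## ---------------------------------------------------------------------------
## BehaviorMatrix (SummarizedExperiment: measures x subjects)
## ---------------------------------------------------------------------------

#' Subjects x measures behavioral data with categories and covariates
#'
#' Stored as a [SummarizedExperiment::SummarizedExperiment] with measures as
#' rows and subjects as columns; `rowData` holds the per-measure category
#' (task / self / unclassified) and `colData` the per-subject nuisance
#' covariates (age, gender, race, education, mean FD). Subsetting by subject
#' (`x[, idx]`) keeps all annotations aligned, which the jackknife relies on.
#'
#' @export
setClass("BehaviorMatrix", contains = "SummarizedExperiment")

setValidity("BehaviorMatrix", function(object) {
  Y <- SummarizedExperiment::assay(object)
  if (anyNA(Y)) return("behavioral matrix contains missing entries")
  rd <- SummarizedExperiment::rowData(object)
  if (!"category" %in% colnames(rd)) return("rowData must carry 'category'")
  if (!all(rd$category %in% .CATEGORY_LEVELS))
    return(paste("categories must be one of:",
                 paste(.CATEGORY_LEVELS, collapse = ", ")))
  TRUE
})

#' Construct a BehaviorMatrix
#'
#' @param Y subjects x measures numeric matrix (row names = subject ids,
#'   column names = measure names).
#' @param categories per-measure category, one of `"task"`, `"self"`,
#'   `"unclassified"`; defaults to all unclassified.
#' @param covariates optional per-subject data.frame of nuisance covariates.
#' @param groundTruth optional list of generative ground-truth values
#'   (stored in `metadata`).
#' @return A [BehaviorMatrix-class] object.
#' @export
BehaviorMatrix <- function(Y, categories = NULL, covariates = NULL,
                           groundTruth = NULL) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) rownames(Y) <- sprintf("sub-%03d", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("measure_%02d", seq_len(ncol(Y)))
  if (is.null(categories)) categories <- rep("unclassified", ncol(Y))
  if (length(categories) != ncol(Y))
    stop("need one category per measure")
  rd <- S4Vectors::DataFrame(category = as.character(categories),
                             row.names = colnames(Y))
  cd <- if (is.null(covariates)) {
    S4Vectors::DataFrame(row.names = rownames(Y))
  } else {
    if (nrow(covariates) != nrow(Y))
      stop("covariates must have one row per subject")
    S4Vectors::DataFrame(covariates, row.names = rownames(Y))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(behavior = t(Y)), rowData = rd, colData = cd,
    metadata = if (is.null(groundTruth)) list() else list(groundTruth = groundTruth))
  new("BehaviorMatrix", se)
}

setMethod("show", "BehaviorMatrix", function(object) {
  cat("BehaviorMatrix:", ncol(object), "subjects x", nrow(object),
      "measures\n  categories:",
      paste(sprintf("%s=%d", names(table(SummarizedExperiment::rowData(object)$category)),
                    table(SummarizedExperiment::rowData(object)$category)),
            collapse = ", "),
      "\n  covariates:",
      if (ncol(SummarizedExperiment::colData(object)))
        paste(colnames(SummarizedExperiment::colData(object)), collapse = ", ")
      else "none", "\n")
})

#' Behavioral values as a subjects x measures matrix
#' @param x a [BehaviorMatrix-class]
#' @export
behaviorValues <- function(x) t(SummarizedExperiment::assay(x))

#' Per-measure categories of a BehaviorMatrix
#' @param x a [BehaviorMatrix-class]
#' @export
measureCategories <- function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$category, rownames(x))
}

#' Per-subject covariates of a BehaviorMatrix
#' @param x a [BehaviorMatrix-class]
#' @return data.frame with one row per subject.
#' @export
subjectCovariates <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Generative ground truth attached to a BehaviorMatrix, if any
#' @param x a [BehaviorMatrix-class]
#' @export
groundTruth <- function(x) S4Vectors::metadata(x)$groundTruth

## ---------------------------------------------------------------------------
## VCMFit
## ---------------------------------------------------------------------------

#' Fitted variance component model
#'
#' Holds the moment estimates of the kernel variance components `Sigma_c`
#' (one measures x measures matrix per similarity kernel) and the residual
#' component `Sigma_e`, together with the derived variance-explained
#' summaries: overall `M`, per-measure `Mi`, and per-kernel trace shares.
#'
#' @slot sigmaC list of measures x measures matrices, one per kernel.
#' @slot sigmaE residual measures x measures matrix.
#' @slot M overall fraction of behavioral variance explained.
#' @slot Mi per-measure fractions.
#' @slot shares per-kernel share of the explained trace.
#' @slot kernelNames names of the kernels used.
#' @slot diagnostics list: raw (untruncated) diagonals, Gram matrix of the
#'   moment system and its condition number.
#' @export
setClass("VCMFit",
  representation(sigmaC = "list", sigmaE = "matrix", M = "numeric",
                 Mi = "numeric", shares = "numeric", kernelNames = "character",
                 diagnostics = "list"))

setMethod("show", "VCMFit", function(object) {
  cat(sprintf("VCMFit: %d kernel(s) [%s], %d measures\n  M = %.3f; kernel shares: %s\n",
              length(object@sigmaC), paste(object@kernelNames, collapse = ", "),
              length(object@Mi), object@M,
              paste(sprintf("%.2f", object@shares), collapse = ", ")))
})

#' Variance explained by a fitted variance component model
#'
#' @param fit a [VCMFit-class]
#' @return list with `M` (overall trace ratio), `Mi` (per-measure ratios) and
#'   `shares` (per-kernel share of the explained trace).
#' @export
varianceExplained <- function(fit) {
  stopifnot(is(fit, "VCMFit"))
  list(M = fit@M, Mi = fit@Mi, shares = fit@shares)
}

## ---------------------------------------------------------------------------
## JackknifeComparison
## ---------------------------------------------------------------------------

#' Delete-one jackknife comparison of two variance component models
#'
#' @slot overall list with the jackknife estimate, variance, z and p for the
#'   overall M difference (model A minus model B).
#' @slot perMeasure data.frame: per-measure M_i difference, jackknife SE, T
#'   statistic (z), p, category.
#' @slot contrasts data.frame of category contrasts (task mean, self mean,
#'   interaction), or NULL when categories are absent.
#' @slot leaveOne matrix of per-leave-out statistic values (subjects x
#'   statistics).
#' @slot nSubjects number of subjects.
#' @export
setClass("JackknifeComparison",
  representation(overall = "list", perMeasure = "data.frame",
                 contrasts = "data.frame", leaveOne = "matrix",
                 nSubjects = "integer"))

setMethod("show", "JackknifeComparison", function(object) {
  cat(sprintf("JackknifeComparison over %d subjects\n  overall dM = %.4f (z = %.2f, p = %.3g)\n",
              object@nSubjects, object@overall$estimate, object@overall$z,
              object@overall$p))
  if (nrow(object@contrasts)) {
    cat("  contrasts:\n")
    print(object@contrasts, digits = 3)
  }
})
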