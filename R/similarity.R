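## FC vectorization, inter-subject similarity kernels, and the additive
## network-block decomposition of the entry-standardized kernel.

.blockIndex <- function(parcellation, level, labels) {
  lab <- networkLabels(parcellation, level)
  idx <- lapply(labels, function(l) which(lab == l))
  bad <- labels[lengths(idx) == 0L]
  if (length(bad))
    stop("unknown or empty network label: ", paste(bad, collapse = ", "))
  idx
}

#' Vectorize an FC matrix (whole-brain or network block)
#'
#' Static (symmetric) matrices contribute their strict upper triangle;
#' dynamic (non-symmetric) AR coefficient matrices contribute all entries
#' including the diagonal, matching their respective degrees of freedom
#' (R(R-1)/2 vs R^2). Block restriction keeps only entries within one
#' network or between a pair of networks (for dynamic FC both directed
#' blocks are concatenated).
#'
#' @param fc a [StaticFC-class] or [DynamicFC-class].
#' @param parcellation a [Parcellation-class]; required unless
#'   `block = "whole"`.
#' @param block `"whole"`, `"within"` or `"between"`.
#' @param networks one network label for `"within"`, two for `"between"`.
#' @param level `"network"` or `"subnetwork"` labels.
#' @param fisherZ Fisher z-transform static correlations before vectorizing
#'   (off by default; r-space matrices are correlated as-is).
#' @return numeric vector.
#' @export
vectorizeFC <- function(fc, parcellation = NULL,
                        block = c("whole", "within", "between"),
                        networks = NULL, level = c("network", "subnetwork"),
                        fisherZ = FALSE) {
  block <- match.arg(block)
  level <- match.arg(level)
  symmetric <- is(fc, "StaticFC")
  if (!symmetric && !is(fc, "DynamicFC"))
    stop("fc must be a StaticFC or DynamicFC")
  M <- fcMatrix(fc)
  if (symmetric && fisherZ) {
    M <- atanh(pmin(pmax(M, -1 + 1e-12), 1 - 1e-12))
  }
  if (block == "whole") {
    if (symmetric) return(M[upper.tri(M)])
    return(as.vector(M))
  }
  if (is.null(parcellation))
    stop("block restriction requires a parcellation")
  if (nRoi(parcellation) != nrow(M))
    stop("FC dimension does not match the parcellation")
  if (block == "within") {
    if (length(networks) != 1L) stop("'within' needs exactly one network")
    i <- .blockIndex(parcellation, level, networks)[[1]]
    B <- M[i, i, drop = FALSE]
    if (symmetric) {
      if (length(i) < 2L) stop("empty within-network block")
      return(B[upper.tri(B)])
    }
    return(as.vector(B))
  }
  if (length(networks) != 2L || networks[1] == networks[2])
    stop("'between' needs two distinct networks")
  ij <- .blockIndex(parcellation, level, networks)
  if (symmetric)
    return(as.vector(M[ij[[1]], ij[[2]], drop = FALSE]))
  c(as.vector(M[ij[[1]], ij[[2]], drop = FALSE]),
    as.vector(M[ij[[2]], ij[[1]], drop = FALSE]))
}

#' Build an inter-subject similarity kernel from vectorized FC patterns
#'
#' `F(i, j)` is the Pearson correlation between subject i's and subject j's
#' FC vectors (each vector centered and scaled by its own mean and SD).
#'
#' @param vectors subjects x P matrix (or list of equal-length vectors).
#' @param mode provenance label, e.g. `"static"` or `"dynamic"`.
#' @param block provenance label for the block selector.
#' @return A [SimilarityKernel-class].
#' @export
buildKernel <- function(vectors, mode = "custom", block = "whole") {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop("need at least 2 subjects")
  sds <- apply(vectors, 1, stats::sd)
  if (any(sds == 0)) stop("constant FC vector: correlation undefined")
  K <- stats::cor(t(vectors))
  diag(K) <- 1
  new("SimilarityKernel", F = K, mode = mode, block = block,
      P = ncol(vectors))
}

#' Whole-brain or block-restricted similarity kernel from a set of FC objects
#'
#' Convenience wrapper: vectorizes each subject's FC with [vectorizeFC()] and
#' correlates subjects with [buildKernel()].
#'
#' @param fcList list of FC objects, one per subject (all the same class).
#' @inheritParams vectorizeFC
#' @return A [SimilarityKernel-class].
#' @export
fcSimilarityKernel <- function(fcList, parcellation = NULL, block = "whole",
                               networks = NULL,
                               level = c("network", "subnetwork"),
                               fisherZ = FALSE) {
  level <- match.arg(level)
  V <- t(vapply(fcList, vectorizeFC, parcellation = parcellation,
                block = block, networks = networks, level = level,
                fisherZ = fisherZ,
                FUN.VALUE = vectorizeFC(fcList[[1]], parcellation, block,
                                        networks, level, fisherZ)))
  mode <- if (is(fcList[[1]], "StaticFC")) "static" else "dynamic"
  blk <- if (block == "whole") "whole"
         else paste0(block, ":", paste(networks, collapse = "-"))
  buildKernel(V, mode = mode, block = blk)
}

.entryPairLabels <- function(parcellation, level, symmetric) {
  lab <- networkLabels(parcellation, level)
  R <- length(lab)
  if (symmetric) {
    ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
    a <- lab[ut[, 1]]; b <- lab[ut[, 2]]
  } else {
    ij <- expand.grid(row = seq_len(R), col = seq_len(R))
    a <- lab[ij$row]; b <- lab[ij$col]
  }
  ## unordered pair id, stable order
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

#' Additive block-pair decomposition of the entry-standardized kernel
#'
#' Each FC entry is standardized across subjects (mean 0, SD 1); entries are
#' grouped by the unordered pair of (sub)networks they connect. With
#' `Z` the standardized subjects x P matrix and `Z_b` its restriction to the
#' `P_b` entries of block pair b, the block kernel is
#' `F_b = Z_b Z_b' / P_b` with weight `w_b = P_b / P`, so that
#' `sum_b w_b F_b` equals the entry-standardized whole-matrix kernel
#' `F_std = Z Z' / P` exactly. Entries constant across subjects are excluded
#' (with a message).
#'
#' Note these Gram kernels standardize per entry, not per subject, which is
#' what makes the decomposition additive; they are distinct from the
#' per-subject Pearson kernels of [buildKernel()].
#'
#' @param fcList list of FC objects, one per subject (all the same class).
#' @param parcellation a [Parcellation-class].
#' @param level `"network"` or `"subnetwork"`.
#' @return list with `fStd` (the whole-matrix standardized kernel), `pairs`
#'   (data.frame: pair id, weight, number of entries), `kernels` (named list
#'   of block kernels), `Z` (standardized entries), `labels` (entry pair
#'   ids), `nExcluded` (constant entries dropped).
#' @export
blockDecompositionKernels <- function(fcList, parcellation,
                                      level = c("network", "subnetwork")) {
  level <- match.arg(level)
  if (length(fcList) < 2L) stop("need at least 2 subjects")
  symmetric <- is(fcList[[1]], "StaticFC")
  V <- t(vapply(fcList, vectorizeFC, block = "whole",
                FUN.VALUE = vectorizeFC(fcList[[1]], block = "whole")))
  labels <- .entryPairLabels(parcellation, level, symmetric)
  if (length(labels) != ncol(V))
    stop("FC dimension does not match the parcellation")
  sds <- apply(V, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message(sum(constant), " FC entries constant across subjects excluded")
    V <- V[, !constant, drop = FALSE]
    labels <- labels[!constant]
  }
  Z <- scale(V)
  P <- ncol(Z)
  pairIds <- sort(unique(labels))
  kernels <- list()
  Pb <- integer(length(pairIds))
  for (k in seq_along(pairIds)) {
    cols <- which(labels == pairIds[k])
    Pb[k] <- length(cols)
    kernels[[pairIds[k]]] <- tcrossprod(Z[, cols, drop = FALSE]) / Pb[k]
  }
  list(fStd = tcrossprod(Z) / P,
       pairs = data.frame(pair = pairIds, weight = Pb / P, P = Pb,
                          stringsAsFactors = FALSE),
       kernels = kernels, Z = Z, labels = labels,
       nExcluded = sum(constant))
}
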