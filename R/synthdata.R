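## Synthetic cohort generator: stable subject-specific AR(1) dynamics with
## shared + individual structure, motion traces with a target censoring
## fraction, and behavioral matrices drawn from the matrix-normal variance
## component model conditional on the empirically computed kernels, so every
## true variance-explained value is known by construction.

#' Derive a reproducible substream seed from a root seed
#'
#' Keeps all derived seeds positive 32-bit integers.
#' @param seed root seed (integer).
#' @param tag integer tag identifying the substream.
#' @export
substreamSeed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483647 * 1009 + as.numeric(tag) * 9973) %%
               2147483646 + 1)
}

#' Symmetric PSD square root with eigenvalue clipping
#'
#' Eigenvalues below `-1e-10` (relative to the largest) raise an error; tiny
#' negative eigenvalues from numerical noise are clipped to zero.
#' @param S symmetric matrix.
#' @return matrix L with `L %*% t(L) = S` (up to clipping).
#' @export
psdSqrt <- function(S) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-8) stop("matrix is not symmetric")
  ed <- eigen(S, symmetric = TRUE)
  tol <- 1e-10 * max(1, abs(ed$values[1]))
  if (min(ed$values) < -tol)
    stop("matrix is not positive semidefinite beyond tolerance")
  ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
}

.spectralRadius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' Construct a parcellation by contiguous assignment
#'
#' ROIs are assigned to networks contiguously in the order the sizes are
#' given; each network can optionally be split into contiguous subnetworks.
#'
#' @param nRoi total number of ROIs.
#' @param networkSizes named integer vector, label -> ROI count; must sum to
#'   `nRoi`.
#' @param subnetworksPer how many contiguous subnetworks to split each
#'   network into (1 = subnetwork equals network).
#' @return A [Parcellation-class].
#' @examples
#' makeParcellation(8, c(A = 4, B = 4))
#' @export
makeParcellation <- function(nRoi, networkSizes, subnetworksPer = 1L) {
  if (sum(networkSizes) != nRoi)
    stop("network sizes must sum to the number of ROIs")
  if (is.null(names(networkSizes)) || any(!nzchar(names(networkSizes))))
    stop("networkSizes must be a named vector")
  network <- rep(names(networkSizes), times = networkSizes)
  sub <- character(nRoi)
  for (lab in names(networkSizes)) {
    i <- which(network == lab)
    if (subnetworksPer <= 1L) {
      sub[i] <- lab
    } else {
      chunk <- ceiling(seq_along(i) / (length(i) / subnetworksPer))
      chunk <- pmin(chunk, subnetworksPer)
      sub[i] <- paste0(lab, ".", chunk)
    }
  }
  Parcellation(sprintf("roi_%03d", seq_len(nRoi)), network, sub)
}

#' Sample a subject-specific AR coefficient matrix
#'
#' Adds a scaled Gaussian perturbation to a shared base matrix and rescales
#' the result so its spectral radius equals `targetRadius`, keeping every
#' subject's dynamics stable while inducing inter-subject variability.
#'
#' @param baseA shared square base matrix.
#' @param individualScale SD of the per-entry perturbation (scaled by
#'   `1/sqrt(R)`); 0 returns the rescaled base matrix.
#' @param targetRadius spectral radius of the returned matrix, in (0, 1).
#' @param seed RNG seed.
#' @return square matrix with spectral radius `targetRadius`.
#' @export
sampleSubjectAR <- function(baseA, individualScale, targetRadius, seed) {
  baseA <- as.matrix(baseA)
  R <- nrow(baseA)
  if (ncol(baseA) != R) stop("baseA must be square")
  if (individualScale < 0) stop("individualScale must be non-negative")
  if (targetRadius >= 1 || targetRadius <= 0)
    stop("targetRadius must lie in (0, 1): spectral radius >= 1 is non-stationary")
  set.seed(seed)
  A <- baseA + individualScale * matrix(stats::rnorm(R * R), R, R) / sqrt(R)
  rad <- .spectralRadius(A)
  if (rad == 0) stop("degenerate matrix: zero spectral radius")
  A * (targetRadius / rad)
}

#' Simulate one run of a stable AR(1) process
#'
#' Forward simulation of `x_t = A x_{t-1} + e_t` with Gaussian innovations.
#' A burn-in is discarded so the returned frames are a stationary draw,
#' unless an explicit initial state is supplied (then the recursion starts
#' there, which with zero innovation covariance yields the exact
#' deterministic recursion).
#'
#' @param A stable coefficient matrix (spectral radius < 1).
#' @param innovationCov PSD innovation covariance (may be the zero matrix).
#' @param nFrames frames to return.
#' @param burnIn frames to discard before sampling (ignored when `init` is
#'   given).
#' @param seed RNG seed.
#' @param init optional initial state vector.
#' @param runId run identifier for the returned object.
#' @return A [RunTimeSeries-class] (without motion traces).
#' @export
simulateRun <- function(A, innovationCov, nFrames, burnIn = 200L, seed = 1L,
                        init = NULL, runId = "run-1") {
  A <- as.matrix(A)
  R <- nrow(A)
  if (.spectralRadius(A) >= 1) stop("unstable A: spectral radius >= 1")
  L <- psdSqrt(innovationCov)
  noiseless <- all(L == 0)
  set.seed(seed)
  if (!is.null(init)) {
    x <- as.numeric(init)
    nburn <- 0L
  } else {
    x <- rep(0, R)
    nburn <- as.integer(burnIn)
  }
  total <- nburn + nFrames
  E <- if (noiseless) NULL else matrix(stats::rnorm(total * R), total, R) %*% t(L)
  X <- matrix(0, nFrames, R)
  for (t in seq_len(total)) {
    x <- as.numeric(A %*% x)
    if (!noiseless) x <- x + E[t, ]
    if (t > nburn) X[t - nburn, ] <- x
  }
  colnames(X) <- if (!is.null(colnames(A))) colnames(A)
                 else sprintf("roi_%03d", seq_len(R))
  RunTimeSeries(X, runId = runId)
}

#' Simulate FD and DVARS traces with a target censoring fraction
#'
#' Clean baseline traces (FD well below 0.2 mm, DVARS well below 75) are
#' seeded with motion spikes whose count is adapted until the rule-based
#' censoring of [computeCensorMask()] at default thresholds removes a
#' fraction of frames within 0.05 of the target.
#'
#' @param nFrames number of frames.
#' @param censorFractionTarget target censored fraction in [0, 1).
#' @param seed RNG seed.
#' @return list with numeric `fd` and `dvars` traces.
#' @export
simulateMotion <- function(nFrames, censorFractionTarget, seed = 1L) {
  if (censorFractionTarget < 0 || censorFractionTarget >= 1)
    stop("censorFractionTarget must lie in [0, 1)")
  set.seed(seed)
  fd0 <- stats::runif(nFrames, 0.03, 0.15)
  dv0 <- stats::runif(nFrames, 30, 65)
  if (censorFractionTarget == 0)
    return(list(fd = fd0, dvars = dv0))
  k <- max(1L, as.integer(round(censorFractionTarget * nFrames / 4)))
  for (iter in seq_len(200L)) {
    fd <- fd0; dv <- dv0
    pos <- sample.int(nFrames, min(k, nFrames))
    fd[pos] <- 0.2 + stats::rexp(length(pos), rate = 10)
    dv[pos] <- 75 + stats::rexp(length(pos), rate = 0.1)
    frac <- mean(!keepFrames(computeCensorMask(fd, dv)))
    if (abs(frac - censorFractionTarget) <= 0.04)
      return(list(fd = fd, dvars = dv))
    step <- as.integer(round((censorFractionTarget - frac) * nFrames / 4))
    if (step == 0L) step <- if (frac < censorFractionTarget) 1L else -1L
    k <- min(nFrames, max(0L, k + step))
    if (k == 0L) k <- 1L
  }
  stop("target censoring fraction infeasible at this run length ",
       "given the frame-expansion and segment rules")
}

#' Structured random similarity kernel from latent subject factors
#'
#' Stand-in for an empirically computed FC similarity kernel in simulation
#' studies: subjects load on a few latent factors plus noise, and their
#' feature vectors are correlated, giving a unit-diagonal PSD kernel with a
#' realistic spread of off-diagonal similarities.
#'
#' @param nSubjects number of subjects.
#' @param nLatent number of latent factors.
#' @param noise SD of the idiosyncratic feature noise.
#' @param P feature vector length.
#' @param seed RNG seed.
#' @return A [SimilarityKernel-class].
#' @export
latentKernel <- function(nSubjects, nLatent = 3L, noise = 1, P = 200L,
                         seed = 1L) {
  set.seed(seed)
  S <- matrix(stats::rnorm(nSubjects * nLatent), nSubjects, nLatent)
  B <- matrix(stats::rnorm(nLatent * P), nLatent, P)
  V <- S %*% B + noise * matrix(stats::rnorm(nSubjects * P), nSubjects, P)
  buildKernel(V, mode = "custom", block = "latent")
}

#' Draw a behavioral matrix from the variance component model
#'
#' Exact matrix-normal sampling of `Y = sum_k C_k + E` with
#' `Vec(C_k) ~ N(0, Sigma_c^k (x) F_k)` and `Vec(E) ~ N(0, Sigma_e (x) I)`:
#' each `C_k = L_{F_k} U_k L_{c_k}'` with `U_k` iid standard normal and the
#' `L` factors symmetric PSD square roots (tiny negative eigenvalues
#' clipped). Because the kernels have unit diagonal, the true overall
#' variance explained is exactly the trace ratio of the chosen components,
#' and is recorded in the returned object's ground truth.
#'
#' @param kernels a [SimilarityKernel-class] / matrix or list of them.
#' @param sigmaC list of measures x measures PSD matrices, one per kernel.
#' @param sigmaE residual measures x measures PSD matrix.
#' @param seed RNG seed.
#' @param categories optional per-measure categories.
#' @param measureNames optional measure names.
#' @return A [BehaviorMatrix-class] with `groundTruth(x)` holding `trueM`,
#'   `trueMi` and per-kernel trace shares.
#' @export
simulateBehavior <- function(kernels, sigmaC, sigmaE, seed = 1L,
                             categories = NULL, measureNames = NULL) {
  Fs <- .asKernelList(kernels)
  if (!is.list(sigmaC)) sigmaC <- list(sigmaC)
  if (length(sigmaC) != length(Fs))
    stop("need one sigmaC matrix per kernel")
  N <- nrow(Fs[[1]])
  Q <- nrow(as.matrix(sigmaE))
  for (Fk in Fs)
    if (!all(dim(Fk) == c(N, N))) stop("kernel dimension mismatch")
  for (S in sigmaC)
    if (!all(dim(as.matrix(S)) == c(Q, Q))) stop("sigmaC dimension mismatch")
  Lf <- lapply(Fs, psdSqrt)
  Lc <- lapply(sigmaC, psdSqrt)
  Le <- psdSqrt(sigmaE)
  set.seed(seed)
  Y <- matrix(0, N, Q)
  for (k in seq_along(Fs)) {
    U <- matrix(stats::rnorm(N * Q), N, Q)
    Y <- Y + Lf[[k]] %*% U %*% t(Lc[[k]])
  }
  Y <- Y + matrix(stats::rnorm(N * Q), N, Q) %*% t(Le)
  if (is.null(measureNames)) measureNames <- sprintf("measure_%02d", seq_len(Q))
  colnames(Y) <- measureNames
  rownames(Y) <- sprintf("sub-%03d", seq_len(N))
  trC <- vapply(sigmaC, function(S) sum(diag(as.matrix(S))), numeric(1))
  trE <- sum(diag(as.matrix(sigmaE)))
  diagC <- vapply(sigmaC, function(S) diag(as.matrix(S)), numeric(Q))
  diagC <- matrix(diagC, nrow = Q)
  trueMi <- rowSums(diagC) / (rowSums(diagC) + diag(as.matrix(sigmaE)))
  names(trueMi) <- measureNames
  truth <- list(trueM = sum(trC) / (sum(trC) + trE),
                trueMi = trueMi,
                traceC = trC, traceE = trE,
                shares = if (sum(trC) > 0) trC / sum(trC) else trC,
                seed = seed)
  BehaviorMatrix(Y, categories = categories, groundTruth = truth)
}
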