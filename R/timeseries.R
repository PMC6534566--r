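## Motion censoring, nuisance regression, static and dynamic FC estimation.

#' Build a frame censoring mask from motion traces
#'
#' Frames with FD strictly above `fdThresh` (mm) or DVARS strictly above
#' `dvarsThresh` are censored, together with `nBefore` frames before and
#' `nAfter` frames after each such frame (clipped at run boundaries). Kept
#' segments shorter than `minSegment` frames are then censored as well.
#'
#' @param fd framewise displacement per frame (mm).
#' @param dvars DVARS per frame.
#' @param fdThresh,dvarsThresh censoring thresholds (strict inequalities).
#' @param nBefore,nAfter how many neighbouring frames to censor around each
#'   flagged frame.
#' @param minSegment minimal length of a kept segment after expansion.
#' @return A [CensorMask-class].
#' @examples
#' m <- computeCensorMask(c(rep(0.1, 3), 0.25, rep(0.1, 6)), rep(50, 10))
#' keepFrames(m)
#' @export
computeCensorMask <- function(fd, dvars, fdThresh = 0.2, dvarsThresh = 75,
                              nBefore = 1L, nAfter = 2L, minSegment = 5L) {
  if (length(fd) != length(dvars))
    stop("fd and dvars must have equal length")
  n <- length(fd)
  if (n == 0L) stop("empty motion traces")
  if (anyNA(fd) || anyNA(dvars)) stop("motion traces contain missing values")
  flagged <- which(fd > fdThresh | dvars > dvarsThresh)
  censored <- rep(FALSE, n)
  for (i in flagged)
    censored[max(1L, i - nBefore):min(n, i + nAfter)] <- TRUE
  keep <- !censored
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  short <- which(r$values & r$lengths < minSegment)
  for (j in short) keep[starts[j]:ends[j]] <- FALSE
  new("CensorMask", keep = keep, fdThresh = fdThresh,
      dvarsThresh = dvarsThresh, nBefore = as.integer(nBefore),
      nAfter = as.integer(nAfter), minSegment = as.integer(minSegment))
}

#' Does a run survive the censored-fraction quality check?
#'
#' Runs with strictly more than half of their frames censored are discarded.
#'
#' @param mask a [CensorMask-class] for a full run.
#' @return TRUE if the censored fraction is at most 50%.
#' @export
runPassesQC <- function(mask) {
  stopifnot(is(mask, "CensorMask"))
  mean(!mask@keep) <= 0.5
}

#' Regress nuisance signals from a run
#'
#' Per-ROI ordinary least squares against an intercept, a linear trend and
#' (optionally) the global signal (mean across ROIs, the ROI-level analogue
#' of the mean cortical signal). Coefficients are fitted on kept frames only;
#' residuals are computed at all frames so the censor mask can still be
#' applied downstream.
#'
#' @param run a [RunTimeSeries-class].
#' @param mask a [CensorMask-class] for the run.
#' @param regressGlobal include the global mean signal as a regressor.
#' @return A [RunTimeSeries-class] of residuals (motion traces carried over).
#' @export
regressNuisance <- function(run, mask, regressGlobal = TRUE) {
  stopifnot(is(run, "RunTimeSeries"), is(mask, "CensorMask"))
  X <- run@data
  keep <- mask@keep
  if (length(keep) != nrow(X)) stop("mask length does not match run")
  if (sum(keep) < 3L) stop("need at least 3 kept frames")
  D <- cbind(intercept = 1, trend = seq_len(nrow(X)))
  if (regressGlobal) D <- cbind(D, global = rowMeans(X))
  qrD <- qr(D[keep, , drop = FALSE])
  if (qrD$rank < ncol(D))
    stop("nuisance regressors are rank deficient on kept frames")
  beta <- qr.coef(qrD, X[keep, , drop = FALSE])
  res <- X - D %*% beta
  RunTimeSeries(res, fd = run@fd, dvars = run@dvars, runId = run@runId)
}

.keptData <- function(run, mask) {
  X <- run@data
  if (length(mask@keep) != nrow(X)) stop("mask length does not match run")
  X[mask@keep, , drop = FALSE]
}

#' Static FC: Fisher-z averaged correlation over runs
#'
#' Per-run Pearson correlation on uncensored frames, Fisher z-transformed,
#' averaged over runs and transformed back to r-space. The diagonal is
#' excluded from averaging (atanh(1) diverges) and reset to 1.
#'
#' @param runs list of [RunTimeSeries-class], QC-passing.
#' @param masks list of matching [CensorMask-class].
#' @return A [StaticFC-class].
#' @export
staticFC <- function(runs, masks) {
  stopifnot(length(runs) == length(masks), length(runs) >= 1L)
  zsum <- NULL
  for (k in seq_along(runs)) {
    X <- .keptData(runs[[k]], masks[[k]])
    if (nrow(X) < 3L) stop("each run needs at least 3 kept frames")
    C <- suppressWarnings(stats::cor(X))
    if (anyNA(C)) stop("constant ROI signal: correlation undefined")
    z <- atanh(pmin(pmax(C, -1), 1))
    diag(z) <- 0
    zsum <- if (is.null(zsum)) z else zsum + z
  }
  M <- tanh(zsum / length(runs))
  diag(M) <- 1
  nm <- colnames(runs[[1]]@data)
  dimnames(M) <- list(nm, nm)
  new("StaticFC", fc = M)
}

.validPairs <- function(keep) {
  ## (t-1, t) pairs with both frames kept; adjacency implies same segment
  t2 <- which(keep[-1] & keep[-length(keep)]) + 1L
  cbind(prev = t2 - 1L, nxt = t2)
}

#' Dynamic FC: first-order autoregressive model over concatenated runs
#'
#' Fits `x_t = A x_{t-1} + e_t` by least squares over all frame pairs
#' (t-1, t) that are consecutive, both uncensored, and within the same run;
#' transitions between censored segments and between runs are ignored. The
#' model fit is reported as `r2 = 1 - ||Cov(e)||_F / ||Cov(x)||_F`, with
#' `Cov(x)` computed over all kept frames.
#'
#' @param runs list of [RunTimeSeries-class].
#' @param masks list of matching [CensorMask-class].
#' @param intercept include an intercept column in the regression (the
#'   default assumes detrended/demeaned input).
#' @return A [DynamicFC-class].
#' @export
dynamicFC <- function(runs, masks, intercept = FALSE) {
  stopifnot(length(runs) == length(masks), length(runs) >= 1L)
  Xp <- Xn <- Xk <- NULL
  for (k in seq_along(runs)) {
    X <- runs[[k]]@data
    keep <- masks[[k]]@keep
    if (length(keep) != nrow(X)) stop("mask length does not match run")
    pr <- .validPairs(keep)
    Xp <- rbind(Xp, X[pr[, "prev"], , drop = FALSE])
    Xn <- rbind(Xn, X[pr[, "nxt"], , drop = FALSE])
    Xk <- rbind(Xk, X[keep, , drop = FALSE])
  }
  R <- ncol(Xp)
  npairs <- nrow(Xp)
  if (npairs <= R + intercept)
    stop("too few valid frame pairs to identify the AR model")
  Dp <- if (intercept) cbind(1, Xp) else Xp
  ## Minimum-norm least squares via SVD. Global-signal regression at ROI
  ## level leaves the data in an (R-1)-dimensional subspace, so a deficiency
  ## of one or two directions is expected and handled; anything larger
  ## signals genuinely degenerate input.
  sv <- svd(Dp)
  tol <- max(dim(Dp)) * .Machine$double.eps * sv$d[1]
  rk <- sum(sv$d > tol)
  if (rk < ncol(Dp) - 2L)
    stop("singular normal equations: degenerate input time series")
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  At <- sv$v %*% (dinv * crossprod(sv$u, Xn))
  E <- Xn - Dp %*% At
  if (intercept) At <- At[-1L, , drop = FALSE]
  A <- t(At)
  dimnames(A) <- list(colnames(Xp), colnames(Xp))
  residCov <- stats::cov(E)
  covX <- stats::cov(Xk)
  r2 <- 1 - norm(residCov, "F") / norm(covX, "F")
  new("DynamicFC", A = A, residCov = residCov, r2 = r2,
      nPairs = as.integer(npairs), rank = as.integer(rk))
}
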