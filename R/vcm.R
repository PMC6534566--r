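## Multi-kernel variance component model, method-of-moments estimation,
## and a univariate likelihood-based cross-check.

.asKernelList <- function(kernels) {
  if (is(kernels, "SimilarityKernel") || is.matrix(kernels))
    kernels <- list(kernels)
  lapply(kernels, function(k) {
    if (is(k, "SimilarityKernel")) similarityMatrix(k) else as.matrix(k)
  })
}

.kernelNames <- function(kernels) {
  if (is(kernels, "SimilarityKernel") || is.matrix(kernels))
    kernels <- list(kernels)
  nm <- names(kernels)
  auto <- vapply(seq_along(kernels), function(i) {
    k <- kernels[[i]]
    if (is(k, "SimilarityKernel")) k@mode else paste0("kernel", i)
  }, character(1))
  if (is.null(nm)) return(make.unique(auto))
  make.unique(ifelse(nzchar(nm), nm, auto))
}

#' Fit the multi-kernel variance component model by the method of moments
#'
#' Model: `Y = C_1 + ... + C_K + E` with `Vec(C_k) ~ N(0, Sigma_c^k (x) F_k)`
#' and `Vec(E) ~ N(0, Sigma_e (x) I)`, where each `F_k` is an inter-subject
#' similarity kernel. For every ordered pair of measures (p, q) the moment
#' equations `E[y_p' F_k y_q] = sum_l <F_k, F_l>_F Sigma^l(p, q)` (with
#' `F_{K+1} = I`) give a shared (K+1) x (K+1) linear system whose Gram matrix
#' is `G_{kl} = <F_k, F_l>_F`; solving it for all pairs at once yields the
#' component matrices, which are then symmetrized. Y columns are mean
#' centered before fitting, and every kernel (including the identity) is
#' double-centered (`H F H` with `H = I - 11'/N`): preprocessed measures
#' carry no grand-mean information, so the moment system must be restricted
#' to the mean-free subspace -- this is what restricted maximum likelihood
#' with an intercept does implicitly, and without it a kernel with a large
#' constant off-diagonal level would have its component biased toward zero.
#'
#' By default the unweighted solution is refined by `glsSteps` rounds of
#' MINQUE-type reweighting: variance components pooled across measures
#' define a working covariance `V = sum_k sigma_k F_k + sigma_e I`, and the
#' moment system is re-solved in the `V^-1` metric
#' (`G*_{kl} = Tr(V^-1 F_k V^-1 F_l)`, `b*_k = y' V^-1 F_k V^-1 y`). Any
#' fixed weight gives unbiased components, so the refinement only improves
#' efficiency; in the single-kernel, single-measure case iterating these
#' equations converges to restricted maximum likelihood. `glsSteps = 0`
#' gives the plain Haseman-Elston-type estimator.
#'
#' Negative diagonal components are truncated to 0 for the
#' variance-explained summaries; raw values are kept in the diagnostics.
#'
#' @param Y a [BehaviorMatrix-class] or subjects x measures matrix
#'   (processed: residualized and normalized).
#' @param kernels a [SimilarityKernel-class], a subjects x subjects matrix,
#'   or a list of them (K >= 1).
#' @param glsSteps number of MINQUE reweighting rounds (0 = unweighted).
#' @return A [VCMFit-class].
#' @export
fitVCM <- function(Y, kernels, glsSteps = 2L) {
  if (is(Y, "BehaviorMatrix")) Y <- behaviorValues(Y)
  Y <- as.matrix(Y)
  Fs <- .asKernelList(kernels)
  knames <- .kernelNames(kernels)
  N <- nrow(Y)
  Q <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("measure_%02d", seq_len(Q))
  for (Fk in Fs) {
    if (!all(dim(Fk) == c(N, N)))
      stop("kernel dimension does not match the subject count")
  }
  K <- length(Fs)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  doubleCenter <- function(M) {
    rm <- rowMeans(M)
    M <- M - rep(rm, times = N) - rep(colMeans(M), each = N) + mean(M)
    (M + t(M)) / 2
  }
  Fall <- lapply(c(Fs, list(diag(N))), doubleCenter)
  G <- matrix(0, K + 1L, K + 1L)
  for (k in seq_len(K + 1L))
    for (l in k:(K + 1L))
      G[k, l] <- G[l, k] <- sum(Fall[[k]] * Fall[[l]])
  cond <- kappa(G, exact = TRUE)
  if (!is.finite(cond) || cond > 1e10)
    stop("ill-conditioned moment system (are the kernels distinct from ",
         "each other and from the identity?)")
  solveSystem <- function(Alist, Gm) {
    B <- lapply(Alist, function(Ak) crossprod(Y, Ak %*% Y))
    Gi <- solve(Gm)
    lapply(seq_len(K + 1L), function(k) {
      S <- Reduce(`+`, Map(`*`, B, Gi[k, ]))
      S <- (S + t(S)) / 2
      dimnames(S) <- list(colnames(Y), colnames(Y))
      S
    })
  }
  Sig <- solveSystem(Fall, G)
  for (step in seq_len(glsSteps)) {
    ## pooled (across measures) components define the working covariance;
    ## floors keep V positive definite when components collapse to zero
    pooled <- vapply(Sig, function(S) mean(pmax(diag(S), 0)), numeric(1))
    tot <- sum(pooled)
    if (tot <= 0) break
    pooled[K + 1L] <- max(pooled[K + 1L], 0.01 * tot)
    V <- Reduce(`+`, Map(`*`, Fall[seq_len(K)], pooled[seq_len(K)])) +
      diag(pooled[K + 1L], N)
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) break
    Alist <- lapply(Fall, function(Fk) Vi %*% Fk %*% Vi)
    Gw <- matrix(0, K + 1L, K + 1L)
    for (k in seq_len(K + 1L))
      for (l in seq_len(K + 1L))
        Gw[k, l] <- sum(Alist[[k]] * t(Fall[[l]]))
    Gw <- (Gw + t(Gw)) / 2
    if (!is.finite(kappa(Gw, exact = TRUE)) || kappa(Gw, exact = TRUE) > 1e10)
      break
    Sig <- solveSystem(Alist, Gw)
  }
  sigmaC <- Sig[seq_len(K)]
  names(sigmaC) <- knames
  sigmaE <- Sig[[K + 1L]]
  rawC <- vapply(sigmaC, diag, numeric(Q))
  rawC <- matrix(rawC, nrow = Q, dimnames = list(colnames(Y), knames))
  rawE <- diag(sigmaE)
  dC <- pmax(rawC, 0)
  dE <- pmax(rawE, 0)
  totC <- rowSums(dC)
  denom <- totC + dE
  if (sum(denom) == 0) stop("all-zero total variance")
  Mi <- ifelse(denom > 0, totC / denom, NA_real_)
  names(Mi) <- colnames(Y)
  M <- sum(totC) / sum(denom)
  shares <- if (sum(totC) > 0) colSums(dC) / sum(totC)
            else stats::setNames(rep(0, K), knames)
  ## untruncated analogues: unbiased linear functions of the moment
  ## estimates, used by the jackknife when differencing two models
  rawTotC <- rowSums(rawC)
  MiRaw <- rawTotC / (rawTotC + rawE)
  MRaw <- sum(rawTotC) / sum(rawTotC + rawE)
  new("VCMFit", sigmaC = sigmaC, sigmaE = sigmaE, M = M, Mi = Mi,
      shares = shares, kernelNames = knames,
      diagnostics = list(rawDiagC = rawC, rawDiagE = rawE, G = G,
                         condition = cond, nSubjects = N,
                         MRaw = MRaw, MiRaw = stats::setNames(MiRaw, colnames(Y))))
}

#' Univariate single-kernel variance explained by maximum likelihood
#'
#' Independent cross-check for the moment estimator in the one-kernel,
#' one-measure case. Uses the eigendecomposition `F = U D U'` to rotate the
#' model to independent coordinates and profiles the (restricted) likelihood
#' over the variance-explained fraction `h = sigma_c^2 / (sigma_c^2 +
#' sigma_e^2)` by a one-dimensional search.
#'
#' @param y numeric vector (one behavioral measure; centered internally).
#' @param kernel a [SimilarityKernel-class] or subjects x subjects matrix.
#' @return list with `M` (the likelihood estimate of the variance-explained
#'   fraction), `sigmaC`, `sigmaE` and `logLik`.
#' @export
remlVarianceExplained <- function(y, kernel) {
  Fk <- .asKernelList(kernel)[[1]]
  y <- as.numeric(y)
  if (length(y) != nrow(Fk)) stop("kernel dimension does not match y")
  n <- length(y)
  y <- y - mean(y)
  ## restrict to the mean-free subspace (the model's intercept is removed):
  ## eigen-decompose the double-centered kernel and drop the coordinate
  ## spanned by the constant vector, which H maps to zero
  H <- diag(n) - 1 / n
  ed <- eigen(H %*% Fk %*% H, symmetric = TRUE)
  ones <- rep(1 / sqrt(n), n)
  j <- which.max(abs(as.numeric(crossprod(ed$vectors, ones))))
  d <- pmax(ed$values[-j], 0)
  z <- as.numeric(crossprod(ed$vectors[, -j, drop = FALSE], y))
  negll <- function(h) {
    lam <- h * d + (1 - h)
    if (any(lam <= 0)) return(Inf)
    s2 <- sum(z^2 / lam) / (n - 1)
    0.5 * (sum(log(lam)) + (n - 1) * log(s2))
  }
  opt <- stats::optimize(negll, interval = c(0, 1 - 1e-6))
  ## guard the boundary: compare with h = 0
  h <- if (negll(0) <= opt$objective) 0 else opt$minimum
  lam <- h * d + (1 - h)
  s2 <- sum(z^2 / lam) / (n - 1)
  list(M = h, sigmaC = h * s2, sigmaE = (1 - h) * s2, logLik = -negll(h))
}
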