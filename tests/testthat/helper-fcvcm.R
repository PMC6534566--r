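## Shared fixtures and independent oracles, built in code.

toyParcellation <- function(nets = c(A = 3L, B = 3L, C = 2L)) {
  makeParcellation(sum(nets), nets)
}

## stable AR matrix with mild structure
toyAR <- function(R, radius = 0.9, seed = 7) {
  set.seed(seed)
  A <- diag(0.8, R) + matrix(rnorm(R * R), R, R) * 0.1 / sqrt(R)
  A * radius / max(Mod(eigen(A, only.values = TRUE)$values))
}

## exhaustive Benjamini-Hochberg definition: reject the k smallest p-values
## where k is the largest index with p_(k) <= k q / m
bhOracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

## explicit pair-list least-squares AR oracle: given the list of (prev, nxt)
## frame indices into X, solve X[nxt, ] ~ X[prev, ] by normal equations
pairListAR <- function(X, prev, nxt) {
  Xp <- X[prev, , drop = FALSE]
  Xn <- X[nxt, , drop = FALSE]
  t(solve(crossprod(Xp), crossprod(Xp, Xn)))
}

## independent solve of the (K+1)x(K+1) moment system on double-centered
## kernels (the unweighted estimator's defining equations)
momentOracle <- function(y, Flist) {
  n <- length(y)
  H <- diag(n) - 1 / n
  y <- y - mean(y)
  Fc <- lapply(c(Flist, list(diag(n))), function(Fk) H %*% Fk %*% H)
  K1 <- length(Fc)
  G <- matrix(0, K1, K1)
  for (k in 1:K1) for (l in 1:K1) G[k, l] <- sum(Fc[[k]] * Fc[[l]])
  b <- vapply(Fc, function(Fk) drop(crossprod(y, Fk %*% y)), numeric(1))
  solve(G, b)
}

## two runs whose given ROI pair has exact sample correlations r1 and r2
runsWithPairCorrelations <- function(r1, r2, n = 40, seed = 5) {
  set.seed(seed)
  mk <- function(r) {
    x <- scale(rnorm(n))
    z <- rnorm(n)
    z <- scale(resid(lm(z ~ x)))
    cbind(roi_1 = as.numeric(x), roi_2 = as.numeric(r * x + sqrt(1 - r^2) * z))
  }
  list(RunTimeSeries(mk(r1), runId = "run-1"),
       RunTimeSeries(mk(r2), runId = "run-2"))
}
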