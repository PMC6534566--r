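test_that("censoring mask follows the scrubbing rules on hand-traced fixtures", {
  ## all clean: everything kept
  m <- computeCensorMask(rep(0.1, 10), rep(50, 10))
  expect_true(all(keepFrames(m)))

  ## one spike at frame 4 censors 3..6; both leftover segments are shorter
  ## than 5 frames and get removed, so nothing survives
  fd <- rep(0.1, 10); fd[4] <- 0.25
  m <- computeCensorMask(fd, rep(50, 10))
  expect_false(any(keepFrames(m)))

  ## thresholds are strict: FD exactly 0.2 and DVARS exactly 75 are kept
  m <- computeCensorMask(rep(0.2, 20), rep(75, 20))
  expect_true(all(keepFrames(m)))

  ## expansion clips at run boundaries
  fd <- rep(0.1, 20); fd[1] <- 0.3
  m <- computeCensorMask(fd, rep(50, 20))
  expect_equal(which(!keepFrames(m)), 1:3)
  expect_equal(length(censorSegments(m)), 1L)
  expect_equal(IRanges::start(censorSegments(m)), 4L)

  ## a kept segment of exactly 5 frames survives, one of 4 is removed
  fd <- rep(0.1, 12); fd[7] <- 0.3   # censors 6..9, keeps 1-5 and 10-12
  m <- computeCensorMask(fd, rep(50, 12))
  expect_equal(which(keepFrames(m)), 1:5)

  ## DVARS triggers independently of FD
  dv <- rep(50, 20); dv[10] <- 80
  m <- computeCensorMask(rep(0.1, 20), dv)
  expect_equal(which(!keepFrames(m)), 9:12)

  expect_error(computeCensorMask(numeric(0), numeric(0)), "empty")
  expect_error(computeCensorMask(rep(0.1, 3), rep(50, 4)), "equal length")
})

test_that("run QC discards runs with strictly more than half censored", {
  ## exactly 50% censored passes, 51%+ fails (minSegment 1 to control counts)
  fd <- rep(0.1, 8); fd[3] <- 0.3  # censors 2..5 -> 4/8
  expect_true(runPassesQC(computeCensorMask(fd, rep(50, 8), minSegment = 1)))
  fd <- rep(0.1, 8); fd[3] <- 0.3; fd[8] <- 0.3  # censors 2..5, 7..8 -> 6/8
  expect_false(runPassesQC(computeCensorMask(fd, rep(50, 8), minSegment = 1)))
  expect_true(runPassesQC(allKeepMask(10)))
})

test_that("raising the FD threshold never censors more frames", {
  for (s in 1:20) {
    set.seed(s)
    fd <- runif(200, 0, 0.4)
    dv <- runif(200, 40, 90)
    prev <- -1L
    for (th in c(0.1, 0.2, 0.3, 0.5)) {
      kept <- sum(keepFrames(computeCensorMask(fd, dv, fdThresh = th)))
      expect_gte(kept, prev)
      prev <- kept
    }
  }
})

test_that("nuisance regression removes trends and the global signal", {
  n <- 50
  tt <- seq_len(n)
  X <- cbind(2 + 0.3 * tt, -1 + 0.05 * tt, 4 - 0.2 * tt)
  run <- RunTimeSeries(X)
  res <- regressNuisance(run, allKeepMask(n), regressGlobal = FALSE)
  expect_lt(max(abs(runData(res))), 1e-8)

  ## a signal identical in all ROIs is absorbed by the global regressor
  set.seed(1)
  g <- cumsum(rnorm(n))
  X <- cbind(g, g, g)
  res <- regressNuisance(RunTimeSeries(X), allKeepMask(n))
  expect_lt(max(abs(runData(res))), 1e-8)
})

test_that("censored frames do not influence regression coefficients", {
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4) + 0.1 * seq_len(n)
  fd <- rep(0.1, n); fd[c(20, 40)] <- 0.5
  mask <- computeCensorMask(fd, rep(50, n))
  Xspike <- X
  Xspike[!keepFrames(mask), ] <- Xspike[!keepFrames(mask), ] + 100
  r1 <- regressNuisance(RunTimeSeries(X), mask)
  r2 <- regressNuisance(RunTimeSeries(Xspike), mask)
  k <- keepFrames(mask)
  expect_equal(runData(r1)[k, ], runData(r2)[k, ], tolerance = 1e-8)
})

test_that("static FC Fisher-averages per-run correlations", {
  runs <- runsWithPairCorrelations(0.5, 0.9)
  masks <- list(allKeepMask(40), allKeepMask(40))
  fc <- staticFC(runs, masks)
  expect_equal(fcMatrix(fc)[1, 2], tanh((atanh(0.5) + atanh(0.9)) / 2),
               tolerance = 1e-10)

  ## single run: its correlation matrix unchanged
  fc1 <- staticFC(runs[1], masks[1])
  expect_equal(fcMatrix(fc1), cor(runData(runs[[1]])), tolerance = 1e-10)

  ## two runs with identical correlations: that matrix returned
  fc2 <- staticFC(list(runs[[1]], runs[[1]]), masks)
  expect_equal(fcMatrix(fc2), cor(runData(runs[[1]])), tolerance = 1e-10)

  ## symmetric with unit diagonal on arbitrary input
  set.seed(3)
  r <- RunTimeSeries(matrix(rnorm(200), 50, 4))
  M <- fcMatrix(staticFC(list(r), list(allKeepMask(50))))
  expect_identical(M, t(M))
  expect_identical(unname(diag(M)), rep(1, 4))

  expect_error(staticFC(list(RunTimeSeries(cbind(rep(1, 10), rnorm(10)))),
                        list(allKeepMask(10))), "constant")
})

test_that("dynamic FC identifies a noiseless recursion exactly", {
  A <- toyAR(5, radius = 0.95)
  run <- simulateRun(A, matrix(0, 5, 5), 60, seed = 1, init = rnorm(5))
  fit <- dynamicFC(list(run), list(allKeepMask(60)))
  expect_equal(unname(fcMatrix(fit)), A, tolerance = 1e-8)
  expect_gt(modelR2(fit), 1 - 1e-8)
})

test_that("dynamic FC equals the explicit pair-list regression", {
  set.seed(4)
  A <- toyAR(4)
  run <- simulateRun(A, diag(4), 120, seed = 9)
  fd <- rep(0.1, 120); fd[c(30, 31, 70)] <- 0.5
  mask <- computeCensorMask(fd, rep(50, 120))
  fit <- dynamicFC(list(run), list(mask))
  keep <- keepFrames(mask)
  nxt <- which(keep[-1] & keep[-120]) + 1L
  exp_A <- pairListAR(runData(run), nxt - 1L, nxt)
  expect_equal(unname(fcMatrix(fit)), unname(exp_A), tolerance = 1e-10)
  expect_equal(fit@nPairs, length(nxt))
})

test_that("splitting a recording into runs drops only the boundary pair", {
  set.seed(5)
  A <- toyAR(4)
  run <- simulateRun(A, diag(4), 100, seed = 11)
  X <- runData(run)
  twoRuns <- list(RunTimeSeries(X[1:50, ]), RunTimeSeries(X[51:100, ]))
  fit2 <- dynamicFC(twoRuns, list(allKeepMask(50), allKeepMask(50)))
  prev <- setdiff(1:99, 50)     # pair (50, 51) crosses the boundary
  exp_A <- pairListAR(X, prev, prev + 1L)
  expect_equal(unname(fcMatrix(fit2)), unname(exp_A), tolerance = 1e-10)
  expect_equal(fit2@nPairs, 98L)
})

test_that("white noise yields a near-zero AR matrix and r2", {
  set.seed(6)
  run <- RunTimeSeries(matrix(rnorm(10000 * 4), 10000, 4))
  fit <- dynamicFC(list(run), list(allKeepMask(10000)))
  expect_lt(norm(fcMatrix(fit), "F"), 0.05)
  expect_lt(abs(modelR2(fit)), 0.05)
})

test_that("r2 is reproduced when refitting data simulated from the fit", {
  A <- toyAR(6, radius = 0.85)
  run <- simulateRun(A, diag(6), 2000, seed = 21)
  fit <- dynamicFC(list(run), list(allKeepMask(2000)))
  run2 <- simulateRun(fcMatrix(fit), residualCov(fit), 2000, seed = 22)
  fit2 <- dynamicFC(list(run2), list(allKeepMask(2000)))
  expect_equal(modelR2(fit2), modelR2(fit), tolerance = 0.1)
})

test_that("dynamic FC rejects degenerate inputs", {
  expect_error(dynamicFC(list(RunTimeSeries(matrix(rnorm(12), 3, 4))),
                         list(allKeepMask(3))), "too few")
  X <- matrix(1, 50, 4)  # constant: rank 1 predictors
  expect_error(dynamicFC(list(RunTimeSeries(X)), list(allKeepMask(50))),
               "singular|too few")
})
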