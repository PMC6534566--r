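test_that("parcellation construction assigns ROIs contiguously", {
  p <- makeParcellation(8, c(A = 4, B = 4))
  expect_equal(networkLabels(p), rep(c("A", "B"), each = 4))
  ## full-scale layout: 7 cortical networks plus subcortex
  p2 <- makeParcellation(419, c(VIS = 61, SM = 77, DATT = 46, SAL = 47,
                                LIM = 26, FP = 52, DMN = 91, SUB = 19))
  expect_equal(nRoi(p2), 419L)
  expect_equal(sum(networkLabels(p2) == "SUB"), 19L)
  expect_error(makeParcellation(8, c(A = 4, B = 3)), "sum")
  ## subnetwork split stays within the parent network
  p3 <- makeParcellation(8, c(A = 4, B = 4), subnetworksPer = 2)
  expect_equal(networkLabels(p3, "subnetwork"),
               rep(c("A.1", "A.2", "B.1", "B.2"), each = 2))
})

test_that("subject AR matrices are perturbed and rescaled to the target radius", {
  base <- toyAR(6)
  radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))
  ## zero perturbation returns the rescaled base matrix
  A0 <- sampleSubjectAR(base, 0, 0.8, seed = 1)
  expect_equal(A0, base * 0.8 / radius(base), tolerance = 1e-12)
  ## different seeds differ, both at the target radius
  A1 <- sampleSubjectAR(base, 0.3, 0.85, seed = 1)
  A2 <- sampleSubjectAR(base, 0.3, 0.85, seed = 2)
  expect_gt(max(abs(A1 - A2)), 0.01)
  expect_equal(radius(A1), 0.85, tolerance = 1e-10)
  expect_equal(radius(A2), 0.85, tolerance = 1e-10)
  expect_error(sampleSubjectAR(base, 0.3, 1.0, seed = 1), "non-stationary")
})

test_that("simulated AR runs are deterministic, stationary and consistent", {
  A <- toyAR(5)
  r1 <- simulateRun(A, diag(5), 300, seed = 3)
  r2 <- simulateRun(A, diag(5), 300, seed = 3)
  expect_identical(runData(r1), runData(r2))
  ## stationarity: sample variance bounded (no divergence)
  expect_lt(max(apply(runData(r1), 2, var)), 50)
  ## noiseless recursion is exact
  x0 <- rnorm(5)
  r0 <- simulateRun(A, matrix(0, 5, 5), 4, seed = 1, init = x0)
  expect_equal(unname(runData(r0)[1, ]), as.numeric(A %*% x0),
               tolerance = 1e-12)
  expect_equal(unname(runData(r0)[3, ]), as.numeric(A %*% A %*% A %*% x0),
               tolerance = 1e-12)
  expect_error(simulateRun(diag(1.1, 4), diag(4), 10), "unstable")
  ## estimation error shrinks with the recording length
  A40 <- toyAR(10, radius = 0.9)
  err <- vapply(c(1200, 4800), function(Tn) {
    run <- simulateRun(A40, diag(10), Tn, seed = 40 + Tn)
    norm(fcMatrix(dynamicFC(list(run), list(allKeepMask(Tn)))) - A40, "F") /
      norm(A40, "F")
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("simulated motion traces hit the target censoring fraction", {
  mo <- simulateMotion(600, 0, seed = 1)
  expect_true(all(keepFrames(computeCensorMask(mo$fd, mo$dvars))))
  mo <- simulateMotion(1200, 0.2, seed = 2)
  frac <- mean(!keepFrames(computeCensorMask(mo$fd, mo$dvars)))
  expect_gte(frac, 0.15)
  expect_lte(frac, 0.25)
  ## heavy motion: the run is discarded by the >50% rule downstream
  mo <- simulateMotion(600, 0.7, seed = 3)
  expect_false(runPassesQC(computeCensorMask(mo$fd, mo$dvars)))
  ## infeasible: 6 frames cannot be censored at 50% given segment rules
  expect_error(simulateMotion(6, 0.5, seed = 4), "infeasible")
  expect_error(simulateMotion(100, 1.2, seed = 4), "\\[0, 1\\)")
})

test_that("matrix-normal behavior sampling matches its model covariance", {
  ## small fixed kernel and Sigma_c; empirical covariance of Vec(C) over
  ## 2000 replicates must match Sigma_c (x) F within 3 standard errors
  set.seed(10)
  K <- buildKernel(matrix(rnorm(4 * 30), 4, 30))
  Fm <- similarityMatrix(K)
  sC <- matrix(c(1, 0.4, 0.4, 0.8), 2, 2)
  nrep <- 2000
  vecs <- vapply(seq_len(nrep), function(r) {
    as.vector(behaviorValues(
      simulateBehavior(K, list(sC), matrix(0, 2, 2), seed = 10000 + r)))
  }, numeric(8))
  emp <- tcrossprod(vecs - rowMeans(vecs)) / (nrep - 1)
  theo <- kronecker(sC, Fm)
  se <- sqrt((outer(diag(theo), diag(theo)) + theo^2) / nrep)
  expect_true(all(abs(emp - theo) <= 3.5 * se))
})

test_that("behavior ground truth records the exact trace ratio", {
  K <- latentKernel(40, seed = 1)
  bm <- simulateBehavior(K, list(diag(0.4, 5)), diag(0.6, 5), seed = 2)
  tr <- groundTruth(bm)
  expect_equal(tr$trueM, 0.4)
  expect_equal(unname(tr$trueMi), rep(0.4, 5))
  ## null model: fitted M stays near zero
  bm0 <- simulateBehavior(K, list(diag(0, 5)), diag(1, 5), seed = 3)
  expect_equal(groundTruth(bm0)$trueM, 0)
  expect_lt(fitVCM(behaviorValues(bm0), K)@M, 0.15)
})

test_that("pure-signal draws have subject Gram structure proportional to F", {
  set.seed(11)
  K <- buildKernel(matrix(rnorm(6 * 40), 6, 40))
  Fm <- similarityMatrix(K)
  G <- matrix(0, 6, 6)
  nrep <- 400
  for (r in seq_len(nrep)) {
    Y <- behaviorValues(simulateBehavior(K, list(diag(1, 3)), diag(0, 3),
                                         seed = 500 + r))
    G <- G + tcrossprod(Y) / 3
  }
  expect_equal(G / nrep, Fm, tolerance = 0.15, ignore_attr = TRUE)
  expect_error(simulateBehavior(K, list(diag(1, 3)), diag(0, 4), seed = 1),
               "dimension")
})

test_that("cohort bundles are reproducible and complete", {
  cfg <- defaultCohortConfig(seed = 42)
  cfg$nSubjects <- 10L
  cfg$networkSizes <- c(A = 5L, B = 5L, C = 5L, D = 5L)
  cfg$nFrames <- 150L
  cfg$nTask <- 3L; cfg$nSelf <- 2L; cfg$nUnclassified <- 1L
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  co <- buildCohort(cfg, d1)
  buildCohort(cfg, d2)
  expect_true(file.exists(file.path(d1, "behavior.csv")))
  expect_identical(readLines(file.path(d1, "behavior.csv")),
                   readLines(file.path(d2, "behavior.csv")))
  expect_identical(readLines(file.path(d1, "timeseries", "sub-003_run-2.tsv")),
                   readLines(file.path(d2, "timeseries", "sub-003_run-2.tsv")))
  ## loading round-trips the key objects
  loaded <- loadCohort(d1)
  expect_equal(length(loaded$runs), 10L)
  expect_equal(dim(behaviorValues(loaded$behavior)), c(10L, 6L))
  expect_equal(unname(measureCategories(loaded$behavior)),
               rep(c("task", "self", "unclassified"), c(3, 2, 1)))
  expect_equal(runData(loaded$runs[[2]][[1]]),
               runData(co$runs[[2]][[1]]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(loaded$behavior@metadata$groundTruth$trueM, co$truth$trueM,
               tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)

  cfg$nSubjects <- 0L
  expect_error(buildCohort(cfg, tempfile()), "invalid config")
})
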