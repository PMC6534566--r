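test_that("the jackknife engine reproduces the closed form for a mean", {
  y <- c(1, 2, 3)
  jk <- deleteOneJackknife(function(i) mean(y[i]), 3)
  expect_equal(unname(jk$estimate), 2)
  expect_equal(unname(jk$variance), 1 / 3)   # s^2 / n exactly
  for (s in 1:5) {
    set.seed(s)
    y <- rnorm(20)
    jk <- deleteOneJackknife(function(i) mean(y[i]), 20)
    expect_equal(unname(jk$variance), var(y) / 20, tolerance = 1e-12)
    expect_equal(unname(jk$estimate), mean(y), tolerance = 1e-12)
  }
})

test_that("identical models give zero difference and p = 1", {
  K <- latentKernel(40, seed = 1)
  set.seed(2)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  cmp <- suppressWarnings(jackknifeCompare(Y, K, K))
  expect_equal(unname(cmp@overall$estimate), 0)
  expect_equal(unname(cmp@overall$p), 1)
  expect_true(all(cmp@perMeasure$p == 1))
})

test_that("swapping the models negates every statistic exactly", {
  K1 <- latentKernel(40, seed = 3)
  K2 <- latentKernel(40, seed = 4)
  set.seed(5)
  Y <- matrix(rnorm(40 * 4), 40, 4)
  cats <- c("task", "task", "self", "self")
  a <- suppressWarnings(jackknifeCompare(Y, K1, K2, categories = cats))
  b <- suppressWarnings(jackknifeCompare(Y, K2, K1, categories = cats))
  expect_equal(unname(a@overall$estimate), -unname(b@overall$estimate),
               tolerance = 1e-12)
  expect_equal(a@perMeasure$T, -b@perMeasure$T, tolerance = 1e-10)
  expect_equal(a@contrasts$estimate, -b@contrasts$estimate, tolerance = 1e-12)
})

test_that("category contrasts aggregate the right measures", {
  K1 <- latentKernel(45, seed = 6)
  K2 <- latentKernel(45, seed = 7)
  set.seed(8)
  Y <- matrix(rnorm(45 * 5), 45, 5)
  cats <- c("task", "task", "self", "unclassified", "self")
  cmp <- suppressWarnings(jackknifeCompare(Y, K1, K2, categories = cats))
  lo <- cmp@leaveOne
  n <- cmp@nSubjects
  taskMean <- rowMeans(lo[, 1 + which(cats == "task")])
  expect_equal(cmp@contrasts$estimate[cmp@contrasts$contrast == "task_mean"],
               mean(taskMean), tolerance = 1e-12)
  inter <- taskMean - rowMeans(lo[, 1 + which(cats == "self")])
  expect_equal(cmp@contrasts$estimate[cmp@contrasts$contrast == "interaction"],
               mean(inter), tolerance = 1e-12)
  ## unclassified measures are absent from all contrasts
  expect_setequal(cmp@contrasts$contrast,
                  c("task_mean", "self_mean", "interaction"))
})

test_that("measure ranking is descending with deterministic tie-breaks", {
  pm <- data.frame(measure = c("b", "a", "c"), dMi = c(0.1, 0.2, 0.1),
                   se = 1, T = c(0.5, 0.5, -1), p = 0.5,
                   category = "task", stringsAsFactors = FALSE)
  cmp <- new("JackknifeComparison", overall = list(), perMeasure = pm,
             contrasts = data.frame(), leaveOne = matrix(0, 2, 2),
             nSubjects = 2L)
  rk <- rankMeasures(cmp)
  expect_equal(rk$measure, c("a", "b", "c"))   # tie at T=0.5 broken by name
  expect_equal(rk$rank, 1:3)
})

test_that("BH rejection matches the exhaustive step-up definition", {
  r <- fdrBH(c(0.01, 0.02, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_equal(fdrBH(rep(1, 5))$nRejected, 0L)
  for (s in 1:200) {
    set.seed(s)
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_identical(fdrBH(p, 0.05)$reject, bhOracle(p, 0.05))
  }
  expect_error(fdrBH(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("block contributions recover a single dominant block pair", {
  set.seed(9)
  parc <- Parcellation(sprintf("r%d", 1:6), rep(c("A", "B"), each = 3))
  N <- 50
  ## subjects share structure only in the A~B cross block
  fcs <- lapply(1:N, function(s) {
    M <- matrix(rnorm(36, sd = 0.2), 6, 6)
    M[1:3, 4:6] <- M[1:3, 4:6] + rnorm(1, sd = 1.5)
    new("DynamicFC", A = M, residCov = diag(6), r2 = 0.5, nPairs = 100L,
        rank = 6L)
  })
  dec <- blockDecompositionKernels(fcs, parc)
  ## behavior correlated with the cross-block signature
  sig <- vapply(fcs, function(f) mean(fcMatrix(f)[1:3, 4:6]), numeric(1))
  Y <- cbind(scale(sig) + rnorm(N, sd = 0.5), rnorm(N))
  res <- blockContributions(Y, dec, measures = 1)
  expect_equal(sum(res$share), 1, tolerance = 1e-12)
  expect_equal(res$pair[which.max(res$share)], "A~B")
  expect_true(res$significant[res$pair == "A~B"])
})
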