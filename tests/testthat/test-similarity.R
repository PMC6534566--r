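test_that("vectorization lengths match the degrees of freedom", {
  R <- 419
  M <- matrix(rnorm(R * R), R, R)
  S <- (M + t(M)) / 2; diag(S) <- 1; S <- pmin(pmax(S, -1), 1)
  sfc <- new("StaticFC", fc = S)
  expect_length(vectorizeFC(sfc), R * (R - 1) / 2)   # 87 571
  dfc <- new("DynamicFC", A = M, residCov = diag(R), r2 = 0.5,
             nPairs = 1000L, rank = as.integer(R))
  expect_length(vectorizeFC(dfc), R^2)               # 175 561
})

test_that("block vectorization selects the right entries", {
  p <- makeParcellation(4, c(A = 2, B = 2))
  A <- matrix(seq_len(16), 4, 4)
  dfc <- new("DynamicFC", A = A, residCov = diag(4), r2 = 0.5,
             nPairs = 10L, rank = 4L)
  ## dynamic between: both directed blocks, 2x2 + 2x2 = 8 entries
  v <- vectorizeFC(dfc, p, block = "between", networks = c("A", "B"))
  expect_length(v, 8)
  expect_setequal(v, c(A[1:2, 3:4], A[3:4, 1:2]))
  ## dynamic within: all 4 block entries including the diagonal
  expect_setequal(vectorizeFC(dfc, p, block = "within", networks = "A"),
                  as.vector(A[1:2, 1:2]))
  S <- (A + t(A)) / 2; diag(S) <- 1
  S <- S / max(abs(S))
  diag(S) <- 1
  sfc <- new("StaticFC", fc = S)
  expect_length(vectorizeFC(sfc, p, block = "within", networks = "A"), 1)
  expect_length(vectorizeFC(sfc, p, block = "between", networks = c("A", "B")), 4)
  expect_error(vectorizeFC(dfc, p, block = "within", networks = "Z"),
               "unknown")
})

test_that("similarity kernels are Pearson correlations between subjects", {
  ## identical subjects: all-ones kernel
  V <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(similarityMatrix(buildKernel(V))), matrix(1, 3, 3))
  ## anti-correlated pair
  V <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(similarityMatrix(buildKernel(V))[1, 2], -1)
  ## printed 3-subject fixture against the hand Pearson formula
  V <- rbind(c(0.2, -0.1, 0.4, 0.3),
             c(0.1, 0.0, 0.5, 0.1),
             c(-0.3, 0.2, -0.4, 0.0))
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  K <- similarityMatrix(buildKernel(V))
  expect_equal(K[1, 2], pearson(V[1, ], V[2, ]), tolerance = 1e-12)
  expect_equal(K[1, 3], pearson(V[1, ], V[3, ]), tolerance = 1e-12)
  expect_equal(K[2, 3], pearson(V[2, ], V[3, ]), tolerance = 1e-12)
  expect_error(buildKernel(rbind(rep(1, 4), c(1, 2, 3, 4))), "constant")
})

test_that("kernels are equivariant under subject permutation", {
  set.seed(5)
  V <- matrix(rnorm(8 * 20), 8, 20)
  K <- similarityMatrix(buildKernel(V))
  p <- sample(8)
  Kp <- similarityMatrix(buildKernel(V[p, ]))
  expect_equal(Kp, K[p, p], tolerance = 1e-12)
})

test_that("block decomposition reconstructs the standardized kernel", {
  set.seed(6)
  parc <- toyParcellation()
  fcs <- lapply(1:7, function(s) {
    M <- matrix(rnorm(64), 8, 8)
    new("DynamicFC", A = M, residCov = diag(8), r2 = 0.5, nPairs = 100L,
        rank = 8L)
  })
  dec <- blockDecompositionKernels(fcs, parc)
  expect_equal(sum(dec$pairs$weight), 1, tolerance = 1e-12)
  recon <- Reduce(`+`, Map(`*`, dec$kernels, dec$pairs$weight))
  expect_lt(max(abs(recon - dec$fStd)), 1e-10)
  ## single block covering everything recovers fStd exactly
  parc1 <- Parcellation(sprintf("r%d", 1:8), rep(c("A", "B"), 4))
  one <- blockDecompositionKernels(fcs, parc1)
  whole <- Reduce(`+`, Map(`*`, one$kernels, one$pairs$weight))
  expect_lt(max(abs(whole - one$fStd)), 1e-10)
  ## static variant: strict upper triangle, grouped by unordered pair
  sfcs <- lapply(1:7, function(s) {
    M <- cov2cor(crossprod(matrix(rnorm(120), 15, 8)))
    new("StaticFC", fc = M)
  })
  decS <- blockDecompositionKernels(sfcs, parc)
  expect_equal(sum(decS$pairs$P), 8 * 7 / 2)
  reconS <- Reduce(`+`, Map(`*`, decS$kernels, decS$pairs$weight))
  expect_lt(max(abs(reconS - decS$fStd)), 1e-10)
})

test_that("constant FC entries are excluded with a message", {
  parc <- Parcellation(sprintf("r%d", 1:4), c("A", "A", "B", "B"))
  fcs <- lapply(1:5, function(s) {
    M <- matrix(rnorm(16), 4, 4)
    M[1, 2] <- 0.5   # constant across subjects
    new("DynamicFC", A = M, residCov = diag(4), r2 = 0.5, nPairs = 50L,
        rank = 4L)
  })
  expect_message(dec <- blockDecompositionKernels(fcs, parc), "constant")
  expect_equal(dec$nExcluded, 1L)
  recon <- Reduce(`+`, Map(`*`, dec$kernels, dec$pairs$weight))
  expect_lt(max(abs(recon - dec$fStd)), 1e-10)
})
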