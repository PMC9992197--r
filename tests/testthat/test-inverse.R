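test_that("depth weights follow the column-norm power law and clip", {
  G <- cbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 10))
  expect_equal(depthWeights(G, exponent = 0), rep(1, 3))
  w <- depthWeights(G, exponent = 0.5, limit = 1000)
  expect_equal(w, c(1, 1 / 2, 1 / 10))
  # clipping bounds the dynamic range by limit^2
  for (lim in c(1, 2, 3)) {
    wc <- depthWeights(G, exponent = 1, limit = lim)
    expect_lte(max(wc) / min(wc), lim^2 + 1e-12)
  }
  expect_error(depthWeights(cbind(G, 0), exponent = 0.5), "zero-norm")
  expect_error(depthWeights(G, exponent = 2), "exponent")
})

test_that("the kernel solves the penalized least-squares problem", {
  set.seed(7)
  for (rep in 1:5) {
    C <- crossprod(matrix(rnorm(144), 12)) / 12 + diag(12)
    G <- matrix(rnorm(12 * 20), 12, 20)
    w <- runif(20, 0.5, 2)
    b <- matrix(rnorm(12 * 3), 12, 3)
    inv <- buildInverse(G, C, lambda2 = 0.33, weights = w)
    s1 <- kernelMatrix(inv) %*% b
    s2 <- oracle_mne_solve(G, C, 0.33, w, b)
    expect_lt(max(abs(s1 - s2)) / max(abs(s2)), 1e-8)
  }
})

test_that("the unregularized limit recovers the inverse of a square gain", {
  set.seed(9)
  G <- matrix(rnorm(64), 8) + diag(8) * 3
  inv <- buildInverse(G, diag(8), lambda2 = 1e-10, weights = rep(1, 8))
  expect_lt(max(abs(kernelMatrix(inv) %*% G - diag(8))), 1e-6)
  # zero data give zero sources at any regularization
  inv2 <- buildInverse(G, diag(8), lambda2 = 0.33, weights = rep(1, 8))
  expect_equal(kernelMatrix(inv2) %*% matrix(0, 8, 5), matrix(0, 8, 5))
  # estimates scale linearly with the data
  b <- matrix(rnorm(8 * 4), 8, 4)
  expect_equal(kernelMatrix(inv2) %*% (3 * b),
               3 * (kernelMatrix(inv2) %*% b), tolerance = 1e-12)
  expect_error(buildInverse(G, -diag(8), lambda2 = 0.33,
                            weights = rep(1, 8)), "positive definite")
  expect_error(buildInverse(G, diag(8), lambda2 = 0), "lambda2")
})

test_that("application streams in blocks without changing the result", {
  w <- fx_world()
  rec <- simulateSubject(w$design, w$space, w$array, w$lf, "HC", seed = 41)
  s1 <- applyInverse(w$inv, rec)
  s2 <- applyInverse(w$inv, rec, blockSize = 100)
  s3 <- applyInverse(w$inv, rec, blockSize = 1e6)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_identical(s1, s3)
  expect_equal(dim(s1), c(nVertices(w$space), nSamples(rec)))
  expect_true(all(applyInverse(w$inv, matrix(0, 32, 10)) == 0))
  expect_error(applyInverse(w$inv, matrix(0, 30, 10)), "channels")
})

test_that("a noiseless single dipole is localized to its ROI patch", {
  g <- fx_geometry()
  G <- gainMatrix(g$lf)
  er <- simulateEmptyRoom(g$array, 30, 1e-13, 200, seed = 1)
  inv <- buildInverse(g$lf, estimateNoiseCovariance(er))
  set.seed(13)
  hits <- 0L
  for (rep in 1:10) {
    v <- sample(nVertices(g$space), 1)
    b <- G[, v, drop = FALSE] %*% matrix(sin(seq(0, 20, length.out = 200)) *
                                           1e-8, 1)
    shat <- applyInverse(inv, b)
    vhat <- which.max(rowMeans(abs(shat)))
    if (vertexLabels(g$space)[vhat] == vertexLabels(g$space)[v])
      hits <- hits + 1L
  }
  expect_gte(hits, 7)
})

test_that("depth weighting reduces the superficial localization bias", {
  g <- fx_geometry()
  G <- gainMatrix(g$lf)
  er <- simulateEmptyRoom(g$array, 30, 1e-13, 200, seed = 2)
  ncov <- estimateNoiseCovariance(er)
  inv0 <- buildInverse(g$lf, ncov, weights = depthWeights(G, exponent = 0))
  inv5 <- buildInverse(g$lf, ncov, weights = depthWeights(G, exponent = 0.5))
  depth <- sqrt(rowSums(vertexPositions(g$space)^2))
  set.seed(17)
  vs <- sample(nVertices(g$space), 24)
  bias <- function(inv) {
    mean(vapply(vs, function(v) {
      b <- G[, v, drop = FALSE] %*% matrix(1e-8, 1, 1)
      vhat <- which.max(abs(applyInverse(inv, b)))
      depth[vhat] - depth[v]
    }, numeric(1)))
  }
  # minimum-norm bias pulls estimates outward (toward larger radius);
  # depth weighting shrinks that pull
  expect_lt(abs(bias(inv5)), abs(bias(inv0)))
})
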