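test_that("the normality gate separates Gaussian from uniform samples", {
  rejUnif <- mean(vapply(1:100, function(i) {
    set.seed(i)
    !shapiroGate(runif(500))$normal
  }, logical(1)))
  expect_gte(rejUnif, 0.95)
  passGauss <- mean(vapply(1:200, function(i) {
    set.seed(i)
    shapiroGate(rnorm(500))$normal
  }, logical(1)))
  expect_gt(passGauss, 0.90)
  expect_lt(passGauss, 0.99)
  g <- shapiroGate(rep(1, 10))
  expect_true(g$degenerate)
  expect_error(shapiroGate(c(1, 2)), "at least 3")
})

test_that("Kruskal-Wallis H matches the rank-sum arithmetic and conventions", {
  kw <- kruskalWallis(1:9, rep(1:3, each = 3))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  # identical observations: H = 0, p = 1 by convention
  same <- kruskalWallis(rep(5, 9), rep(1:3, each = 3))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # exact enumeration agrees with itself run twice and with the
  # chi-square approximation on the fixture (coarsely)
  ex <- kruskalWallis(1:9, rep(1:3, each = 3), exact = TRUE)
  expect_equal(ex$H, 7.2, tolerance = 1e-12)
  expect_equal(ex$method, "exact permutation")
  # permutation p of the maximal separation = number of orderings giving
  # H >= 7.2; for {1..9} split 3/3/3 that is 6/1680
  expect_equal(ex$p, 6 / choose(9, 3) / choose(6, 3), tolerance = 1e-12)
  expect_error(kruskalWallis(1:5, rep(1, 5)), "2 groups")
})

test_that("chi-square and exact permutation p agree on small samples", {
  # the chi-square reference is an approximation: at n = (4,4,4) its
  # mean absolute deviation from the enumerated permutation p is ~0.03
  set.seed(42)
  devs <- vapply(1:20, function(i) {
    x <- rnorm(12)
    g <- rep(1:3, each = 4)
    abs(kruskalWallis(x, g)$p - kruskalWallis(x, g, exact = TRUE)$p)
  }, numeric(1))
  expect_lt(mean(devs), 0.05)
  # "auto" switches to enumeration at and below total n = 10
  x <- rnorm(9)
  expect_equal(kruskalWallis(x, rep(1:3, 3), exact = "auto")$method,
               "exact permutation")
  expect_equal(kruskalWallis(rnorm(12), rep(1:3, 4), exact = "auto")$method,
               "chi-square")
})

test_that("post hoc pairwise tests are Bonferroni-scaled and clipped", {
  set.seed(6)
  x <- c(rnorm(10), rnorm(10) + 0.2, rnorm(10) + 3)
  g <- rep(c("A", "B", "C"), each = 10)
  ph <- pairwisePosthoc(x, g)
  expect_equal(nrow(ph), 3)
  expect_setequal(ph$contrast, c("A-B", "A-C", "B-C"))
  expect_true(all(ph$p_bonf >= ph$p_raw))
  expect_true(all(ph$p_bonf <= 1))
  expect_equal(ph$p_bonf, pmin(1, ph$p_raw * 3))
  # a weak pair is clipped at 1 (raw 0.4 -> 1.0)
  expect_equal(ph$p_bonf[ph$p_raw > 1 / 3], rep(1, sum(ph$p_raw > 1 / 3)))
  expect_error(pairwisePosthoc(rnorm(5), rep("A", 5)), "2 groups")
})

test_that("Benjamini-Hochberg step-up rejects exactly the right set", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.25)
  fdr <- bhFdr(p, q = 0.05)
  expect_identical(fdr$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(fdr$adjusted >= p))
  # sorted adjusted p's are monotone
  expect_true(all(diff(fdr$adjusted[order(p)]) >= 0))
  all1 <- bhFdr(rep(1, 10))
  expect_false(any(all1$reject))
  expect_true(all(all1$adjusted == 1))
  one <- bhFdr(0.04)
  expect_equal(one$adjusted, 0.04)
  expect_true(one$reject)
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("empirical FDR stays controlled on simulated p-mixtures", {
  set.seed(123)
  m <- 200
  fdp <- vapply(1:500, function(i) {
    isNull <- runif(m) < 0.8
    p <- ifelse(isNull, runif(m), rbeta(m, 0.1, 1))
    rej <- bhFdr(p, q = 0.05)$reject
    if (!any(rej)) return(0)
    sum(rej & isNull) / sum(rej)
  }, numeric(1))
  expect_lte(mean(fdp), 0.07)
})

test_that("correlation method follows the normality gate", {
  x <- 1:20
  ex <- clinicalCorrelation(x, 2 * x + 1)
  expect_equal(ex$R, 1, tolerance = 1e-12)
  # strictly decreasing monotone transform: Spearman -1
  set.seed(2)
  xr <- rexp(20)^2                       # clearly non-normal
  mono <- clinicalCorrelation(xr, -xr^3)
  expect_equal(mono$method, "spearman")
  expect_equal(mono$R, -1, tolerance = 1e-12)
  # Spearman agrees with the brute-force rank formula on a 6-point fixture
  a <- c(3.1, 0.2, 5.5, 2.2, 9.0, 4.4)
  b <- c(1.0, 2.5, 0.7, 8.8, 3.2, 6.1)
  got <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))$estimate
  expect_equal(unname(got), oracle_spearman(a, b), tolerance = 1e-12)
  expect_error(clinicalCorrelation(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(clinicalCorrelation(1:3, 1:3), "at least 4")
})

test_that("summary t-tests reproduce the cognitive-score group contrasts", {
  # CI vs CNI full-scale IQ: overwhelming difference in either variant
  for (variant in c("welch", "pooled")) {
    r <- summaryTTest(84.63, 4.79, 24, 107.79, 8.03, 24, variant = variant)
    expect_lt(r$p, 0.001)
  }
  pooled <- summaryTTest(84.63, 4.79, 24, 107.79, 8.03, 24, "pooled")
  sp2 <- (23 * 4.79^2 + 23 * 8.03^2) / 46
  tdirect <- (84.63 - 107.79) / sqrt(sp2 * (2 / 24))
  expect_equal(pooled$t, tdirect, tolerance = 1e-12)
  expect_equal(abs(pooled$t), 12.13, tolerance = 0.01)
  expect_equal(pooled$df, 46)
  same <- summaryTTest(10, 2, 12, 10, 2, 12)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # resampling cross-check: samples matching the summaries give a similar t
  set.seed(31)
  ts <- vapply(1:200, function(i) {
    a <- rnorm(24, 84.63, 4.79); b <- rnorm(24, 107.79, 8.03)
    a <- (a - mean(a)) / sd(a) * 4.79 + 84.63
    b <- (b - mean(b)) / sd(b) * 8.03 + 107.79
    t.test(a, b, var.equal = TRUE)$statistic
  }, numeric(1))
  expect_lt(abs(mean(ts) - tdirect), 0.05)
  expect_error(summaryTTest(1, 0, 5, 2, 1, 5), "sds")
})
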