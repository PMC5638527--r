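test_that("spearman correlation matches the brute-force mid-rank oracle", {
  r1 <- spearman_cor(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r1$r, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(30, 20, 10))$r, -1)

  expect_equal(spearman_cor(c(1, 2, 2, 4), c(3, 1, 4, 4))$r,
               oracle_spearman_r(c(1, 2, 2, 4), c(3, 1, 4, 4)),
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE) + runif(n, 0, 0.01) * (i %% 2)
    y <- sample(1:5, n, replace = TRUE)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    expect_equal(spearman_cor(x, y)$r, oracle_spearman_r(x, y),
                 tolerance = 1e-10)
  }
  expect_error(spearman_cor(1:3, 1:4), "length")
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40)
  base <- spearman_cor(x, y)$r
  expect_equal(spearman_cor(exp(x), y)$r, base, tolerance = 1e-12)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$r, base, tolerance = 1e-12)
  expect_equal(spearman_cor(-x, y)$r, -base, tolerance = 1e-12)
})

test_that("spearman p-value matches the t approximation of cor.test", {
  set.seed(12)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  ours <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
})

test_that("standardized regression reduces to known closed forms", {
  set.seed(31)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50)
  res <- regress_standardized(y, cbind(x = x))
  expect_equal(res$coefficients$beta, cor(x, y), tolerance = 1e-10)

  # exactly orthogonal z-scored predictors: betas = marginal correlations
  z1 <- scale(rnorm(40))
  z2 <- scale(residuals(lm(rnorm(40) ~ z1)))
  z2 <- z2 / sd(z2)
  yy <- 0.5 * z1 - 0.3 * z2 + rnorm(40, 0, 0.5)
  res2 <- regress_standardized(yy, cbind(a = z1, b = z2))
  # independent route: normal equations on standardized variables
  Z <- scale(cbind(z1, z2)); zy <- scale(yy)
  betas <- solve(crossprod(Z), crossprod(Z, zy))
  expect_equal(res2$coefficients$beta, drop(betas), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(res2$coefficients$beta,
               c(cor(z1, yy), cor(z2, yy)), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(regress_standardized(yy, cbind(a = z1, b = z1)), "collinear")
})

test_that("standardized betas are invariant to affine predictor rescaling", {
  set.seed(77)
  X <- cbind(al = rnorm(60, 25, 1.4), pmp = rnorm(60, 5, 3))
  y <- -10 * X[, 1] + 2 * X[, 2] + rnorm(60, 0, 5)
  b1 <- regress_standardized(y, X)$coefficients$beta
  X2 <- cbind(al = 1000 * X[, 1] - 3, pmp = X[, 2] / 7 + 2)
  b2 <- regress_standardized(y, X2)$coefficients$beta
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("Steel-Dwass behaves on identical and separated groups", {
  same <- list(a = rep(c(1, 2, 3), 3), b = rep(c(1, 2, 3), 3),
               c = rep(c(1, 2, 3), 3))
  res <- steel_dwass(same)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p > 0.999))

  far <- list(g1 = 1:10, g2 = 1:10, g3 = 101:110)
  res2 <- steel_dwass(far)
  p3 <- res2$p[res2$group1 == "g3" | res2$group2 == "g3"]
  expect_true(all(p3 < 0.01))
  expect_gt(res2$p[res2$group1 == "g1" & res2$group2 == "g2"], 0.99)

  expect_error(steel_dwass(list(1:5)), "2")
  expect_error(steel_dwass(list(1:5, 2)), "at least 2 observations")
})

test_that("Steel-Dwass with two groups reduces to the Mann-Whitney p", {
  set.seed(60)
  for (i in 1:10) {
    a <- rnorm(sample(5:15, 1))
    b <- rnorm(sample(5:15, 1), mean = runif(1, -1, 1))
    sd2 <- steel_dwass(list(a = a, b = b))
    expect_equal(sd2$p, mann_whitney(a, b, method = "normal", correct = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("Steel-Dwass adjusted p penalizes relative to the pairwise p", {
  set.seed(61)
  gs <- list(a = rnorm(12), b = rnorm(12, 0.5), c = rnorm(12, 1))
  res <- steel_dwass(gs)
  raw <- c(mann_whitney(gs$a, gs$b, correct = FALSE),
           mann_whitney(gs$a, gs$c, correct = FALSE),
           mann_whitney(gs$b, gs$c, correct = FALSE))
  expect_true(all(res$p >= raw - 1e-12))
})

test_that("Mann-Whitney p-values behave at the extremes and under ties", {
  expect_gt(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.9)
  # complete separation of 3 vs 3: exact two-sided p = 2/C(6,3) = 0.1
  expect_equal(mann_whitney(c(1, 2, 3), c(100, 101, 102), method = "exact"),
               0.1, tolerance = 1e-12)
  a <- c(1, 2, 2, 5); b <- c(2, 3, 5, 6)
  expect_equal(mann_whitney(a, b, method = "exact"), oracle_mw_exact(a, b),
               tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Fisher-z comparison of correlations matches the closed form", {
  expect_equal(compare_correlations(0.5, 30, 0.5, 50), 1)
  z <- (atanh(0.8) - atanh(0)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(z, 5.326, tolerance = 1e-3)
  expect_lt(compare_correlations(0.8, 50, 0.0, 50), 1e-6)
  expect_equal(compare_correlations(0.8, 50, 0.0, 50),
               2 * pnorm(-z), tolerance = 1e-12)
  expect_equal(compare_correlations(0.3, 40, -0.2, 25),
               compare_correlations(-0.2, 25, 0.3, 40), tolerance = 1e-15)
  expect_error(compare_correlations(1, 10, 0.5, 10), "\\|r\\| < 1")
})
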