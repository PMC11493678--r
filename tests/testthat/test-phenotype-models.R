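test_that("just-identified CFA matches the closed-form loading solution", {
  target <- diag(3)
  target[1, 2] <- target[2, 1] <- 0.48
  target[1, 3] <- target[3, 1] <- 0.40
  target[2, 3] <- target[3, 2] <- 0.30
  X <- exact_corr_data(500, target, seed = 31)
  fit <- fit_one_factor_cfa(X)
  # closed form: lambda_1 = sqrt(r12 r13 / r23) etc.
  expect_equal(unname(fit$loadings),
               c(sqrt(.48 * .40 / .30), sqrt(.48 * .30 / .40),
                 sqrt(.40 * .30 / .48)),
               tolerance = 1e-5)
  expect_false(fit$heywood)
})

test_that("CFA recovers generating loadings from exact-moment data", {
  lam <- c(0.7, 0.7, 0.7, 0.7)
  target <- tcrossprod(lam) + diag(1 - lam^2)
  X <- exact_corr_data(10000, target, seed = 32)
  fit <- fit_one_factor_cfa(X)
  expect_equal(unname(fit$loadings), lam, tolerance = 1e-3)
  expect_equal(unname(fit$theta), 1 - lam^2, tolerance = 1e-3)
})

test_that("CFA on sampled one-factor data recovers loadings within 3 SE", {
  lam <- c(0.8, 0.6, 0.7, 0.5)
  set.seed(test_seed("cfa-sampled"))
  n <- 5000
  F <- stats::rnorm(n)
  X <- sapply(lam, function(l) l * F + sqrt(1 - l^2) * stats::rnorm(n))
  fit <- fit_one_factor_cfa(X)
  se_approx <- sqrt(1 - lam^2) / sqrt(n) * 2  # conservative loading SE
  expect_true(all(abs(fit$loadings - lam) < 3 * pmax(se_approx, 0.01)))
})

test_that("uncorrelated indicators are flagged degenerate; <3 indicators error", {
  # over-identified case (4 indicators) so sampling noise in the pairwise
  # correlations cannot masquerade as a common factor
  set.seed(test_seed("cfa-degenerate"))
  X <- matrix(stats::rnorm(20000), 5000, 4)
  fit <- fit_one_factor_cfa(X)
  expect_true(fit$degenerate)
  # the factor explains no covariance: implied cross-covariances ~ 0
  cross <- tcrossprod(fit$loadings)[upper.tri(diag(4))]
  expect_lt(max(abs(cross)), 0.05)
  expect_error(fit_one_factor_cfa(X[, 1:2]), "under-identified")
})

test_that("factor scores equal the GLS projection and shrink", {
  lam <- c(0.8, 0.6, 0.5)
  model <- structure(list(loadings = lam, theta = 1 - lam^2,
                          indicator_names = NULL), class = "factor_model")
  set.seed(test_seed("scores"))
  F <- stats::rnorm(2000)
  X <- sapply(lam, function(l) l * F + sqrt(1 - l^2) * stats::rnorm(2000))
  sc <- factor_scores(model, X)
  # brute-force GLS projection on standardized indicators
  w <- solve(tcrossprod(lam) + diag(1 - lam^2), lam)
  expect_equal(sc, as.vector(scale(X) %*% w), tolerance = 1e-10)
  expect_lte(stats::sd(sc), 1)
  # all-missing row -> NA
  X2 <- X; X2[5, ] <- NA
  expect_true(is.na(factor_scores(model, X2)[5]))
})

test_that("the g composite is a restandardized mean, permutation invariant", {
  set.seed(test_seed("gcomp"))
  X <- matrix(stats::rnorm(400), 100, 4)
  g1 <- g_composite(X)
  g2 <- g_composite(X[, c(3, 1, 4, 2)])
  expect_equal(as.numeric(g1), as.numeric(g2), tolerance = 1e-12)
  expect_equal(stats::sd(g1), 1, tolerance = 1e-9)
  # identical tests reproduce the (standardized) test itself
  x <- stats::rnorm(50)
  gx <- g_composite(cbind(x, x, x, x))
  expect_equal(as.numeric(gx), as.numeric(scale(x)), tolerance = 1e-9)
  # hand-computed 3-row toy: means of standardized columns, restandardized
  toy <- rbind(c(1, 2), c(2, 4), c(3, 6))
  m <- rowMeans(scale(toy))
  expect_equal(as.numeric(g_composite(toy, max_missing = 0)),
               as.numeric((m - mean(m)) / stats::sd(m)), tolerance = 1e-9)
  # one missing test tolerated and flagged; all missing -> NA
  toy2 <- rbind(c(1, 2, 3, 4), c(2, NA, 1, 0), c(NA, NA, NA, NA),
                c(0, 1, -1, 2))
  gc <- g_composite(toy2)
  expect_true(attr(gc, "partial")[2])
  expect_true(is.na(gc[3]))
})

test_that("correlation CI behaves at the degenerate and antisymmetric edges", {
  set.seed(test_seed("corr-ci"))
  x <- stats::rnorm(100); y <- stats::rnorm(100)
  expect_true(corr_with_ci(x, x)$degenerate)
  r1 <- corr_with_ci(x, y); r2 <- corr_with_ci(x, -y)
  expect_equal(r1$r, -r2$r)
  expect_equal(r1$ci, -rev(r2$ci))
  expect_error(corr_with_ci(x, rep(1, 100)), "zero-variance")
})

test_that("Fisher-z CI coverage is nominal at n = 500, r = 0.4", {
  set.seed(test_seed("corr-coverage"))
  rho <- 0.4
  hits <- replicate(2000, {
    x <- stats::rnorm(500)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(500)
    ci <- corr_with_ci(x, y)$ci
    ci[1] <= rho && rho <= ci[2]
  })
  expect_gte(mean(hits), 0.94)
  expect_lte(mean(hits), 0.96)
})

test_that("standardized regression matches the normal equations oracle", {
  set.seed(test_seed("reg-oracle"))
  X <- matrix(stats::rnorm(300), 100, 3)
  y <- X %*% c(0.3, -0.2, 0.5) + stats::rnorm(100)
  res <- standardized_multiple_regression(y, as.data.frame(X))
  Xs <- cbind(1, scale(X)); ys <- scale(y)
  b <- solve(crossprod(Xs), crossprod(Xs, ys))
  expect_equal(res$coef$beta, as.numeric(b[-1]), tolerance = 1e-10)
  # R^2 identity: beta' r_xy on standardized variables
  r_xy <- drop(stats::cor(X, y))
  expect_equal(res$r_squared, sum(res$coef$beta * r_xy), tolerance = 1e-10)
})

test_that("orthogonal predictors recover their marginal correlations", {
  set.seed(test_seed("reg-orth"))
  n <- 4000
  x1 <- stats::rnorm(n); x1 <- x1 - mean(x1)
  x2 <- stats::residuals(stats::lm(stats::rnorm(n) ~ x1))  # centered, x2'x1 = 0
  y <- 0.4 * x1 - 0.3 * x2 + stats::rnorm(n)
  res <- standardized_multiple_regression(y, data.frame(a = x1, b = x2))
  expect_within(res$coef$beta, c(stats::cor(x1, y), stats::cor(x2, y)), 1e-10)
})

test_that("zero-variance and collinear designs are rejected by name", {
  y <- stats::rnorm(50)
  expect_error(standardized_multiple_regression(y, data.frame(x = rep(2, 50))),
               "zero-variance")
  x <- stats::rnorm(50)
  expect_error(standardized_multiple_regression(y, data.frame(a = x, b = x)),
               "collinear")
})

test_that("R^2 is invariant under affine rescaling of the inputs", {
  set.seed(test_seed("reg-affine"))
  X <- matrix(stats::rnorm(200), 100, 2)
  y <- X %*% c(0.5, 0.2) + stats::rnorm(100)
  r1 <- standardized_multiple_regression(y, as.data.frame(X))
  r2 <- standardized_multiple_regression(3 * y - 1,
                                         as.data.frame(sweep(X, 2, c(2, 0.5), "*") + 7))
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-10)
  expect_equal(r1$coef$beta, r2$coef$beta, tolerance = 1e-10)
})
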