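test_that("cluster sandwich matches a hand-computed toy and the HC0 limit", {
  set.seed(test_seed("sandwich-toy"))
  y <- stats::rnorm(12); x <- stats::rnorm(12); cl <- rep(1:4, each = 3)
  fit <- cluster_robust_fit(y, data.frame(x = x), cluster = cl)
  Xd <- cbind(1, as.vector(scale(x))); ys <- as.vector(scale(y))
  b <- solve(crossprod(Xd), crossprod(Xd, ys))
  r <- ys - Xd %*% b
  meat <- matrix(0, 2, 2)
  for (g in 1:4) {
    i <- cl == g
    s <- crossprod(Xd[i, , drop = FALSE], r[i])
    meat <- meat + s %*% t(s)
  }
  V <- solve(crossprod(Xd)) %*% meat %*% solve(crossprod(Xd))
  expect_equal(fit$coef$se, sqrt(V[2, 2]), tolerance = 1e-10)

  # singleton clusters: cluster sandwich = HC0
  set.seed(test_seed("sandwich-hc0"))
  y2 <- stats::rnorm(80); x2 <- stats::rnorm(80)
  f_singleton <- cluster_robust_fit(y2, data.frame(x = x2), cluster = 1:80)
  lmfit <- stats::lm(scale(y2) ~ scale(x2))
  hc0 <- sqrt(diag(sandwich::vcovHC(lmfit, type = "HC0")))[2]
  expect_equal(f_singleton$coef$se, unname(hc0), tolerance = 1e-10)
})

test_that("duplicating rows within clusters leaves point estimates unchanged", {
  set.seed(test_seed("sandwich-dup"))
  y <- stats::rnorm(60); x <- stats::rnorm(60); cl <- rep(1:20, each = 3)
  f1 <- cluster_robust_fit(y, data.frame(x = x), cluster = cl)
  idx <- rep(seq_along(y), 2)
  f2 <- cluster_robust_fit(y[idx], data.frame(x = x[idx]), cluster = cl[idx])
  expect_equal(f2$coef$beta, f1$coef$beta, tolerance = 1e-12)
})

test_that("within/between fit rejects MZ pairs and degenerates gracefully", {
  set.seed(test_seed("wb-edges"))
  fam <- rep(1:50, each = 2)
  pc <- stats::rnorm(100); pn <- stats::rnorm(100)
  expect_error(
    within_between_fit(stats::rnorm(100), pc, pn, family_id = fam,
                       zygosity = rep("MZ", 100)),
    "MZ pairs")
  # constant outcome: all coefficients zero, variance components ~0
  fit0 <- within_between_fit(rep(1, 100), pc, pn, family_id = fam)
  expect_true(all(abs(fit0$coef$beta) < 1e-8))
  expect_lt(fit0$sigma2_family + fit0$sigma2_residual, 1e-8)
  # unpaired individuals dropped with a message
  expect_message(
    within_between_fit(stats::rnorm(101), c(pc, 1), c(pn, 1),
                       family_id = c(fam, 99)),
    "unpaired")
})

test_that("GxE interaction coefficient is invariant to SES centering", {
  set.seed(test_seed("gxe-centering"))
  n <- 600
  fam <- rep(seq_len(n / 2), each = 2)
  pc <- stats::rnorm(n); pn <- stats::rnorm(n); ses <- stats::rnorm(n)[fam]
  y <- 0.2 * pc + 0.1 * pn + 0.3 * ses + 0.08 * pn * ses + stats::rnorm(n)
  f1 <- gxe_fit(y, pc, pn, ses, family_id = fam,
                covariate_interactions = FALSE)
  f2 <- gxe_fit(y, pc, pn, ses + 5, family_id = fam,
                covariate_interactions = FALSE)
  i1 <- f1$coef[f1$coef$term %in% f1$interaction, "beta"]
  i2 <- f2$coef[f2$coef$term %in% f2$interaction, "beta"]
  # both PGS are standardized inside; SES shift only moves main effects
  expect_equal(i1, i2, tolerance = 1e-6)
})

test_that("an injected PGS x SES interaction is recovered", {
  set.seed(test_seed("gxe-recovery"))
  n <- 8000
  fam <- rep(seq_len(n / 2), each = 2)
  pc <- stats::rnorm(n); pn <- stats::rnorm(n)
  ses <- stats::rnorm(n / 2)[fam]
  y <- 0.2 * pc + 0.15 * pn + 0.3 * ses + 0.08 * pn * ses +
    stats::rnorm(n / 2)[fam] * 0.4 + stats::rnorm(n) * 0.8
  fit <- gxe_fit(y, pc, pn, ses, family_id = fam,
                 covariate_interactions = FALSE)
  co <- fit$coef
  b_int <- co[co$term == "pgs_noncog:ses", ]
  # recovered on the standardized-y scale
  expect_within(b_int$beta, 0.08 / stats::sd(y), 0.03)
  b_null <- co[co$term == "pgs_cog:ses", ]
  expect_lt(abs(b_null$beta), 2.5 * b_null$se + 0.01)
})

test_that("null-interaction CIs cover zero at a near-nominal rate", {
  # scaled-down coverage study (80 replicates, n = 1200)
  set.seed(test_seed("gxe-coverage"))
  hits <- replicate(80, {
    n <- 1200
    fam <- rep(seq_len(n / 2), each = 2)
    pc <- stats::rnorm(n); pn <- stats::rnorm(n); ses <- stats::rnorm(n / 2)[fam]
    y <- 0.2 * pc + 0.1 * pn + 0.3 * ses + stats::rnorm(n / 2)[fam] * 0.4 +
      stats::rnorm(n)
    fit <- gxe_fit(y, pc, pn, ses, family_id = fam,
                   covariate_interactions = FALSE)
    co <- fit$coef[fit$coef$term == "pgs_noncog:ses", ]
    co$ci_lo <= 0 && 0 <= co$ci_hi
  })
  expect_gte(mean(hits), 0.88)
})

test_that("SES strata cut exactly 25/50/25 and equal slopes stay equal", {
  set.seed(test_seed("strata"))
  n <- 4000
  pc <- stats::rnorm(n); pn <- stats::rnorm(n); ses <- stats::rnorm(n)
  y <- 0.25 * pc + 0.2 * pn + 0.3 * ses + stats::rnorm(n)
  st <- ses_strata_slopes(y, pc, pn, ses)
  expect_equal(st$n[st$term == "pgs_cog"], c(1000, 2000, 1000))
  for (term in c("pgs_cog", "pgs_noncog")) {
    d <- st[st$term == term, ]
    for (i in 1:2) for (j in (i + 1):3) {
      z <- abs(d$beta[i] - d$beta[j]) / sqrt(d$se[i]^2 + d$se[j]^2)
      expect_lt(z, 3)
    }
  }
  expect_error(ses_strata_slopes(y[1:50], pc[1:50], pn[1:50], ses[1:50],
                                 min_per_stratum = 30), "fewer than")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  bh_brute <- function(p) {
    n <- length(p)
    o <- order(p)
    ranked <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(ranked)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(test_seed("bh"))
  for (rep in 1:1000) {
    m <- sample(1:40, 1)
    p <- stats::runif(m)^sample(c(1, 2, 4), 1)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # permutation equivariance
  p <- stats::runif(20)
  perm <- sample.int(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("a single-age cohort leaves the developmental trend undefined", {
  cfg <- sim_config(n_mz_pairs = 60, n_dz_pairs = 60, n_snps = 100,
                    block_size = 1, decay = 0, ages = 16,
                    delta_cog = 0.2, delta_noncog = 0.15, delta_spec = 0.4,
                    n_causal = list(cog = 25, noncog = 25, ach_specific = 25),
                    seed = test_seed("single-age"))
  panel <- build_ld_panel(cfg$n_snps, cfg$block_size, seed = 61)
  g <- simulate_families(panel, 60, 60, seed = 62)
  co <- simulate_phenotypes(g, cfg)
  tr <- co$truth$individuals
  scores <- data.frame(family_id = tr$family_id, member = tr$member,
                       cog = tr$g_cog, noncog = tr$g_noncog)
  expect_warning(prof <- developmental_profile(co, scores, B = 0),
                 "undefined")
  expect_false(prof$trend_defined)
})
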