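test_that("subtraction model is self-consistent on an exactly generated S", {
  cfg <- sim_config()
  S <- implied_s_target(cfg)
  fit <- fit_subtraction_model(S, V = NULL)
  L <- cfg$gwas_loadings
  expect_equal(unname(fit$loadings_cog), unname(L[, "Cog"]), tolerance = 1e-4)
  expect_equal(unname(fit$loadings_noncog),
               unname(L[c("EA", "IN", "DE"), "NonCog"]), tolerance = 1e-4)
  expect_equal(unname(fit$residuals), cfg$h2_resid, tolerance = 1e-4)
  expect_lt(fit$fit_value, 1e-8)
  expect_equal(fit$implied_S[lower.tri(fit$implied_S, diag = TRUE)],
               S[lower.tri(S, diag = TRUE)], tolerance = 1e-4)
})

test_that("the EA variance decomposition identity holds by construction", {
  cfg <- sim_config()
  fit <- fit_subtraction_model(implied_s_target(cfg), V = NULL)
  S_imp <- fit$implied_S
  noncog_var_EA <- S_imp["EA", "EA"] - fit$loadings_cog["EA"]^2 -
    fit$residuals["EA"]
  expect_equal(unname(noncog_var_EA), unname(fit$loadings_noncog["EA"]^2),
               tolerance = 1e-10)
  # the two factors are uncorrelated in the implied structure: the EA-CP
  # covariance carries no NonCog contribution
  expect_equal(unname(S_imp["EA", "CP"]),
               unname(fit$loadings_cog["EA"] * fit$loadings_cog["CP"]),
               tolerance = 1e-10)
})

test_that("per-SNP latent effects match the two-indicator subtraction formula", {
  model <- structure(list(
    loadings_cog = stats::setNames(c(0.9, 0.5, 0.5, 0.4, 0.3, 0.4, 0.3, -0.3),
                                   gwas_trait_names()),
    loadings_noncog = stats::setNames(c(0.6, 0.45, -0.5), c("EA", "IN", "DE"))),
    class = "subtraction_model")
  M <- 1000
  set.seed(test_seed("snp-two-ind"))
  mk <- function(z, n) data.frame(SNP = sprintf("rs%04d", 1:M), CHR = 1,
                                  BP = 1:M, A1 = "A", A2 = "G", MAF = 0.3,
                                  N = n, Z = z, stringsAsFactors = FALSE)
  zCP <- stats::rnorm(M); zEA <- stats::rnorm(M)
  latent <- snp_effects(model, list(CP = mk(zCP, 1e5), EA = mk(zEA, 1e5)))
  bCP <- zCP / sqrt(1e5); bEA <- zEA / sqrt(1e5)
  b_cog <- bCP / 0.9
  b_noncog <- (bEA - 0.4 * b_cog) / 0.6
  expect_equal(latent$factors$Cog$BETA, b_cog, tolerance = 1e-8)
  expect_equal(latent$factors$NonCog$BETA, b_noncog, tolerance = 1e-8)
})

test_that("null SNPs map to zero latent effects; implied effects reproduce inputs", {
  model <- structure(list(
    loadings_cog = stats::setNames(c(0.9, 0.5, 0.5, 0.4, 0.3, 0.4, 0.3, -0.3),
                                   gwas_trait_names()),
    loadings_noncog = stats::setNames(c(0.6, 0.45, -0.5), c("EA", "IN", "DE"))),
    class = "subtraction_model")
  mk0 <- function(n) data.frame(SNP = c("a", "b"), CHR = 1, BP = 1:2,
                                A1 = "A", A2 = "G", MAF = 0.3, N = n, Z = 0,
                                stringsAsFactors = FALSE)
  latent <- snp_effects(model, list(CP = mk0(1e5), EA = mk0(1e5)))
  expect_equal(latent$factors$Cog$BETA, c(0, 0))
  expect_equal(latent$factors$NonCog$BETA, c(0, 0))
  # consistency: for the just-identified system, lambda * beta reproduces b
  set.seed(test_seed("snp-consistency"))
  mk <- function(z) data.frame(SNP = "x", CHR = 1, BP = 1, A1 = "A", A2 = "G",
                               MAF = 0.3, N = 1e5, Z = z, stringsAsFactors = FALSE)
  lt <- snp_effects(model, list(CP = mk(1.7), EA = mk(-0.4)))
  b_hat_CP <- 0.9 * lt$factors$Cog$BETA
  b_hat_EA <- 0.4 * lt$factors$Cog$BETA + 0.6 * lt$factors$NonCog$BETA
  expect_equal(b_hat_CP, 1.7 / sqrt(1e5), tolerance = 1e-10)
  expect_equal(b_hat_EA, -0.4 / sqrt(1e5), tolerance = 1e-10)
})

test_that("end-to-end: sumstats from a known structure recover the loadings", {
  cfg <- sim_config(N_gwas = rep(1e5, 8))
  S_true <- implied_s_target(cfg)
  panel <- validation_panel(8000)
  ss <- simulate_sumstats(S_true, cfg$N_gwas, panel,
                          seed = test_seed("gsem-end2end"))
  h <- harmonize(ss)
  sv <- build_s_v(h, panel$ldscore, n_blocks = 100)
  fit <- fit_subtraction_model(sv$S, sv$V)
  L <- cfg$gwas_loadings
  devs <- c(fit$loadings_cog - L[, "Cog"],
            fit$loadings_noncog - L[c("EA", "IN", "DE"), "NonCog"],
            fit$residuals - cfg$h2_resid)
  expect_true(all(abs(devs) < 2.8 * fit$se + 0.01))
})

test_that("latent factor rg with a genetically identical external trait is ~1", {
  cfg <- sim_config(N_gwas = rep(2e5, 8))
  panel <- validation_panel(6000)
  M <- panel$n_snps
  set.seed(test_seed("rg-external"))
  u_c <- stats::rnorm(M) / sqrt(M); u_n <- stats::rnorm(M) / sqrt(M)
  L <- cfg$gwas_loadings
  B <- cbind(u_c, u_n) %*% t(L) +
    sweep(matrix(stats::rnorm(M * 8), M, 8), 2, sqrt(cfg$h2_resid / M), "*")
  colnames(B) <- gwas_trait_names()
  ss <- simulate_sumstats_from_effects(B, cfg$N_gwas, panel,
                                       seed = test_seed("rg-external-noise"))
  sv <- build_s_v(harmonize(ss), panel$ldscore, n_blocks = 60)
  fit <- fit_subtraction_model(sv$S, sv$V)
  latent <- snp_effects(fit, harmonize(ss))
  # external trait driven purely by the NonCog genetic factor
  ext <- simulate_sumstats_from_effects(
    cbind(EXT = 0.7 * u_n), 2e5, panel, seed = test_seed("rg-external-ext"))
  r_non <- rg_external(latent, "NonCog", ext$traits$EXT, panel$ldscore,
                       n_blocks = 60)
  expect_gt(r_non$rg, 0.85)
  r_cog <- rg_external(latent, "Cog", ext$traits$EXT, panel$ldscore,
                       n_blocks = 60)
  expect_lt(abs(r_cog$rg), 2.5 * r_cog$rg_se + 0.05)
})
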