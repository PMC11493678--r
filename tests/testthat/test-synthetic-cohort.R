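test_that("LD panel blocks are valid correlation matrices with brute-force LD scores", {
  panel <- build_ld_panel(100, 20, decay = 0.6, seed = 1)
  for (B in panel$blocks) {
    expect_equal(diag(B), rep(1, nrow(B)))
    expect_equal(B, t(B))
    expect_gt(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  l_bf <- unlist(lapply(panel$blocks, function(B) rowSums(B^2)))
  expect_equal(panel$ldscore, l_bf, tolerance = 1e-12)
  expect_true(all(panel$ldscore >= 1 - 1e-9))
  expect_equal(sum(lengths(panel$block_index)), 100L)
})

test_that("unit blocks and zero decay both give the LD-free panel", {
  p1 <- build_ld_panel(50, 1, decay = 0.6, seed = 2)
  p0 <- build_ld_panel(50, 10, decay = 0, seed = 2)
  expect_equal(p1$ldscore, rep(1, 50))
  expect_equal(unname(p0$ldscore), rep(1, 50))
  for (B in p0$blocks) expect_equal(B, diag(nrow(B)))
  expect_equal(p1$maf, p0$maf)  # same seed, same MAF draw
})

test_that("mixed block patterns produce the requested geometry", {
  p <- build_ld_panel(60, c(1, 1, 8), decay = c(0, 0, 0.85), seed = 3)
  sizes <- lengths(p$block_index)
  expect_equal(sizes[1:3], c(1L, 1L, 8L))
  expect_equal(sum(sizes), 60L)
  expect_gt(max(p$ldscore), 3)
  expect_equal(min(p$ldscore), 1)
})

test_that("MZ co-twins have identical dosage rows and parents are present", {
  panel <- build_ld_panel(300, 10, decay = 0.4, seed = 4)
  g <- simulate_families(panel, 30, 30, seed = test_seed("geno-basic"))
  off <- g$info[g$info$role == "offspring", ]
  expect_equal(nrow(off), 120L)
  expect_equal(sum(g$info$role == "parent"), 120L)
  for (f in unique(off$family_id[off$zygosity == "MZ"])) {
    rows <- which(g$info$family_id == f & g$info$role == "offspring")
    expect_identical(g$dosage[rows[1], ], g$dosage[rows[2], ])
  }
  expect_true(all(g$dosage %in% 0:2))
  # every offspring family has two parent rows
  par_cnt <- table(g$info$family_id[g$info$role == "parent"])
  expect_true(all(par_cnt == 2))
})

test_that("DZ co-twins are related 0.5 and offspring preserve allele frequencies", {
  panel <- build_ld_panel(10000, 1, decay = 0, seed = 2)
  g <- simulate_families(panel, 0, 400, seed = test_seed("geno-dz"))
  off <- g$info$role == "offspring"
  D <- scale(g$dosage[off, ])
  i1 <- seq(1, 800, 2); i2 <- seq(2, 800, 2)
  r <- rowSums(D[i1, ] * D[i2, ]) / (ncol(D) - 1)
  expect_within(mean(r), 0.5, 0.02)
  # offspring allele frequencies track panel MAF (binomial sampling scale)
  freq <- colMeans(g$dosage[off, ]) / 2
  se <- sqrt(panel$maf * (1 - panel$maf) / (2 * sum(off)))
  expect_gt(mean(abs(freq - panel$maf) < 3.5 * se), 0.98)
})

test_that("phenotype columns have unit variance and truth table is coherent", {
  cfg <- sim_config(n_mz_pairs = 1000, n_dz_pairs = 1000, n_snps = 600,
                    block_size = 1, decay = 0,
                    n_causal = list(cog = 150, noncog = 150, ach_specific = 150),
                    seed = test_seed("pheno-var"))
  panel <- build_ld_panel(cfg$n_snps, cfg$block_size, cfg$maf_range,
                          cfg$decay, seed = 11)
  g <- simulate_families(panel, cfg$n_mz_pairs, cfg$n_dz_pairs, seed = 12)
  co <- simulate_phenotypes(g, cfg)
  for (age in co$ages) {
    d <- cohort_slice(co, age, "self")
    for (col in c("ncs_edu_1", "ncs_selfreg_3", "cog_v1", "achievement")) {
      expect_equal(stats::var(d[[col]]), 1, tolerance = 0.08)
      expect_equal(mean(d[[col]]), 0, tolerance = 0.08)
    }
  }
  tr <- co$truth$individuals
  expect_equal(nrow(tr), 4000L)
  # genetic values standardized; MZ co-twins share them exactly
  expect_equal(stats::sd(tr$g_cog), 1, tolerance = 0.05)
  mz <- tr[tr$zygosity == "MZ", ]
  expect_equal(mz$g_noncog[mz$member == 1], mz$g_noncog[mz$member == 2])
  # SES constant within family, zygosity constant within family
  expect_true(all(tapply(co$data$ses, co$data$family_id,
                         function(v) length(unique(v))) == 1))
})

test_that("noise-free indicators reproduce the latent factors exactly", {
  cfg <- sim_config(n_mz_pairs = 50, n_dz_pairs = 50, n_snps = 200,
                    block_size = 1, decay = 0,
                    loadings = list(cog = rep(1, 4), ncs_edu = rep(1, 4),
                                    ncs_selfreg = rep(1, 4)),
                    rater_reliability = 1,
                    n_causal = list(cog = 50, noncog = 50, ach_specific = 50),
                    seed = test_seed("pheno-noisefree"))
  panel <- build_ld_panel(cfg$n_snps, cfg$block_size, cfg$maf_range,
                          cfg$decay, seed = 13)
  g <- simulate_families(panel, cfg$n_mz_pairs, cfg$n_dz_pairs, seed = 14)
  co <- simulate_phenotypes(g, cfg)
  d <- cohort_slice(co, co$ages[2], "teacher")
  lat <- co$truth$latents
  lat <- lat[lat$age == co$ages[2], ]
  m <- merge(d, lat, by = c("family_id", "member"))
  expect_equal(m$ncs_edu_1, m$ncs_edu, tolerance = 1e-12)
  expect_equal(m$ncs_selfreg_4, m$ncs_selfreg, tolerance = 1e-12)
  expect_equal(m$cog_v2, m$cog, tolerance = 1e-12)
})

test_that("an over-committed achievement variance budget names the age", {
  expect_error(
    sim_config(delta_spec = rep(0.9, 4), ses_effect = 0.4),
    "achievement variance budget exceeded at age 7")
})

test_that("simulated sumstats obey the null and LDSC chi-square expectations", {
  panel <- build_ld_panel(20000, 1, decay = 0, seed = 6)
  ss0 <- simulate_sumstats(matrix(0, 1, 1), 50000, panel,
                           seed = test_seed("ss-null"))
  chi2 <- ss0$traits[[1]]$Z^2
  expect_equal(mean(chi2), 1, tolerance = 0.03)

  ss1 <- simulate_sumstats(matrix(0.4, 1, 1), 50000, panel,
                           seed = test_seed("ss-h2"))
  # E[chi2] = 1 + N h2 / M = 2 for the LD-free panel
  expect_within(mean(ss1$traits[[1]]$Z^2), 2, 0.05)

  ss2 <- simulate_sumstats(diag(c(0.3, 0.3)), 50000, panel,
                           seed = test_seed("ss-rg0"))
  z1z2 <- ss2$traits[[1]]$Z * ss2$traits[[2]]$Z
  expect_lt(abs(mean(z1z2)), 3 * stats::sd(z1z2) / sqrt(length(z1z2)))
})

test_that("a non-PSD genetic covariance target is rejected with eigenvalues", {
  S_bad <- matrix(c(0.4, 0.9, 0.9, 0.4), 2)
  panel <- build_ld_panel(300, 1, decay = 0, seed = 7)
  expect_error(simulate_sumstats(S_bad, 1e4, panel), "eigenvalue")
})

test_that("factor-consistent sumstats reproduce the implied genetic covariance", {
  cfg <- sim_config(n_mz_pairs = 200, n_dz_pairs = 200, n_snps = 4000,
                    block_size = 1, decay = 0, N_gwas = rep(2e5, 8),
                    n_causal = list(cog = 800, noncog = 800, ach_specific = 800),
                    seed = test_seed("ss-factor"))
  panel <- build_ld_panel(cfg$n_snps, cfg$block_size, cfg$maf_range,
                          cfg$decay, seed = 8)
  g <- simulate_families(panel, cfg$n_mz_pairs, cfg$n_dz_pairs, seed = 9)
  co <- simulate_phenotypes(g, cfg)
  fss <- simulate_sumstats_factor(co$truth$architecture, cfg, panel)
  # cross-trait Z products concentrate on the target genetic covariance
  S_t <- implied_s_target(cfg)
  zCP <- fss$sumstats$traits$CP$Z; zEA <- fss$sumstats$traits$EA$Z
  est <- (mean(zCP * zEA)) * cfg$n_snps / sqrt(2e5 * 2e5)
  expect_within(est, S_t["CP", "EA"], 0.06)
  # latent effect vectors have unit genetic variance by construction
  expect_equal(sum(fss$latent_effects[, "Cog"]^2), 1, tolerance = 1e-9)
})
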