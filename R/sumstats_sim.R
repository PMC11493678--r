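#' Simulate multi-trait GWAS summary statistics from a genetic covariance target
#'
#' Per-SNP true joint effects across `K` traits are drawn i.i.d. from
#' `N(0, S_target / M)` (standardized genotype and phenotype scales), so the
#' aggregate genetic covariance equals `S_target`. Marginal GWAS estimates
#' then follow the LD-score regression generative model:
#' `beta_hat = D beta_true + e`, `e ~ N(0, D / N)` blockwise, and
#' `Z = beta_hat * sqrt(N)`, which implies `E[chi2_j] = 1 + N h2 l_j / M`.
#' Sampling noise is independent across traits (no GWAS sample overlap).
#'
#' @param S_target `K x K` positive semi-definite genetic covariance matrix;
#'   its diagonal holds the per-trait SNP heritabilities.
#' @param N_gwas length-`K` GWAS sample sizes.
#' @param panel an [build_ld_panel()] object.
#' @param seed integer seed.
#' @param traits trait names (default from `S_target` dimnames, else T1..TK).
#' @return A `sumstats_set`: named list of per-trait data frames with
#'   columns `SNP CHR BP A1 A2 MAF N Z` over the shared SNP map.
#' @export
simulate_sumstats <- function(S_target, N_gwas, panel, seed = 1L, traits = NULL) {
  stopifnot(is.matrix(S_target), nrow(S_target) == ncol(S_target))
  K <- nrow(S_target)
  if (length(N_gwas) == 1L) N_gwas <- rep(N_gwas, K)
  stopifnot(length(N_gwas) == K, all(N_gwas > 0))
  ev <- eigen((S_target + t(S_target)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("S_target is not positive semi-definite; eigenvalues: %s",
                 paste(signif(ev, 3), collapse = ", ")))
  }
  if (is.null(traits)) {
    traits <- if (!is.null(rownames(S_target))) rownames(S_target)
              else paste0("T", seq_len(K))
  }
  M <- panel$n_snps
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  # draw true effects with cross-trait covariance S/M
  S_half <- .mat_sqrt((S_target + t(S_target)) / 2)
  B <- matrix(stats::rnorm(M * K), M, K) %*% S_half / sqrt(M)
  ss <- .marginalize_effects(B, N_gwas, panel, traits)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  ss
}

#' Simulate GWAS summary statistics from explicit per-SNP true effects
#'
#' Same marginalization as [simulate_sumstats()] but with a caller-supplied
#' true joint effect matrix, used by the pipeline to keep the GWAS traits
#' genetically consistent with the simulated cohort (shared causal variants).
#'
#' @param true_effects `M x K` matrix of standardized per-SNP effects.
#' @param N_gwas length-`K` sample sizes.
#' @param panel LD panel.
#' @param seed integer seed.
#' @param traits trait names.
#' @return A `sumstats_set`.
#' @export
simulate_sumstats_from_effects <- function(true_effects, N_gwas, panel,
                                           seed = 1L, traits = NULL) {
  stopifnot(is.matrix(true_effects), nrow(true_effects) == panel$n_snps)
  K <- ncol(true_effects)
  if (length(N_gwas) == 1L) N_gwas <- rep(N_gwas, K)
  if (is.null(traits)) {
    traits <- if (!is.null(colnames(true_effects))) colnames(true_effects)
              else paste0("T", seq_len(K))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  ss <- .marginalize_effects(true_effects, N_gwas, panel, traits)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  ss
}

# beta_hat = D beta + chol(D)' z / sqrt(N), blockwise; returns sumstats_set
.marginalize_effects <- function(B, N_gwas, panel, traits) {
  M <- panel$n_snps
  K <- ncol(B)
  chols <- .panel_chol(panel)
  Bhat <- matrix(NA_real_, M, K)
  for (b in seq_along(panel$blocks)) {
    idx <- panel$block_index[[b]]
    Dm <- panel$blocks[[b]]
    noise <- t(chols[[b]]) %*% matrix(stats::rnorm(length(idx) * K), length(idx), K)
    Bhat[idx, ] <- Dm %*% B[idx, , drop = FALSE] +
      sweep(noise, 2, sqrt(N_gwas), "/")
  }
  out <- lapply(seq_len(K), function(k) {
    data.frame(SNP = panel$snp, CHR = panel$chr, BP = panel$bp,
               A1 = panel$A1, A2 = panel$A2, MAF = panel$maf,
               N = N_gwas[k], Z = Bhat[, k] * sqrt(N_gwas[k]),
               stringsAsFactors = FALSE)
  })
  names(out) <- traits
  structure(list(traits = out, snp = panel$snp), class = "sumstats_set")
}

#' Build the eight-trait GWAS summary statistics of the synthetic study
#'
#' Trait-level true effects are `Lambda %*% t(u_cog, u_noncog)` plus
#' trait-specific residual effects with heritability `h2_resid`, where the
#' latent effect vectors are the cohort's own causal effects (normalized to
#' unit genetic variance on the panel). The implied genetic covariance is
#' [implied_s_target()].
#'
#' @param arch causal architecture (`truth$architecture` of a cohort, or the
#'   equivalent list with `set_cog`, `set_non`, `u_cog`, `u_noncog`).
#' @param config a [sim_config()].
#' @param panel LD panel the cohort was genotyped on.
#' @return list with the `sumstats_set` (`$sumstats`) and the true latent
#'   per-SNP effect matrix (`$latent_effects`, columns Cog/NonCog).
#' @export
simulate_sumstats_factor <- function(arch, config, panel) {
  M <- panel$n_snps
  u_c <- .embed_normalized(arch$u_cog, arch$set_cog, panel)
  u_n <- .embed_normalized(arch$u_noncog, arch$set_non, panel)
  L <- config$gwas_loadings
  resid <- with_substream(config$seed, "sumstats_resid", {
    sweep(matrix(stats::rnorm(M * 8L), M, 8L), 2, sqrt(config$h2_resid / M), "*")
  })
  B <- cbind(u_c, u_n) %*% t(L) + resid
  colnames(B) <- gwas_trait_names()
  ss <- with_substream(config$seed, "sumstats_noise",
                       .marginalize_effects(B, config$N_gwas, panel,
                                            gwas_trait_names()))
  list(sumstats = ss, latent_effects = cbind(Cog = u_c, NonCog = u_n))
}

# embed causal effects into an M-vector scaled so the genetic variance
# (w' D w over blocks) is exactly 1
.embed_normalized <- function(u, snp_idx, panel) {
  v <- 0
  for (b in seq_along(panel$blocks)) {
    idx <- panel$block_index[[b]]
    sel <- match(intersect(idx, snp_idx), snp_idx)
    if (!length(sel)) next
    pos <- match(snp_idx[sel], idx)
    v <- v + drop(t(u[sel]) %*% panel$blocks[[b]][pos, pos, drop = FALSE] %*% u[sel])
  }
  out <- numeric(panel$n_snps)
  out[snp_idx] <- u / sqrt(v)
  out
}

.mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

#' @export
print.sumstats_set <- function(x, ...) {
  cat(sprintf("<sumstats_set> %d traits (%s) x %d SNPs\n",
              length(x$traits), paste(names(x$traits), collapse = ", "),
              length(x$snp)))
  invisible(x)
}
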