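#' Simulation configuration for the synthetic twin-cohort study
#'
#' Bundles every knob of the synthetic study: cohort sizes, LD panel
#' geometry, ACE variance shares of the latent traits, indicator loadings,
#' the developmental direct-effect schedules for achievement, indirect
#' (parental-genotype) effect sizes, SES and population-stratification
#' confounds, and the generating structure of the eight GWAS traits used by
#' the genomic SEM stage.
#'
#' Defaults encode the study conditions the package emulates: four
#' measurement waves at ages 7/9/12/16; a flat cognitive direct-effect
#' schedule with a rising non-cognitive schedule (developmental
#' amplification); indirect effects of the same order as the direct ones,
#' which roughly halves within-family coefficients relative to
#' population-level ones; latent heritabilities of 0.5 (cognitive) and 0.4
#' (non-cognitive skills).
#'
#' @param n_mz_pairs,n_dz_pairs numbers of MZ and DZ twin pairs.
#' @param n_snps,block_size,maf_range,decay LD panel geometry, see
#'   [build_ld_panel()].
#' @param ages strictly increasing measurement ages (years).
#' @param ace_variances named list of `c(a2, c2, e2)` for latent traits
#'   `cog`, `ncs_edu`, `ncs_selfreg`; each triple must sum to 1.
#' @param loadings named list of per-indicator loading vectors.
#' @param ach_c2 shared-environment share of achievement variance; the
#'   non-shared remainder is solved per age from the variance budget.
#' @param n_causal named list of causal-SNP counts for the `cog`,
#'   `noncog` and `ach_specific` genetic factors; `NULL` means 5% of
#'   `n_snps` each.
#' @param overlap_causal,overlap_cor if `TRUE`, the cog and noncog causal
#'   sets coincide and their per-SNP effects correlate `overlap_cor`
#'   (default mirrors the modest cognitive/non-cognitive genetic overlap);
#'   if `FALSE` (default) the sets are disjoint.
#' @param delta_cog,delta_noncog,delta_spec per-age direct-effect SDs of the
#'   cognitive, non-cognitive and achievement-specific genetic factors on
#'   achievement (standardized scale).
#' @param eta_cog,eta_noncog indirect-effect SDs: coefficients on the
#'   parental mean genetic value, capturing passive gene-environment
#'   correlation / demographic confounding.
#' @param ses_effect SD-units effect of family SES on achievement; SES is
#'   exogenous (independent of genotype) unless stratification is on.
#' @param strat_strength SD-units effect of a geography-like stratification
#'   axis on achievement; `strat_geno_shift` is the liability-threshold
#'   shift the same axis applies to allele frequencies.
#' @param rater_reliability squared correlation between a rater-specific
#'   view of a latent trait and the latent itself.
#' @param gwas_loadings 8 x 2 matrix of generating loadings of the GWAS
#'   traits (rows `CP, SD, ME, TM, RT, EA, IN, DE`) on the latent `Cog` and
#'   `NonCog` genetic factors.
#' @param h2_resid length-8 residual (trait-specific) SNP heritabilities.
#' @param N_gwas length-8 per-trait GWAS sample sizes.
#' @param seed master seed; all stages draw from named substreams of it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 2000L,
                       n_dz_pairs = 2000L,
                       n_snps = 20000L,
                       block_size = c(1L, 1L, 1L, 1L, 8L),
                       maf_range = c(0.05, 0.5),
                       decay = c(0, 0, 0, 0, 0.85),
                       ages = c(7, 9, 12, 16),
                       ace_variances = list(cog = c(0.5, 0.2, 0.3),
                                            ncs_edu = c(0.4, 0.2, 0.4),
                                            ncs_selfreg = c(0.4, 0.2, 0.4)),
                       loadings = list(cog = rep(0.7, 4),
                                       ncs_edu = rep(0.7, 4),
                                       ncs_selfreg = rep(0.7, 4)),
                       ach_c2 = 0.15,
                       n_causal = NULL,
                       overlap_causal = FALSE,
                       overlap_cor = 0.15,
                       delta_cog = rep(0.17, 4),
                       delta_noncog = c(0.06, 0.08, 0.11, 0.15),
                       delta_spec = rep(0.55, 4),
                       eta_cog = 0.12,
                       eta_noncog = 0.10,
                       ses_effect = 0.25,
                       strat_strength = 0.05,
                       strat_geno_shift = 0.1,
                       rater_reliability = 0.7,
                       gwas_loadings = default_gwas_loadings(),
                       h2_resid = c(0.10, 0.10, 0.10, 0.10, 0.10, 0.05, 0.05, 0.05),
                       N_gwas = rep(100000, 8),
                       seed = 20240826L) {
  cfg <- list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    n_snps = as.integer(n_snps), block_size = as.integer(block_size),
    maf_range = maf_range, decay = decay, ages = ages,
    ace_variances = ace_variances, loadings = loadings, ach_c2 = ach_c2,
    n_causal = n_causal, overlap_causal = isTRUE(overlap_causal),
    overlap_cor = overlap_cor,
    delta_cog = delta_cog, delta_noncog = delta_noncog,
    delta_spec = delta_spec, eta_cog = eta_cog, eta_noncog = eta_noncog,
    ses_effect = ses_effect, strat_strength = strat_strength,
    strat_geno_shift = strat_geno_shift,
    rater_reliability = rater_reliability,
    gwas_loadings = gwas_loadings, h2_resid = h2_resid, N_gwas = N_gwas,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Canonical GWAS trait names for the subtraction model
#' @export
gwas_trait_names <- function() c("CP", "SD", "ME", "TM", "RT", "EA", "IN", "DE")

#' Default generating loadings of the eight GWAS traits
#'
#' Five cognitive tasks load only on the Cog factor; educational
#' attainment, income and deprivation load on both Cog and NonCog, with
#' deprivation loading negatively.
#' @return 8 x 2 matrix (rows in [gwas_trait_names()] order).
#' @export
default_gwas_loadings <- function() {
  L <- cbind(Cog = c(0.9, 0.5, 0.5, 0.4, 0.3, 0.4, 0.3, -0.3),
             NonCog = c(0, 0, 0, 0, 0, 0.6, 0.45, -0.5))
  rownames(L) <- gwas_trait_names()
  L
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: ACE triples sum to 1, ages strictly
#' increasing, schedules defined for every age, the implied genetic
#' covariance of the GWAS traits PSD with diagonal in `[0, 1]`.
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly validated (errors name the offending field).
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config") || is.list(cfg))
  if (cfg$n_mz_pairs < 0 || cfg$n_dz_pairs < 0 ||
      cfg$n_mz_pairs + cfg$n_dz_pairs < 1) {
    stop("need at least one twin pair")
  }
  if (any(diff(cfg$ages) <= 0)) stop("ages must be strictly increasing")
  for (tr in names(cfg$ace_variances)) {
    v <- cfg$ace_variances[[tr]]
    if (length(v) != 3 || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop(sprintf("ace_variances$%s must be a non-negative triple summing to 1", tr))
    }
  }
  n_age <- length(cfg$ages)
  for (f in c("delta_cog", "delta_noncog", "delta_spec")) {
    v <- cfg[[f]]
    if (length(v) != n_age || any(!is.finite(v))) {
      stop(sprintf("%s must be a finite vector with one entry per age", f))
    }
  }
  if (!is.finite(cfg$eta_cog) || !is.finite(cfg$eta_noncog)) {
    stop("eta_cog and eta_noncog must be finite")
  }
  if (cfg$rater_reliability <= 0 || cfg$rater_reliability > 1) {
    stop("rater_reliability must be in (0, 1]")
  }
  L <- cfg$gwas_loadings
  if (!is.matrix(L) || nrow(L) != 8 || ncol(L) != 2) {
    stop("gwas_loadings must be an 8 x 2 matrix")
  }
  if (length(cfg$h2_resid) != 8 || any(cfg$h2_resid < 0)) {
    stop("h2_resid must be 8 non-negative values")
  }
  S <- implied_s_target(cfg)
  if (any(diag(S) < 0) || any(diag(S) > 1)) {
    stop("implied S_target diagonal must lie in [0, 1]; reduce gwas_loadings or h2_resid")
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("implied S_target is not PSD (min eigenvalue %.3e)", min(ev)))
  }
  # achievement variance budget must leave room for an E remainder
  .ach_e2_schedule(cfg)
  invisible(cfg)
}

#' Genetic covariance matrix implied by the generating loadings
#'
#' `S = Lambda Lambda' + diag(h2_resid)`: the target genetic covariance of
#' the eight GWAS traits under unit-variance, uncorrelated latent factors.
#' @param cfg a `sim_config`.
#' @return 8 x 8 symmetric matrix with trait dimnames.
#' @export
implied_s_target <- function(cfg) {
  L <- cfg$gwas_loadings
  S <- L %*% t(L) + diag(cfg$h2_resid)
  dimnames(S) <- list(gwas_trait_names(), gwas_trait_names())
  S
}

# Per-age non-shared-environment remainder of the achievement variance
# budget. var(delta*g + eta*gpar) per factor = delta^2 + 0.5 eta^2 +
# delta*eta because cov(g_child, mean parental g) = 0.5 and var(mean
# parental g) = 0.5 for standardized parental values.
.ach_e2_schedule <- function(cfg) {
  n_age <- length(cfg$ages)
  e2 <- numeric(n_age)
  for (t in seq_len(n_age)) {
    v_cog <- cfg$delta_cog[t]^2 + 0.5 * cfg$eta_cog^2 + cfg$delta_cog[t] * cfg$eta_cog
    v_non <- cfg$delta_noncog[t]^2 + 0.5 * cfg$eta_noncog^2 + cfg$delta_noncog[t] * cfg$eta_noncog
    used <- v_cog + v_non + cfg$delta_spec[t]^2 + cfg$ses_effect^2 +
      cfg$strat_strength^2 + cfg$ach_c2
    e2[t] <- 1 - used
    if (e2[t] < 0.005) {
      stop(sprintf(
        "achievement variance budget exceeded at age %s (shares sum to %.3f)",
        format(cfg$ages[t]), used))
    }
  }
  e2
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d MZ + %d DZ pairs, %d SNPs (blocks of %d), ages %s, seed %d\n",
    x$n_mz_pairs, x$n_dz_pairs, x$n_snps, x$block_size,
    paste(x$ages, collapse = "/"), x$seed))
  invisible(x)
}
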