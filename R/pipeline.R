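#' Pipeline configuration
#'
#' A [sim_config()] plus per-stage analysis options. The YAML surface of
#' [validate_config()] exposes exactly these fields; unknown keys are
#' rejected.
#'
#' @param sim a [sim_config()] (or a list of its arguments).
#' @param bootstrap_B bootstrap replicates for twin-model and trend CIs.
#' @param jackknife_blocks LDSC jackknife blocks.
#' @param ci_level confidence level for all intervals.
#' @param output_dir default output directory of [run_pipeline()].
#' @param seed master seed (overrides the sim seed when given).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), bootstrap_B = 100L,
                            jackknife_blocks = 200L, ci_level = 0.95,
                            output_dir = "noncogdev_run", seed = NULL) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, bootstrap_B = as.integer(bootstrap_B),
                 jackknife_blocks = as.integer(jackknife_blocks),
                 ci_level = ci_level, output_dir = output_dir),
            class = "pipeline_config")
}

#' Parse and validate a pipeline configuration file
#'
#' Reads a YAML file whose keys are the [sim_config()] fields plus
#' `bootstrap_B`, `jackknife_blocks`, `ci_level`, `output_dir`, `seed`.
#' Missing keys take their defaults; unknown keys raise an error naming
#' the offending key; structural invariants (ACE shares summing to 1,
#' increasing ages, PSD genetic covariance target, achievement variance
#' budget) are enforced. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path (or `NULL` for all defaults).
#' @return A `pipeline_config`.
#' @export
validate_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sim_keys <- names(formals(sim_config))
  opt_keys <- c("bootstrap_B", "jackknife_blocks", "ci_level", "output_dir",
                "seed")
  unknown <- setdiff(names(raw), c(sim_keys, opt_keys))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  sim_args <- raw[intersect(names(raw), sim_keys)]
  if (!is.null(sim_args$gwas_loadings)) {
    gl <- sim_args$gwas_loadings
    L <- do.call(rbind, lapply(gwas_trait_names(), function(tr) {
      if (is.null(gl[[tr]])) stop(sprintf("gwas_loadings missing trait '%s'", tr))
      as.numeric(gl[[tr]])
    }))
    dimnames(L) <- list(gwas_trait_names(), c("Cog", "NonCog"))
    sim_args$gwas_loadings <- L
  }
  if (!is.null(sim_args$ace_variances)) {
    sim_args$ace_variances <- lapply(sim_args$ace_variances, as.numeric)
  }
  if (!is.null(sim_args$loadings)) {
    sim_args$loadings <- lapply(sim_args$loadings, as.numeric)
  }
  sim <- do.call(sim_config, sim_args)
  opts <- raw[intersect(names(raw), opt_keys)]
  do.call(pipeline_config, c(list(sim = sim), opts))
}

#' Write a pipeline configuration back to YAML
#'
#' Round-trips with [validate_config()]: writing, re-reading and
#' re-writing yields an identical file.
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  s <- config$sim
  L <- s$gwas_loadings
  out <- list(
    n_mz_pairs = s$n_mz_pairs, n_dz_pairs = s$n_dz_pairs,
    n_snps = s$n_snps, block_size = s$block_size,
    maf_range = s$maf_range, decay = s$decay, ages = s$ages,
    ace_variances = s$ace_variances, loadings = s$loadings,
    ach_c2 = s$ach_c2, n_causal = s$n_causal,
    overlap_causal = s$overlap_causal, overlap_cor = s$overlap_cor,
    delta_cog = s$delta_cog, delta_noncog = s$delta_noncog,
    delta_spec = s$delta_spec, eta_cog = s$eta_cog,
    eta_noncog = s$eta_noncog, ses_effect = s$ses_effect,
    strat_strength = s$strat_strength, strat_geno_shift = s$strat_geno_shift,
    rater_reliability = s$rater_reliability,
    gwas_loadings = stats::setNames(
      lapply(seq_len(nrow(L)), function(i) as.numeric(L[i, ])),
      rownames(L)),
    h2_resid = s$h2_resid, N_gwas = s$N_gwas, seed = s$seed,
    bootstrap_B = config$bootstrap_B,
    jackknife_blocks = config$jackknife_blocks,
    ci_level = config$ci_level, output_dir = config$output_dir
  )
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Config hash for caching and the run manifest
#' @param config a `pipeline_config`.
#' @return md5 hex string of the canonical YAML serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  config$output_dir <- "."  # where results land does not define the run
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates all stages: `simulate` (panel, genotypes, phenotypes,
#' GWAS sumstats), `factors` (latent factors and the achievement
#' regressions beyond g), `twin` (per-age trivariate Cholesky and
#' achievement ACE), `gsem` (LDSC genetic covariance, subtraction model,
#' per-SNP latent effects), `pgs` (LDpred-inf weights and scores) and
#' `assoc` (PGS developmental trajectory, within/between-family
#' decomposition, gene-environment interactions and SES strata). Results
#' are written as TSV/CSV/JSON under `output_dir`; heavy intermediates are
#' cached as RDS keyed by the config hash, so a subset of `stages` can be
#' re-run against a cached simulation.
#'
#' @param config a `pipeline_config`.
#' @param output_dir output directory (default from the config).
#' @param stages subset of stages to run (later stages load cached
#'   intermediates).
#' @param quiet suppress progress messages.
#' @return A run manifest (list of class `run_manifest`), also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         stages = c("simulate", "factors", "twin", "gsem",
                                    "pgs", "assoc"),
                         quiet = FALSE) {
  all_stages <- c("simulate", "factors", "twin", "gsem", "pgs", "assoc")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (is.null(output_dir)) output_dir <- config$output_dir
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$sim$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config_hash = hash, seed = seed,
                   package_version = as.character(utils::packageVersion("noncogdev")),
                   stages = list())
  cache_path <- function(name) file.path(output_dir,
                                         sprintf("cache_%s_%s.rds", name, hash))
  checksum <- function(paths) {
    v <- tools::md5sum(paths)
    names(v) <- basename(names(v))
    as.list(v)
  }
  env <- new.env(parent = emptyenv())
  load_cache <- function(name) {
    p <- cache_path(name)
    if (!file.exists(p)) {
      stop(sprintf("stage '%s' needs cached '%s'; run the earlier stages first",
                   paste(stages, collapse = ","), name))
    }
    readRDS(p)
  }
  get_sim <- function() {
    if (is.null(env$sim)) env$sim <- load_cache("sim")
    env$sim
  }
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    say("[%s] running ...", name)
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), output_dir))
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      files = checksum(files))
    say("[%s] done (%.1f s)", name, manifest$stages[[name]]$seconds)
  }

  run_stage("simulate", function() {
    cfg <- config$sim
    panel <- build_ld_panel(cfg$n_snps, cfg$block_size, cfg$maf_range,
                            cfg$decay, seed = substream_seed(seed, "panel"))
    geno <- simulate_families(panel, cfg$n_mz_pairs, cfg$n_dz_pairs,
                              seed = substream_seed(seed, "genotypes"),
                              keep_parents = TRUE,
                              strat_geno_shift = cfg$strat_geno_shift)
    cohort <- simulate_phenotypes(geno, cfg)
    fss <- simulate_sumstats_factor(cohort$truth$architecture, cfg, panel)
    sim <- list(panel = panel, geno = geno, cohort = cohort,
                sumstats = fss$sumstats, latent_true = fss$latent_effects)
    saveRDS(sim, cache_path("sim"))
    env$sim <- sim
    f1 <- file.path(output_dir, "cohort.csv")
    write_cohort(cohort, f1)
    f2 <- write_sumstats(fss$sumstats, file.path(output_dir, "sumstats"))
    f3 <- write_panel(panel, file.path(output_dir, "panel"))
    c(f1, f2, f3)
  })

  run_stage("factors", function() {
    sim <- get_sim()
    cohort <- sim$cohort
    rows <- list()
    for (age in cohort$ages) {
      for (rater in c("self", "parent", "teacher")) {
        d <- cohort_slice(cohort, age, rater)
        g <- g_composite(d[, c("cog_v1", "cog_v2", "cog_nv1", "cog_nv2")])
        for (fac in c("ncs_edu", "ncs_selfreg")) {
          ind <- d[, paste0(fac, "_", 1:4)]
          cf <- fit_one_factor_cfa(ind)
          sc <- factor_scores(cf, ind)
          rr <- standardized_multiple_regression(
            d$achievement, stats::setNames(data.frame(sc, g), c(fac, "g")),
            level = config$ci_level)
          co <- rr$coef
          co$age <- age; co$rater <- rater; co$factor <- fac
          co$n <- rr$n; co$r_squared <- rr$r_squared
          rows[[length(rows) + 1L]] <- co
        }
      }
    }
    q1 <- do.call(rbind, rows)
    f <- file.path(output_dir, "q1_regressions.tsv")
    utils::write.table(q1, f, sep = "\t", row.names = FALSE, quote = FALSE)
    f
  })

  run_stage("twin", function() {
    sim <- get_sim()
    cohort <- sim$cohort
    rows <- list(); ace_rows <- list()
    for (i in seq_along(cohort$ages)) {
      age <- cohort$ages[i]
      d <- cohort_slice(cohort, age, "self")
      d$g <- g_composite(d[, c("cog_v1", "cog_v2", "cog_nv1", "cog_nv2")])
      cf <- fit_one_factor_cfa(d[, paste0("ncs_edu_", 1:4)])
      d$ncs <- factor_scores(cf, d[, paste0("ncs_edu_", 1:4)])
      pairs <- pair_traits(d, c("g", "ncs", "achievement"))
      ch <- fit_trivariate_cholesky(pairs, B = config$bootstrap_B,
                                    level = config$ci_level,
                                    seed = substream_seed(seed, paste0("chol", i)))
      dec <- ch$ach_decomposition
      ci <- if (!is.null(ch$ci)) ch$ci$A[, 3, 1:3] else matrix(NA, 2, 3)
      rows[[i]] <- data.frame(
        age = age, component = c("via_g", "via_ncs", "specific"),
        share = unname(dec), ci_lo = ci[1, ], ci_hi = ci[2, ],
        n_mz = ch$n_mz, n_dz = ch$n_dz, stringsAsFactors = FALSE)
      ace <- fit_ace(pair_traits(d, "achievement"), B = 0)
      ace_rows[[i]] <- data.frame(age = age, a2 = ace$a2, c2 = ace$c2,
                                  e2 = ace$e2, rmz = ace$rmz, rdz = ace$rdz)
    }
    f1 <- file.path(output_dir, "q2_twin_cholesky.tsv")
    utils::write.table(do.call(rbind, rows), f1, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    f2 <- file.path(output_dir, "q2_twin_ace.tsv")
    utils::write.table(do.call(rbind, ace_rows), f2, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    c(f1, f2)
  })

  run_stage("gsem", function() {
    sim <- get_sim()
    h <- harmonize(sim$sumstats)
    sv <- build_s_v(h, sim$panel$ldscore, M = sim$panel$n_snps,
                    n_blocks = config$jackknife_blocks)
    model <- fit_subtraction_model(sv$S, sv$V)
    latent <- snp_effects(model, h)
    env$gsem <- list(sv = sv, model = model, latent = latent)
    saveRDS(env$gsem, cache_path("gsem"))
    f1 <- file.path(output_dir, "gsem_model.json")
    jsonlite::write_json(list(
      loadings_cog = as.list(model$loadings_cog),
      loadings_noncog = as.list(model$loadings_noncog),
      residuals = as.list(model$residuals),
      se = as.list(model$se), fit_value = model$fit_value,
      S = sv$S, psd_projected = sv$psd_projected),
      f1, auto_unbox = TRUE, digits = NA)
    f2 <- file.path(output_dir, "cog.latent.sumstats.tsv")
    write_sumstats(latent_as_sumstats(latent, "Cog"), f2)
    f3 <- file.path(output_dir, "noncog.latent.sumstats.tsv")
    write_sumstats(latent_as_sumstats(latent, "NonCog"), f3)
    c(f1, f2, f3)
  })

  run_stage("pgs", function() {
    sim <- get_sim()
    if (is.null(env$gsem)) env$gsem <- load_cache("gsem")
    latent <- env$gsem$latent
    files <- character()
    scores <- NULL
    for (fac in c("Cog", "NonCog")) {
      ss <- latent_as_sumstats(latent, fac)
      wts <- ldpred_inf(ss, sim$panel, h2 = NULL, trait = fac)
      st <- pgs_score(sim$geno, wts)
      fw <- file.path(output_dir, sprintf("%s.weights.tsv", tolower(fac)))
      write_pgs(wts, fw)
      files <- c(files, fw)
      colnames(st)[colnames(st) == "score_std"] <- tolower(fac)
      st <- st[, c("id", "family_id", "member", "zygosity", tolower(fac))]
      scores <- if (is.null(scores)) st else merge(scores, st,
        by = c("id", "family_id", "member", "zygosity"))
    }
    names(scores)[names(scores) == "cog"] <- "cog"
    names(scores)[names(scores) == "noncog"] <- "noncog"
    env$scores <- scores
    saveRDS(scores, cache_path("scores"))
    fs <- file.path(output_dir, "pgs_scores.csv")
    utils::write.csv(scores, fs, row.names = FALSE, quote = FALSE)
    c(files, fs)
  })

  run_stage("assoc", function() {
    sim <- get_sim()
    if (is.null(env$scores)) env$scores <- load_cache("scores")
    scores <- env$scores
    cohort <- sim$cohort
    covs <- c("sex", paste0("PC", 1:10))

    prof <- developmental_profile(cohort, scores, covariates = covs,
                                  B = config$bootstrap_B,
                                  level = config$ci_level,
                                  seed = substream_seed(seed, "trend"))
    f1 <- file.path(output_dir, "q2_pgs_trajectory.tsv")
    utils::write.table(prof$trajectory, f1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    f2 <- file.path(output_dir, "q2_pgs_trend.tsv")
    utils::write.table(prof$trend, f2, sep = "\t", row.names = FALSE,
                       quote = FALSE)

    wb_rows <- list(); gxe_rows <- list()
    for (age in cohort$ages) {
      d <- cohort_slice(cohort, age, "self")
      m <- merge(d, scores, by = c("family_id", "member"))
      dz <- m[m$zygosity.x == "DZ", ]
      wb <- within_between_fit(dz$achievement, dz$cog, dz$noncog,
                               covariates = dz[covs], family_id = dz$family_id,
                               level = config$ci_level)
      co <- wb$coef; co$age <- age; co$n_pairs <- wb$n_pairs
      wb_rows[[length(wb_rows) + 1L]] <- co
      gx <- gxe_fit(m$achievement, m$cog, m$noncog, m$ses,
                    covariates = m[covs], family_id = m$family_id,
                    level = config$ci_level)
      co <- gx$coef[gx$coef$term %in% gx$interaction, ]
      co$age <- age
      gxe_rows[[length(gxe_rows) + 1L]] <- co
    }
    f3 <- file.path(output_dir, "q3_within_between.tsv")
    utils::write.table(do.call(rbind, wb_rows), f3, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    f4 <- file.path(output_dir, "q4_gxe.tsv")
    utils::write.table(do.call(rbind, gxe_rows), f4, sep = "\t",
                       row.names = FALSE, quote = FALSE)

    age_max <- max(cohort$ages)
    d <- cohort_slice(cohort, age_max, "self")
    m <- merge(d, scores, by = c("family_id", "member"))
    strata <- ses_strata_slopes(m$achievement, m$cog, m$noncog, m$ses)
    f5 <- file.path(output_dir, "q4_ses_strata.tsv")
    utils::write.table(strata, f5, sep = "\t", row.names = FALSE, quote = FALSE)
    c(f1, f2, f3, f4, f5)
  })

  manifest$finished <- TRUE
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> config %s, seed %d\n", substr(x$config_hash, 1, 8),
              x$seed))
  for (s in names(x$stages)) {
    cat(sprintf("  %-9s %6.1f s, %d file(s)\n", s, x$stages[[s]]$seconds,
                length(x$stages[[s]]$files)))
  }
  invisible(x)
}
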