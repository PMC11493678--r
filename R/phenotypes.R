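#' Simulate developmental twin phenotypes with direct and indirect genetic effects
#'
#' Builds the full phenotype surface of the synthetic study from a genotyped
#' twin sample:
#'
#' * Latent genetic factors: standardized polygenic values `g_cog`,
#'   `g_noncog` and an achievement-specific `g_spec`, each a weighted sum
#'   over its designated causal SNPs (disjoint sets by default).
#' * Latent traits per age: `cog`, `ncs_edu`, `ncs_selfreg`, each
#'   `sqrt(a2) * g + sqrt(c2) * C_family + sqrt(e2) * E_individual` with the
#'   configured ACE shares (C and E redrawn independently per age: cross-age
#'   stability flows through the genetic factor only).
#' * Achievement per age `t`:
#'   `delta_cog(t) g_cog + delta_noncog(t) g_noncog + delta_spec(t) g_spec +
#'    eta_cog gpar_cog + eta_noncog gpar_noncog + ses_effect SES +
#'    strat_strength u + sqrt(c2) C + sqrt(e2_t) E`,
#'   where `gpar` is the parental mean genetic value (the indirect-effect
#'   pathway) and `e2_t` is solved so the generating variance is exactly 1;
#'   the configured deltas are therefore standardized effect sizes.
#' * Indicators: for each non-cognitive factor and each rater
#'   (self/parent/teacher), a rater-specific view of the latent with
#'   reliability `rater_reliability`, then `lambda * view + residual` per
#'   indicator. Cognitive tests (2 verbal + 2 non-verbal) and achievement
#'   are single measurements repeated across rater rows.
#'
#' A hidden truth table (true genetic values, parental means, latent factor
#' scores) is retained for validation; it is not part of the observed
#' interface.
#'
#' @param genotypes a [simulate_families()] object (parents required unless
#'   both `eta` are 0).
#' @param config a [sim_config()].
#' @return An object of class `twin_cohort`: list with `data` (long
#'   observed table: one row per family x member x age x rater), `truth`
#'   (list of `individuals` and `latents` data frames), `ages`, `config`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_set"))
  config <- validate_sim_config(config)
  e2_sched <- .ach_e2_schedule(config)
  M <- genotypes$panel$n_snps
  seed <- config$seed

  off <- genotypes$info$role == "offspring"
  n_off <- sum(off)
  n_fam <- length(genotypes$family_id)
  has_parents <- any(genotypes$info$role == "parent")
  if (!has_parents && (config$eta_cog != 0 || config$eta_noncog != 0)) {
    stop("indirect effects (eta != 0) require keep_parents = TRUE genotypes")
  }

  # --- causal architecture ---------------------------------------------
  nc <- config$n_causal
  if (is.null(nc)) {
    k <- max(1L, round(0.05 * M))
    nc <- list(cog = k, noncog = k, ach_specific = k)
  }
  need <- if (config$overlap_causal) max(nc$cog, nc$noncog) + nc$ach_specific
          else nc$cog + nc$noncog + nc$ach_specific
  if (need > M) stop("causal sets require more SNPs than the panel holds")

  arch <- with_substream(seed, "causal", {
    perm <- sample.int(M)
    if (config$overlap_causal) {
      set_cog <- sort(perm[seq_len(nc$cog)])
      set_non <- set_cog
      set_spec <- sort(perm[nc$cog + seq_len(nc$ach_specific)])
      u_c <- stats::rnorm(nc$cog)
      r <- config$overlap_cor
      u_n <- r * u_c + sqrt(1 - r^2) * stats::rnorm(nc$cog)
    } else {
      set_cog <- sort(perm[seq_len(nc$cog)])
      set_non <- sort(perm[nc$cog + seq_len(nc$noncog)])
      set_spec <- sort(perm[nc$cog + nc$noncog + seq_len(nc$ach_specific)])
      u_c <- stats::rnorm(nc$cog)
      u_n <- stats::rnorm(nc$noncog)
    }
    list(set_cog = set_cog, set_non = set_non, set_spec = set_spec,
         u_cog = u_c, u_noncog = u_n, u_spec = stats::rnorm(nc$ach_specific))
  })

  g_cog_all <- .genetic_value(genotypes, arch$u_cog, arch$set_cog)
  g_non_all <- .genetic_value(genotypes, arch$u_noncog, arch$set_non)
  g_spec_all <- .genetic_value(genotypes, arch$u_spec, arch$set_spec)

  info_off <- genotypes$info[off, , drop = FALSE]
  g_cog <- g_cog_all[off]; g_non <- g_non_all[off]; g_spec <- g_spec_all[off]
  fam_of_off <- match(info_off$family_id, genotypes$family_id)

  if (has_parents) {
    par <- genotypes$info$role == "parent"
    fam_of_par <- match(genotypes$info$family_id[par], genotypes$family_id)
    gpar_cog_f <- as.vector(tapply(g_cog_all[par], fam_of_par, mean))
    gpar_non_f <- as.vector(tapply(g_non_all[par], fam_of_par, mean))
  } else {
    gpar_cog_f <- gpar_non_f <- rep(0, n_fam)
  }
  gpar_cog <- gpar_cog_f[fam_of_off]
  gpar_non <- gpar_non_f[fam_of_off]

  # --- family-level context --------------------------------------------
  ses_f <- with_substream(seed, "ses", stats::rnorm(n_fam))
  u_f <- genotypes$strat
  ses <- ses_f[fam_of_off]
  u_strat <- u_f[fam_of_off]

  cov_df <- with_substream(seed, "covariates", {
    sex_f <- stats::rbinom(n_fam, 1, 0.5)
    sex <- ifelse(info_off$zygosity == "MZ", sex_f[fam_of_off],
                  stats::rbinom(n_off, 1, 0.5))
    pcs <- matrix(stats::rnorm(n_off * 10L), n_off, 10L)
    pc1_f <- u_f + 0.5 * stats::rnorm(n_fam)
    pcs[, 1] <- pc1_f[fam_of_off] / sqrt(1.25)  # synthetic ancestry axis
    colnames(pcs) <- paste0("PC", 1:10)
    data.frame(sex = sex,
               chip = sample(c("chipA", "chipB"), n_off, replace = TRUE),
               batch = sample(paste0("b", 1:4), n_off, replace = TRUE),
               pcs, stringsAsFactors = FALSE)
  })

  # --- latent traits and achievement per age ---------------------------
  ages <- config$ages
  n_age <- length(ages)
  av <- config$ace_variances
  lat_list <- vector("list", n_age)
  ach <- matrix(NA_real_, n_off, n_age)
  lat_names <- c("cog", "ncs_edu", "ncs_selfreg")
  g_of <- list(cog = g_cog, ncs_edu = g_non, ncs_selfreg = g_non)

  for (t in seq_len(n_age)) {
    lt <- with_substream(seed, paste0("latents_age", t), {
      out <- matrix(NA_real_, n_off, 3L, dimnames = list(NULL, lat_names))
      for (tr in lat_names) {
        v <- av[[tr]]
        C <- stats::rnorm(n_fam)[fam_of_off]
        E <- stats::rnorm(n_off)
        out[, tr] <- sqrt(v[1]) * g_of[[tr]] + sqrt(v[2]) * C + sqrt(v[3]) * E
      }
      C_ach <- stats::rnorm(n_fam)[fam_of_off]
      E_ach <- stats::rnorm(n_off)
      a <- config$delta_cog[t] * g_cog + config$delta_noncog[t] * g_non +
        config$delta_spec[t] * g_spec +
        config$eta_cog * gpar_cog + config$eta_noncog * gpar_non +
        config$ses_effect * ses + config$strat_strength * u_strat +
        sqrt(config$ach_c2) * C_ach + sqrt(e2_sched[t]) * E_ach
      list(latents = out, ach = a)
    })
    lat_list[[t]] <- lt$latents
    ach[, t] <- lt$ach
  }

  # --- indicators -------------------------------------------------------
  raters <- c("self", "parent", "teacher")
  w <- config$rater_reliability
  rows <- vector("list", n_age * length(raters))
  k <- 0L
  for (t in seq_len(n_age)) {
    # cognitive tests are rater-invariant; draw once per age
    ctests <- with_substream(seed, paste0("cogtests_age", t), {
      lam <- config$loadings$cog
      sapply(seq_along(lam), function(j)
        lam[j] * lat_list[[t]][, "cog"] + sqrt(1 - lam[j]^2) * stats::rnorm(n_off))
    })
    colnames(ctests) <- c("cog_v1", "cog_v2", "cog_nv1", "cog_nv2")
    for (r in raters) {
      ind <- with_substream(seed, paste0("indicators_age", t, "_", r), {
        out <- list()
        for (fac in c("ncs_edu", "ncs_selfreg")) {
          lam <- config$loadings[[fac]]
          view <- sqrt(w) * lat_list[[t]][, fac] + sqrt(1 - w) * stats::rnorm(n_off)
          X <- sapply(seq_along(lam), function(j)
            lam[j] * view + sqrt(1 - lam[j]^2) * stats::rnorm(n_off))
          colnames(X) <- paste0(fac, "_", seq_along(lam))
          out[[fac]] <- X
        }
        out
      })
      k <- k + 1L
      rows[[k]] <- data.frame(
        family_id = info_off$family_id, member = info_off$member,
        zygosity = info_off$zygosity, age = ages[t], rater = r,
        ind$ncs_edu, ind$ncs_selfreg, ctests,
        achievement = ach[, t], ses = ses, cov_df,
        stringsAsFactors = FALSE
      )
    }
  }
  data <- do.call(rbind, rows)
  data <- data[order(data$family_id, data$member, data$age, data$rater), ]
  rownames(data) <- NULL

  latents_long <- do.call(rbind, lapply(seq_len(n_age), function(t) {
    data.frame(family_id = info_off$family_id, member = info_off$member,
               age = ages[t], lat_list[[t]], achievement = ach[, t],
               stringsAsFactors = FALSE)
  }))

  truth <- list(
    individuals = data.frame(
      id = info_off$id, family_id = info_off$family_id,
      member = info_off$member, zygosity = info_off$zygosity,
      g_cog = g_cog, g_noncog = g_non, g_spec = g_spec,
      gpar_cog = gpar_cog, gpar_noncog = gpar_non,
      ses = ses, strat = u_strat, stringsAsFactors = FALSE),
    latents = latents_long,
    architecture = arch
  )

  structure(list(data = data, truth = truth, ages = ages, config = config),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("<twin_cohort> %d rows (%d families, ages %s, raters %s)\n",
              nrow(x$data), length(unique(x$data$family_id)),
              paste(x$ages, collapse = "/"),
              paste(unique(x$data$rater), collapse = "/")))
  invisible(x)
}

#' Extract a per-individual wide slice of a cohort at one age/rater
#'
#' Convenience accessor used throughout the analysis stages: one row per
#' offspring with indicators, achievement, SES and covariates.
#' @param cohort a `twin_cohort`.
#' @param age one of `cohort$ages`.
#' @param rater one of `"self"`, `"parent"`, `"teacher"`.
#' @return data frame, one row per individual.
#' @export
cohort_slice <- function(cohort, age, rater = "self") {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (!age %in% cohort$ages) stop("age not measured in this cohort")
  d <- cohort$data
  out <- d[d$age == age & d$rater == rater, , drop = FALSE]
  rownames(out) <- NULL
  out
}
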