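#' Cluster-robust standardized regression (GEE with independence working correlation)
#'
#' Point estimates are OLS on standardized variables (the estimating
#' equations of an independence working correlation); standard errors use
#' the cluster sandwich, accounting for the non-independence of twins
#' within a family. With singleton clusters the SEs reduce exactly to
#' heteroskedasticity-robust (HC0) SEs.
#'
#' @param y outcome vector.
#' @param predictors data frame of focal predictors (standardized betas and
#'   BH-adjusted p-values are reported for these).
#' @param covariates optional data frame of covariates.
#' @param cluster cluster id vector (e.g. family id).
#' @param level confidence level.
#' @return An object of class `fit_result`: `coef` data frame (`term, beta,
#'   se, ci_lo, ci_hi, p, p_adj`), `n`, `n_clusters`, `model`.
#' @export
cluster_robust_fit <- function(y, predictors, covariates = NULL, cluster,
                               level = 0.95) {
  predictors <- as.data.frame(predictors)
  df <- data.frame(.y = y, predictors, check.names = FALSE)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df$.cluster <- cluster
  df <- df[stats::complete.cases(df), , drop = FALSE]
  cl <- df$.cluster; df$.cluster <- NULL
  for (j in names(df)) {
    if (is.numeric(df[[j]]) && stats::sd(df[[j]]) > 0) {
      df[[j]] <- as.vector(scale(df[[j]]))
    }
  }
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  V <- sandwich::vcovCL(fit, cluster = cl, type = "HC0", cadjust = FALSE)
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  keep <- names(b) != "(Intercept)"
  b <- b[keep]; se <- se[keep]
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - level) / 2)
  focal <- names(b) %in% names(predictors)
  p_adj <- rep(NA_real_, length(p))
  p_adj[focal] <- bh_adjust(p[focal])
  structure(list(
    coef = data.frame(term = names(b), beta = unname(b), se = unname(se),
                      ci_lo = unname(b - q * se), ci_hi = unname(b + q * se),
                      p = unname(p), p_adj = p_adj, stringsAsFactors = FALSE),
    n = nrow(df), n_clusters = length(unique(cl)), model = fit
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d in %d clusters\n", x$n, x$n_clusters))
  print(transform(x$coef, beta = round(beta, 3), se = round(se, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p = signif(p, 3), p_adj = signif(p_adj, 3)))
  invisible(x)
}

#' Within/between-family decomposition of polygenic-score effects (DZ pairs)
#'
#' Decomposes each standardized PGS into the family mean (between-family
#' predictor, capturing indirect genetic effects and demographic
#' confounding) and the deviation from the family mean (within-family
#' predictor, the direct genetic effect protected by the randomization of
#' meiosis), then fits a linear mixed model with a family random intercept
#' by maximum likelihood.
#'
#' @param y outcome vector (one element per individual).
#' @param pgs_cog,pgs_noncog per-individual scores.
#' @param covariates optional covariate data frame.
#' @param family_id family identifier.
#' @param zygosity optional; if provided, any MZ rows raise an error (MZ
#'   co-twins carry no within-pair genetic variance).
#' @param level confidence level.
#' @return An object of class `within_between_result`: `coef` with rows
#'   `within_cog`, `within_noncog`, `between_cog`, `between_noncog`;
#'   variance components `sigma2_family`, `sigma2_residual`; `n_pairs`.
#' @export
within_between_fit <- function(y, pgs_cog, pgs_noncog, covariates = NULL,
                               family_id, zygosity = NULL, level = 0.95) {
  if (!is.null(zygosity) && any(zygosity == "MZ")) {
    stop("MZ pairs supplied: within-family genetic effects require DZ pairs")
  }
  df <- data.frame(.y = y, .cog = pgs_cog, .noncog = pgs_noncog,
                   .fam = family_id, stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  cnt <- table(df$.fam)
  unpaired <- names(cnt)[cnt != 2]
  if (length(unpaired)) {
    message(sprintf("dropping %d unpaired individual(s)", sum(cnt[unpaired])))
    df <- df[!(df$.fam %in% unpaired), , drop = FALSE]
  }
  if (!nrow(df)) stop("no complete pairs left")
  for (j in setdiff(names(df), ".fam")) {
    if (is.numeric(df[[j]]) && stats::sd(df[[j]]) > 0) {
      df[[j]] <- as.vector(scale(df[[j]]))
    }
  }
  fam_mean <- function(v) stats::ave(v, df$.fam)
  df$between_cog <- fam_mean(df$.cog)
  df$within_cog <- df$.cog - df$between_cog
  df$between_noncog <- fam_mean(df$.noncog)
  df$within_noncog <- df$.noncog - df$between_noncog
  covs <- setdiff(names(df), c(".y", ".cog", ".noncog", ".fam",
                               "within_cog", "within_noncog",
                               "between_cog", "between_noncog"))
  fml <- stats::reformulate(
    c("within_cog", "within_noncog", "between_cog", "between_noncog",
      covs, "(1 | .fam)"), response = ".y")
  fit <- lme4::lmer(fml, data = df, REML = FALSE)
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  terms <- c("within_cog", "within_noncog", "between_cog", "between_noncog")
  b <- sm[terms, 1]; se <- sm[terms, 2]
  q <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    coef = data.frame(term = terms, beta = unname(b), se = unname(se),
                      ci_lo = unname(b - q * se), ci_hi = unname(b + q * se),
                      p = 2 * stats::pnorm(-abs(unname(b / se))),
                      stringsAsFactors = FALSE),
    sigma2_family = vc$vcov[vc$grp == ".fam"],
    sigma2_residual = vc$vcov[vc$grp == "Residual"],
    n_pairs = nrow(df) / 2, model = fit
  ), class = "within_between_result")
}

#' @export
print.within_between_result <- function(x, ...) {
  cat(sprintf("<within_between_result> %d DZ pairs; sigma2(family) = %.3f, sigma2(resid) = %.3f\n",
              x$n_pairs, x$sigma2_family, x$sigma2_residual))
  print(transform(x$coef, beta = round(beta, 3), se = round(se, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p = signif(p, 3)))
  invisible(x)
}

#' Gene-environment interaction model: PGS x SES on achievement
#'
#' Linear mixed model with a family random intercept including both PGS,
#' SES, the two PGS x SES interactions and, optionally, two-way
#' interactions between the predictors (each PGS and SES) and every
#' covariate — guarding the focal interactions against confounded
#' moderation.
#'
#' @param y outcome.
#' @param pgs_cog,pgs_noncog standardized scores (standardized internally).
#' @param ses SES composite (standardized internally).
#' @param covariates optional covariate data frame.
#' @param family_id family identifier for the random intercept.
#' @param covariate_interactions include predictor x covariate terms.
#' @param level confidence level.
#' @return An object of class `fit_result` with all fixed effects; the
#'   `interaction` element names the two focal PGS x SES rows.
#' @export
gxe_fit <- function(y, pgs_cog, pgs_noncog, ses, covariates = NULL,
                    family_id, covariate_interactions = TRUE, level = 0.95) {
  df <- data.frame(.y = y, pgs_cog = pgs_cog, pgs_noncog = pgs_noncog,
                   ses = ses, .fam = family_id, stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (j in setdiff(names(df), ".fam")) {
    if (is.numeric(df[[j]]) && stats::sd(df[[j]]) > 0) {
      df[[j]] <- as.vector(scale(df[[j]]))
    }
  }
  covs <- setdiff(names(df), c(".y", "pgs_cog", "pgs_noncog", "ses", ".fam"))
  terms <- c("pgs_cog", "pgs_noncog", "ses",
             "pgs_cog:ses", "pgs_noncog:ses", covs)
  if (covariate_interactions && length(covs)) {
    terms <- c(terms,
               as.vector(outer(c("pgs_cog", "pgs_noncog", "ses"), covs,
                               paste, sep = ":")))
  }
  fml <- stats::reformulate(c(terms, "(1 | .fam)"), response = ".y")
  X <- stats::model.matrix(stats::reformulate(terms), data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design after interaction expansion: %s",
                 paste(bad, collapse = ", ")))
  }
  fit <- lme4::lmer(fml, data = df, REML = FALSE)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  b <- sm[, 1]; se <- sm[, 2]
  q <- stats::qnorm(1 - (1 - level) / 2)
  p <- 2 * stats::pnorm(-abs(b / se))
  focal <- rownames(sm) %in% c("pgs_cog:ses", "pgs_noncog:ses")
  p_adj <- rep(NA_real_, length(p)); p_adj[focal] <- bh_adjust(p[focal])
  structure(list(
    coef = data.frame(term = rownames(sm), beta = unname(b), se = unname(se),
                      ci_lo = unname(b - q * se), ci_hi = unname(b + q * se),
                      p = unname(p), p_adj = p_adj, stringsAsFactors = FALSE),
    interaction = c("pgs_cog:ses", "pgs_noncog:ses"),
    n = nrow(df), n_clusters = length(unique(df$.fam)), model = fit
  ), class = "fit_result")
}

#' Per-stratum PGS slopes across SES groups
#'
#' Stratifies the sample at the 25th and 75th SES percentiles (low /
#' middle 50% / high; rank-based cutpoints, so an `n` divisible by 4
#' splits exactly 25/50/25) and reports the mutually adjusted standardized
#' slopes of achievement on each PGS within every stratum. Variables are
#' standardized on the full sample so slopes are comparable across strata.
#'
#' @param y achievement.
#' @param pgs_cog,pgs_noncog scores.
#' @param ses SES composite.
#' @param min_per_stratum minimum individuals per stratum.
#' @return data frame: `stratum`, `term`, `beta`, `se`, `ci_lo`, `ci_hi`,
#'   `n`, plus per-stratum mean achievement.
#' @export
ses_strata_slopes <- function(y, pgs_cog, pgs_noncog, ses,
                              min_per_stratum = 30L) {
  ok <- stats::complete.cases(y, pgs_cog, pgs_noncog, ses)
  y <- scale(y[ok]); cg <- scale(pgs_cog[ok]); ng <- scale(pgs_noncog[ok])
  ses <- ses[ok]
  n <- length(ses)
  r <- rank(ses, ties.method = "first")
  stratum <- cut(r, breaks = c(0, floor(n / 4), n - floor(n / 4), n),
                 labels = c("low", "middle", "high"))
  out <- lapply(levels(stratum), function(s) {
    i <- stratum == s
    if (sum(i) < min_per_stratum) {
      stop(sprintf("SES stratum '%s' has fewer than %d individuals", s,
                   min_per_stratum))
    }
    f <- stats::lm(y[i] ~ cg[i] + ng[i])
    sm <- summary(f)$coefficients
    data.frame(stratum = s, term = c("pgs_cog", "pgs_noncog"),
               beta = sm[2:3, 1], se = sm[2:3, 2],
               ci_lo = sm[2:3, 1] - 1.96 * sm[2:3, 2],
               ci_hi = sm[2:3, 1] + 1.96 * sm[2:3, 2],
               n = sum(i), mean_achievement = mean(y[i]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone non-decreasing in the input order
#' statistics, capped at 1), via `stats::p.adjust` after input validation.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Developmental trajectory of PGS prediction of achievement
#'
#' Runs the population-level cluster-robust regression of achievement on
#' the Cog and NonCog scores (plus covariates) at every measured age and
#' summarizes the trend: the OLS slope of the per-age betas over age per
#' factor, with a nonparametric bootstrap CI over families.
#'
#' @param cohort a `twin_cohort`.
#' @param scores data frame with `family_id`, `member`, `cog`, `noncog`.
#' @param covariates character vector of covariate columns present in the
#'   cohort data (default none: the synthetic covariates are null effects).
#' @param B bootstrap replicates for the trend CI (0 skips).
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return list of class `developmental_profile`: `trajectory` (age x
#'   factor beta table), `trend` (per-factor slope with CI), `n_ages`.
#' @export
developmental_profile <- function(cohort, scores, covariates = character(),
                                  B = 200L, level = 0.95, seed = 1L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  ages <- cohort$ages
  if (length(ages) < 2) {
    out <- list(trajectory = NULL, trend = NULL, n_ages = length(ages),
                trend_defined = FALSE)
    class(out) <- "developmental_profile"
    warning("single measurement age: developmental trend undefined")
    return(out)
  }
  slices <- lapply(ages, function(a) {
    d <- cohort_slice(cohort, a, rater = "self")
    m <- merge(d, scores, by = c("family_id", "member"))
    m[stats::complete.cases(m[c("achievement", "cog", "noncog", covariates)]), ]
  })
  fit_age <- function(d) {
    f <- cluster_robust_fit(d$achievement,
                            data.frame(cog = d$cog, noncog = d$noncog),
                            covariates = if (length(covariates))
                              d[covariates] else NULL,
                            cluster = d$family_id)
    f$coef[f$coef$term %in% c("cog", "noncog"), ]
  }
  traj <- do.call(rbind, lapply(seq_along(ages), function(i) {
    co <- fit_age(slices[[i]])
    co$age <- ages[i]
    co
  }))
  slope_of <- function(tr) {
    vapply(c("cog", "noncog"), function(f) {
      d <- tr[tr$term == f, ]
      stats::coef(stats::lm(beta ~ age, data = d))[2]
    }, numeric(1))
  }
  trend_pt <- slope_of(traj)

  trend <- data.frame(factor = c("cog", "noncog"), slope = unname(trend_pt),
                      ci_lo = NA_real_, ci_hi = NA_real_,
                      stringsAsFactors = FALSE)
  if (B > 0) {
    fams <- unique(slices[[1]]$family_id)
    idx_by_fam <- lapply(slices, function(d) split(seq_len(nrow(d)), d$family_id))
    bs <- with_substream(seed, "trend_bootstrap", {
      t(replicate(B, {
        fb <- sample(fams, replace = TRUE)
        tr <- do.call(rbind, lapply(seq_along(ages), function(i) {
          d <- slices[[i]]
          idx <- unlist(idx_by_fam[[i]][fb], use.names = FALSE)
          co <- tryCatch(fit_age(d[idx, , drop = FALSE]),
                         error = function(e) NULL)
          if (is.null(co)) return(NULL)
          co$age <- ages[i]
          co
        }))
        if (is.null(tr) || nrow(tr) < 2 * length(ages)) rep(NA_real_, 2)
        else slope_of(tr)
      }))
    })
    alpha <- (1 - level) / 2
    trend$ci_lo <- apply(bs, 2, stats::quantile, alpha, na.rm = TRUE)
    trend$ci_hi <- apply(bs, 2, stats::quantile, 1 - alpha, na.rm = TRUE)
  }
  structure(list(trajectory = traj, trend = trend, n_ages = length(ages),
                 trend_defined = TRUE),
            class = "developmental_profile")
}

#' @export
print.developmental_profile <- function(x, ...) {
  if (!x$trend_defined) {
    cat("<developmental_profile> trend undefined (single age)\n")
    return(invisible(x))
  }
  cat(sprintf("<developmental_profile> %d ages\n", x$n_ages))
  print(transform(x$trajectory, beta = round(beta, 3), se = round(se, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p = signif(p, 3), p_adj = signif(p_adj, 3)))
  cat("trend (slope of beta over age):\n")
  print(transform(x$trend, slope = round(slope, 4), ci_lo = round(ci_lo, 4),
                  ci_hi = round(ci_hi, 4)))
  invisible(x)
}
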