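#' Fit the extended GWAS-by-subtraction model to a genetic covariance matrix
#'
#' Two uncorrelated unit-variance latent genetic factors: `Cog`, on which
#' all eight traits load, and `NonCog`, on which only educational
#' attainment, income and deprivation load. Residual genetic variances are
#' free for every trait (none constrained to zero). The model is fitted by
#' diagonally weighted least squares: minimize
#' `(s - sigma(theta))' diag(V)^-1 (s - sigma(theta))` over the
#' half-vectorized unique elements of `S`, with sandwich standard errors
#' using the full sampling covariance `V`. Sign identification anchors the
#' Cog factor by a positive loading on cognitive performance and the
#' NonCog factor by a positive loading on educational attainment.
#'
#' @param S 8 x 8 genetic covariance matrix in canonical trait order
#'   (`CP, SD, ME, TM, RT, EA, IN, DE`), e.g. from [build_s_v()].
#' @param V sampling covariance of the unique elements of `S`
#'   (half-vectorized lower triangle, column-major), or `NULL` for unit
#'   weights (exact-S self-consistency fits).
#' @return An object of class `subtraction_model`: `loadings_cog` (8),
#'   `loadings_noncog` (EA/IN/DE), `residuals` (8), `se` (sandwich SEs per
#'   parameter), `fit_chisq`-style weighted fit value `fit_value`,
#'   `heywood` flags, `implied_S`.
#' @export
fit_subtraction_model <- function(S, V = NULL) {
  traits <- gwas_trait_names()
  stopifnot(is.matrix(S), all(dim(S) == 8))
  if (!is.null(rownames(S)) && !identical(rownames(S), traits)) {
    stop("S must be in canonical trait order CP, SD, ME, TM, RT, EA, IN, DE")
  }
  noncog_idx <- match(c("EA", "IN", "DE"), traits)
  ltri <- which(lower.tri(S, diag = TRUE))
  s_obs <- S[ltri]
  w <- if (is.null(V)) rep(1, length(s_obs)) else 1 / pmax(diag(V), 1e-12)

  # par: 8 cog loadings, 3 noncog loadings, 8 residual variances
  implied <- function(par) {
    lc <- par[1:8]
    ln <- numeric(8); ln[noncog_idx] <- par[9:11]
    th <- par[12:19]
    out <- tcrossprod(lc) + tcrossprod(ln) + diag(th, 8)
    dimnames(out) <- list(traits, traits)
    out
  }
  # optimize with residual SDs (squared inside), so the variance bound
  # th >= 0 is automatic and plain BFGS can run unconstrained
  obj <- function(q) {
    par <- q; par[12:19] <- q[12:19]^2
    r <- implied(par)[ltri] - s_obs
    sum(w * r^2)
  }
  # starts: factor-analytic guess from S
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lc0 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0.1))
  if (lc0[1] < 0) lc0 <- -lc0
  ln0 <- c(0.4, 0.3, -0.3)
  th0 <- pmax(diag(S) - lc0^2, 0.05)
  th0[noncog_idx] <- pmax(diag(S)[noncog_idx] - lc0[noncog_idx]^2 - ln0^2, 0.05)
  q0 <- c(lc0, ln0, sqrt(th0))
  fit <- stats::optim(q0, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  if (fit$convergence != 0 || fit$value > obj(q0)) {
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-15))
  }
  if (fit$convergence != 0) {
    stop(sprintf("subtraction model did not converge (code %d)", fit$convergence))
  }
  par <- fit$par
  par[12:19] <- par[12:19]^2
  # sign anchors: CP loading positive on Cog, EA loading positive on NonCog
  if (par[1] < 0) par[1:8] <- -par[1:8]
  if (par[9] < 0) par[9:11] <- -par[9:11]
  heywood <- par[12:19] <= 1e-8

  se <- rep(NA_real_, 19)
  if (!is.null(V)) {
    # sandwich: (J'WJ)^-1 J'W V W J (J'WJ)^-1 with J = d sigma / d theta
    J <- .num_jacobian(function(p) implied(p)[ltri], par)
    JW <- t(J) %*% diag(w)
    bread <- tryCatch(solve(JW %*% J), error = function(e) NULL)
    if (!is.null(bread)) {
      cov_par <- bread %*% JW %*% V %*% t(JW) %*% bread
      se <- sqrt(pmax(diag(cov_par), 0))
    }
  }
  nm <- c(paste0("cog_", traits), paste0("noncog_", c("EA", "IN", "DE")),
          paste0("resid_", traits))
  names(se) <- nm
  structure(list(
    loadings_cog = stats::setNames(par[1:8], traits),
    loadings_noncog = stats::setNames(par[9:11], c("EA", "IN", "DE")),
    residuals = stats::setNames(par[12:19], traits),
    se = se, fit_value = fit$value, heywood = heywood,
    implied_S = implied(par), par = stats::setNames(par, nm)
  ), class = "subtraction_model")
}

.num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h
    J[, i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

#' @export
print.subtraction_model <- function(x, ...) {
  cat(sprintf("<subtraction_model> fit value %.4g%s\n", x$fit_value,
              if (any(x$heywood)) " [Heywood residual(s) at 0]" else ""))
  print(round(rbind(Cog = x$loadings_cog,
                    NonCog = { v <- numeric(8); names(v) <- names(x$loadings_cog)
                               v[names(x$loadings_noncog)] <- x$loadings_noncog; v },
                    residual = x$residuals), 3))
  invisible(x)
}

#' Per-SNP effects on the latent Cog and NonCog factors
#'
#' With the factor loadings fixed at their fitted values, each SNP's vector
#' of standardized indicator effects `b_i = Z_i / sqrt(N_i)` is regressed
#' on the two loading columns by weighted least squares (weights `N_i`, the
#' inverse sampling variances), which is the one-linear-solve-per-SNP
#' reduction of augmenting the model with SNP -> Cog and SNP -> NonCog
#' paths. Because the design is shared across SNPs this is a single matrix
#' product over the genome. SEs propagate the per-indicator sampling
#' variances through the solve.
#'
#' @param model a [fit_subtraction_model()].
#' @param ss_set harmonized `sumstats_set` with the eight indicator traits
#'   in canonical order.
#' @return An object of class `latent_sumstats`: data frame per factor with
#'   `SNP, A1, A2, MAF, BETA, SE, Z, N_eff`.
#' @export
snp_effects <- function(model, ss_set) {
  stopifnot(inherits(model, "subtraction_model"))
  canonical <- gwas_trait_names()
  tl <- if (inherits(ss_set, "sumstats_set")) ss_set$traits else ss_set
  traits <- canonical[canonical %in% names(tl)]
  if (length(traits) < 2) {
    stop("sumstats set must contain at least two canonical indicator traits")
  }
  tl <- tl[traits]
  snp <- tl[[1]]$SNP
  for (d in tl) if (!identical(d$SNP, snp)) stop("traits not harmonized to one SNP map")

  lc <- model$loadings_cog[traits]
  ln <- numeric(length(traits)); names(ln) <- traits
  common <- intersect(names(model$loadings_noncog), traits)
  ln[common] <- model$loadings_noncog[common]
  X <- cbind(Cog = unname(lc), NonCog = unname(ln))
  if (qr(X)$rank < 2) stop("loading matrix is rank deficient for the supplied traits")

  B <- vapply(tl, function(d) d$Z / sqrt(d$N), numeric(length(snp)))  # M x 8
  N <- vapply(tl, function(d) d$N[1], numeric(1))
  W <- diag(N)
  H <- solve(t(X) %*% W %*% X, t(X) %*% W)     # 2 x 8 linear map
  beta <- B %*% t(H)                           # M x 2
  cov_latent <- H %*% diag(1 / N) %*% t(H)
  se <- sqrt(diag(cov_latent))

  ref <- tl[[1]]
  out <- lapply(1:2, function(k) {
    data.frame(SNP = snp, CHR = ref$CHR, BP = ref$BP, A1 = ref$A1,
               A2 = ref$A2, MAF = ref$MAF, BETA = beta[, k], SE = se[k],
               Z = beta[, k] / se[k], N_eff = 1 / se[k]^2,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- c("Cog", "NonCog")
  structure(list(factors = out, snp = snp, map = H), class = "latent_sumstats")
}

#' @export
print.latent_sumstats <- function(x, ...) {
  cat(sprintf("<latent_sumstats> Cog & NonCog effects for %d SNPs (N_eff %.0f / %.0f)\n",
              length(x$snp), x$factors$Cog$N_eff[1], x$factors$NonCog$N_eff[1]))
  invisible(x)
}

#' Convert a latent factor's per-SNP effects to the sumstats TSV dialect
#'
#' Emits `SNP CHR BP A1 A2 MAF N Z` using the propagated effective sample
#' size `N_eff = 1 / SE^2` (standardized scale), so latent factors can flow
#' through [ldsc_rg()], [ldpred_inf()] and file round-trips like any
#' measured trait.
#'
#' @param latent a [snp_effects()] result.
#' @param factor `"Cog"` or `"NonCog"`.
#' @return A sumstats data frame.
#' @export
latent_as_sumstats <- function(latent, factor = c("Cog", "NonCog")) {
  factor <- match.arg(factor)
  d <- latent$factors[[factor]]
  data.frame(SNP = d$SNP, CHR = d$CHR, BP = d$BP, A1 = d$A1, A2 = d$A2,
             MAF = d$MAF, N = d$N_eff, Z = d$Z, stringsAsFactors = FALSE)
}

#' Genetic correlation between a latent factor and an external trait
#'
#' [ldsc_rg()] applied to the latent factor's per-SNP effects (converted
#' via [latent_as_sumstats()]) and an external sumstats table, after
#' harmonization.
#'
#' @param latent a [snp_effects()] result.
#' @param factor `"Cog"` or `"NonCog"`.
#' @param external external trait sumstats data frame.
#' @param ldscores,M,n_blocks as in [ldsc_rg()].
#' @return An `ldsc_rg` object.
#' @export
rg_external <- function(latent, factor, external, ldscores, M = NULL,
                        n_blocks = 200L) {
  ss1 <- latent_as_sumstats(latent, factor)
  h <- harmonize(list(latent = ss1, external = external))
  l <- .align_ldscores(ss1, ldscores)
  keep <- match(h$snp, ss1$SNP)
  ldsc_rg(h$traits$latent, h$traits$external, l[keep], M = M,
          n_blocks = n_blocks)
}
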