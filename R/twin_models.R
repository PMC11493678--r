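#' Build a twin-pair trait table from per-individual data
#'
#' Reshapes a per-individual table (two members per family) into one row
#' per pair with `<trait>_1` / `<trait>_2` columns. Traits are standardized
#' on the pooled MZ+DZ sample before pairing; pairs with a missing member
#' or missing trait values are dropped (complete pairs only).
#'
#' @param data per-individual data frame.
#' @param traits character vector of trait column names; keep the intended
#'   entry order (e.g. `g`, non-cognitive factor, achievement).
#' @param family_col,member_col,zygosity_col column names.
#' @return A `twin_pairs` data frame.
#' @export
pair_traits <- function(data, traits,
                        family_col = "family_id", member_col = "member",
                        zygosity_col = "zygosity") {
  for (tr in traits) data[[tr]] <- as.vector(scale(data[[tr]]))
  d1 <- data[data[[member_col]] == 1, c(family_col, zygosity_col, traits)]
  d2 <- data[data[[member_col]] == 2, c(family_col, traits)]
  m <- merge(d1, d2, by = family_col, suffixes = c("_1", "_2"))
  names(m)[names(m) == zygosity_col] <- "zygosity"
  names(m)[names(m) == family_col] <- "family_id"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  # restore entry order: trait_1 columns then interleaved is fine, keep map
  attr(m, "traits") <- traits
  m
}

.pair_mat <- function(pairs, traits) {
  as.matrix(pairs[, c(paste0(traits, "_1"), paste0(traits, "_2"))])
}

#' Intraclass correlation of twin pairs (double entry)
#'
#' Pearson correlation on double-entered pairs: each pair contributes both
#' `(t1, t2)` and `(t2, t1)` orderings, making the estimate invariant to
#' within-pair member labels.
#'
#' @param pairs a [pair_traits()] table (or any data frame with
#'   `<trait>_1`, `<trait>_2`, `zygosity`).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param trait trait name (default: first trait of the table).
#' @return Intraclass correlation (numeric scalar).
#' @export
intraclass_corr <- function(pairs, zygosity, trait = NULL) {
  if (is.null(trait)) trait <- attr(pairs, "traits")[1]
  d <- pairs[pairs$zygosity == zygosity, , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 pairs of the requested zygosity")
  x <- d[[paste0(trait, "_1")]]; y <- d[[paste0(trait, "_2")]]
  if (stats::sd(c(x, y)) == 0) stop("zero-variance trait")
  stats::cor(c(x, y), c(y, x))
}

#' Falconer variance-component estimates from intraclass correlations
#'
#' `h2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`. Components
#' outside `[0, 1]` are returned unclipped with `in_bounds = FALSE`.
#'
#' @param rmz,rdz MZ and DZ intraclass correlations in `[-1, 1]`.
#' @return list `h2`, `c2`, `e2`, `in_bounds`.
#' @export
falconer <- function(rmz, rdz) {
  stopifnot(abs(rmz) <= 1, abs(rdz) <= 1)
  h2 <- 2 * (rmz - rdz); c2 <- 2 * rdz - rmz; e2 <- 1 - rmz
  list(h2 = h2, c2 = c2, e2 = e2,
       in_bounds = all(c(h2, c2, e2) >= 0 & c(h2, c2, e2) <= 1))
}

# ---- ML machinery -----------------------------------------------------

# -2 log likelihood (up to a data-only constant) of zygosity-group sample
# moments under implied covariances; moments use the ML (1/n) denominator
# around the sample mean.
.twin_m2ll <- function(S_list, n_list, Sigma_list) {
  tot <- 0
  for (z in seq_along(S_list)) {
    ch <- tryCatch(chol(Sigma_list[[z]]), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    tot <- tot + n_list[[z]] * (ldet + sum(chol2inv(ch) * S_list[[z]]))
  }
  tot
}

.moments <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / n
}

.ltri_fill <- function(v, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

#' Maximum-likelihood ACE fit from zygosity-group covariance matrices
#'
#' Fits the univariate ACE model to 2 x 2 MZ and DZ pair covariance
#' matrices by ML, using the square-root parameterization `(a, c, e)` so
#' the variance components are non-negative by construction. The expected
#' pair covariance is `a^2 + c^2` (MZ) and `0.5 a^2 + c^2` (DZ), with
#' common total variance `a^2 + c^2 + e^2`.
#'
#' @param S_mz,S_dz 2 x 2 sample covariance matrices (ML denominator).
#' @param n_mz,n_dz pair counts.
#' @return list with shares `a2`, `c2`, `e2`, raw variances, implied
#'   `rmz`/`rdz`, `m2ll`, `boundary` flag (a pinned at zero), convergence.
#' @export
fit_ace_cov <- function(S_mz, S_dz, n_mz, n_dz) {
  obj <- function(par) {
    a <- par[1]; cc <- par[2]; e <- par[3]
    v <- a^2 + cc^2 + e^2
    Sig <- function(r) matrix(c(v, r, r, v), 2)
    .twin_m2ll(list(S_mz, S_dz), list(n_mz, n_dz),
               list(Sig(a^2 + cc^2), Sig(0.5 * a^2 + cc^2)))
  }
  cmz <- S_mz[1, 2]; cdz <- S_dz[1, 2]
  v0 <- (S_mz[1, 1] + S_mz[2, 2] + S_dz[1, 1] + S_dz[2, 2]) / 4
  a20 <- min(max(2 * (cmz - cdz), 0.05), v0 * 0.95)
  c20 <- min(max(2 * cdz - cmz, 0.02), v0 * 0.9)
  e20 <- max(v0 - a20 - c20, 0.02)
  fit <- stats::optim(sqrt(c(a20, c20, e20)), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (fit$convergence != 0) {
    stop(sprintf("ACE fit did not converge (code %d, final -2lnL %.4g)",
                 fit$convergence, fit$value))
  }
  va <- fit$par[1]^2; vc <- fit$par[2]^2; ve <- fit$par[3]^2
  v <- va + vc + ve
  list(a2 = va / v, c2 = vc / v, e2 = ve / v,
       var_a = va, var_c = vc, var_e = ve,
       rmz = (va + vc) / v, rdz = (0.5 * va + vc) / v,
       m2ll = fit$value, boundary = va / v < 1e-6, converged = TRUE)
}

#' Maximum-likelihood ACE model for twin pairs
#'
#' Standardizes the trait on the pooled sample, computes zygosity-group
#' moments, fits [fit_ace_cov()], and attaches nonparametric bootstrap
#' confidence intervals (resampling families within zygosity).
#'
#' @param pairs a [pair_traits()] table containing both zygosities.
#' @param trait trait name (default: first trait).
#' @param B bootstrap replicates (0 skips CIs).
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return An object of class `ace_estimate`.
#' @export
fit_ace <- function(pairs, trait = NULL, B = 500L, level = 0.95, seed = 1L) {
  if (is.null(trait)) trait <- attr(pairs, "traits")[1]
  cols <- paste0(trait, c("_1", "_2"))
  mz <- pairs[pairs$zygosity == "MZ", cols, drop = FALSE]
  dz <- pairs[pairs$zygosity == "DZ", cols, drop = FALSE]
  if (nrow(mz) < 2 || nrow(dz) < 2) {
    stop("both zygosity groups are required for an ACE fit")
  }
  sd_all <- stats::sd(unlist(pairs[cols]))
  mz <- as.matrix(mz) / sd_all; dz <- as.matrix(dz) / sd_all

  point <- fit_ace_cov(.moments(mz), .moments(dz), nrow(mz), nrow(dz))
  est <- c(a2 = point$a2, c2 = point$c2, e2 = point$e2)

  ci <- NULL
  if (B > 0) {
    bs <- with_substream(seed, "ace_bootstrap", {
      t(replicate(B, {
        bmz <- mz[sample.int(nrow(mz), replace = TRUE), , drop = FALSE]
        bdz <- dz[sample.int(nrow(dz), replace = TRUE), , drop = FALSE]
        f <- tryCatch(fit_ace_cov(.moments(bmz), .moments(bdz),
                                  nrow(bmz), nrow(bdz)),
                      error = function(e) NULL)
        if (is.null(f)) c(NA, NA, NA) else c(f$a2, f$c2, f$e2)
      }))
    })
    colnames(bs) <- names(est)
    alpha <- (1 - level) / 2
    ci <- apply(bs, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  }
  structure(c(point, list(estimates = est, ci = ci,
                          n_mz = nrow(mz), n_dz = nrow(dz), trait = trait)),
            class = "ace_estimate")
}

#' @export
print.ace_estimate <- function(x, ...) {
  cat(sprintf("<ace_estimate> '%s': a2 = %.3f, c2 = %.3f, e2 = %.3f (rMZ %.3f, rDZ %.3f; %d MZ + %d DZ pairs)%s\n",
              x$trait, x$a2, x$c2, x$e2, x$rmz, x$rdz, x$n_mz, x$n_dz,
              if (isTRUE(x$boundary)) " [a2 at boundary]" else ""))
  if (!is.null(x$ci)) print(round(x$ci, 3))
  invisible(x)
}

# implied 2p x 2p covariance matrices for a multivariate twin model
.chol_sigma <- function(LA, LC, LE) {
  A <- tcrossprod(LA); C <- tcrossprod(LC); E <- tcrossprod(LE)
  W <- A + C + E
  list(MZ = rbind(cbind(W, A + C), cbind(A + C, W)),
       DZ = rbind(cbind(W, 0.5 * A + C), cbind(0.5 * A + C, W)))
}

#' Trivariate Cholesky decomposition of twin data (ML)
#'
#' Fits lower-triangular genetic (A), shared-environment (C) and
#' non-shared-environment (E) path matrices to the 6 x 6 cross-twin
#' covariance structure of three ordered traits, by maximum likelihood with
#' cross-twin factor correlations 1 (A, MZ), 0.5 (A, DZ), 1 (C) and 0 (E).
#' The entry order is the analysis's research question: with order
#' (g, non-cognitive factor, achievement) the third row of the standardized
#' squared A paths splits the heritability of achievement into a part
#' shared with cognitive ability, a part shared with non-cognitive skills
#' beyond cognitive ability, and an achievement-specific remainder.
#'
#' @param pairs a [pair_traits()] table with three traits.
#' @param traits trait names in entry order (default: table attribute).
#' @param B bootstrap replicates for CIs (0 skips).
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return An object of class `cholesky_model`: raw `L_A`, `L_C`, `L_E`,
#'   `paths_std` (standardized paths by component), `shares`
#'   (standardized squared paths), `ach_decomposition`, `ci`, `m2ll`.
#' @export
fit_trivariate_cholesky <- function(pairs, traits = NULL, B = 500L,
                                    level = 0.95, seed = 1L) {
  if (is.null(traits)) traits <- attr(pairs, "traits")
  stopifnot(length(traits) == 3)
  mz <- .pair_mat(pairs[pairs$zygosity == "MZ", , drop = FALSE], traits)
  dz <- .pair_mat(pairs[pairs$zygosity == "DZ", , drop = FALSE], traits)
  if (nrow(mz) < 10 || nrow(dz) < 10) stop("both zygosity groups required (>= 10 pairs each)")
  sds <- apply(rbind(mz[, 1:3], mz[, 4:6], dz[, 1:3], dz[, 4:6]), 2, stats::sd)
  mz <- sweep(mz, 2, rep(sds, 2), "/"); dz <- sweep(dz, 2, rep(sds, 2), "/")

  point <- .fit_cholesky_cov(.moments(mz), .moments(dz), nrow(mz), nrow(dz))

  ci <- NULL
  if (B > 0) {
    stat <- function(f) c(f$shares$A, f$shares$C, f$shares$E)
    bs <- with_substream(seed, "cholesky_bootstrap", {
      t(replicate(B, {
        bmz <- mz[sample.int(nrow(mz), replace = TRUE), , drop = FALSE]
        bdz <- dz[sample.int(nrow(dz), replace = TRUE), , drop = FALSE]
        f <- tryCatch(.fit_cholesky_cov(.moments(bmz), .moments(bdz),
                                        nrow(bmz), nrow(bdz)),
                      error = function(e) NULL)
        if (is.null(f)) rep(NA_real_, 27) else stat(f)
      }))
    })
    alpha <- (1 - level) / 2
    qs <- apply(bs, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
    ci <- list(A = array(qs[, 1:9], c(2, 3, 3)),
               C = array(qs[, 10:18], c(2, 3, 3)),
               E = array(qs[, 19:27], c(2, 3, 3)))
  }
  structure(c(point, list(traits = traits, ci = ci,
                          n_mz = nrow(mz), n_dz = nrow(dz))),
            class = "cholesky_model")
}

#' Trivariate Cholesky ML fit from 6 x 6 zygosity covariance matrices
#'
#' Moment-level interface (deterministic given moments); used by
#' [fit_trivariate_cholesky()] and by exact-moment oracle checks.
#' @param S_mz,S_dz 6 x 6 sample covariances (twin1 traits then twin2).
#' @param n_mz,n_dz pair counts.
#' @return list as in [fit_trivariate_cholesky()] (no CIs).
#' @export
fit_cholesky_cov <- function(S_mz, S_dz, n_mz, n_dz) {
  .fit_cholesky_cov(S_mz, S_dz, n_mz, n_dz)
}

.fit_cholesky_cov <- function(S_mz, S_dz, n_mz, n_dz) {
  p <- 3L
  nL <- p * (p + 1) / 2
  obj <- function(par) {
    LA <- .ltri_fill(par[1:nL], p)
    LC <- .ltri_fill(par[nL + 1:nL], p)
    LE <- .ltri_fill(par[2 * nL + 1:nL], p)
    Sig <- .chol_sigma(LA, LC, LE)
    .twin_m2ll(list(S_mz, S_dz), list(n_mz, n_dz), list(Sig$MZ, Sig$DZ))
  }
  # moment starts: A ~ 2(Xmz - Xdz), C ~ 2Xdz - Xmz, E ~ W - A - C
  W <- (S_mz[1:3, 1:3] + S_mz[4:6, 4:6] + S_dz[1:3, 1:3] + S_dz[4:6, 4:6]) / 4
  Xmz <- (S_mz[1:3, 4:6] + t(S_mz[1:3, 4:6])) / 2
  Xdz <- (S_dz[1:3, 4:6] + t(S_dz[1:3, 4:6])) / 2
  A0 <- .psd_project(2 * (Xmz - Xdz), floor = 0.02)
  C0 <- .psd_project(2 * Xdz - Xmz, floor = 0.02)
  E0 <- .psd_project(W - A0 - C0, floor = 0.05)
  par0 <- c(t(chol(A0))[lower.tri(A0, diag = TRUE)],
            t(chol(C0))[lower.tri(C0, diag = TRUE)],
            t(chol(E0))[lower.tri(E0, diag = TRUE)])
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$convergence != 0) {
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-14))
  }
  if (fit$convergence != 0) {
    stop(sprintf("Cholesky fit did not converge (code %d)", fit$convergence))
  }
  LA <- .ltri_fill(fit$par[1:nL], p)
  LC <- .ltri_fill(fit$par[nL + 1:nL], p)
  LE <- .ltri_fill(fit$par[2 * nL + 1:nL], p)
  # sign convention: positive diagonals
  for (j in 1:p) {
    if (LA[j, j] < 0) LA[, j] <- -LA[, j]
    if (LC[j, j] < 0) LC[, j] <- -LC[, j]
    if (LE[j, j] < 0) LE[, j] <- -LE[, j]
  }
  tot <- rowSums(LA^2) + rowSums(LC^2) + rowSums(LE^2)
  std <- function(L) sweep(L, 1, sqrt(tot), "/")
  shares <- list(A = std(LA)^2, C = std(LC)^2, E = std(LE)^2)
  list(L_A = LA, L_C = LC, L_E = LE,
       paths_std = list(A = std(LA), C = std(LC), E = std(LE)),
       shares = shares,
       ach_decomposition = c(via_g = shares$A[3, 1],
                             via_ncs = shares$A[3, 2],
                             specific = shares$A[3, 3]),
       total_var = tot, m2ll = fit$value)
}

.psd_project <- function(S, floor = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
}

#' @export
print.cholesky_model <- function(x, ...) {
  cat(sprintf("<cholesky_model> traits %s (%d MZ + %d DZ pairs)\n",
              paste(x$traits, collapse = " -> "), x$n_mz, x$n_dz))
  cat("achievement A-variance decomposition (standardized squared paths):\n")
  print(round(x$ach_decomposition, 4))
  invisible(x)
}

#' Common pathway model for multiple indicators measured on twins
#'
#' ML fit of a twin model in which the covariance among `k` indicators is
#' channelled through one latent factor with its own ACE decomposition
#' (latent variance fixed to 1 for identification), plus indicator-specific
#' ACE residuals.
#'
#' @param pairs data frame with `<ind>_1` / `<ind>_2` columns and
#'   `zygosity`.
#' @param indicators indicator base names (>= 3).
#' @return list with `latent` ACE shares, `loadings`, residual share
#'   matrix `residual` (k x 3), `m2ll`.
#' @export
fit_common_pathway <- function(pairs, indicators) {
  k <- length(indicators)
  if (k < 3) stop("common pathway model needs >= 3 indicators (under-identified)")
  mz <- .pair_mat(pairs[pairs$zygosity == "MZ", , drop = FALSE], indicators)
  dz <- .pair_mat(pairs[pairs$zygosity == "DZ", , drop = FALSE], indicators)
  S_mz <- .moments(mz); S_dz <- .moments(dz)
  n_mz <- nrow(mz); n_dz <- nrow(dz)

  # par: lambda (k), sphere coords (3) for latent ACE, residual sqrt (3k)
  unpack <- function(par) {
    lam <- par[1:k]
    x <- par[k + 1:3]
    ace <- x^2 / sum(x^2)          # latent shares, sum to 1
    res <- matrix(par[k + 3 + 1:(3 * k)], k, 3)^2
    list(lam = lam, ace = ace, res = res)
  }
  imp <- function(q, rA) {
    lat_cross <- rA * q$ace[1] + q$ace[2]
    W <- tcrossprod(q$lam) + diag(rowSums(q$res), k)
    X <- tcrossprod(q$lam) * lat_cross +
      diag(rA * q$res[, 1] + q$res[, 2], k)
    rbind(cbind(W, X), cbind(X, W))
  }
  obj <- function(par) {
    q <- unpack(par)
    .twin_m2ll(list(S_mz, S_dz), list(n_mz, n_dz),
               list(imp(q, 1), imp(q, 0.5)))
  }
  W0 <- (S_mz[1:k, 1:k] + S_mz[k + 1:k, k + 1:k] +
           S_dz[1:k, 1:k] + S_dz[k + 1:k, k + 1:k]) / 4
  ev <- eigen(W0, symmetric = TRUE)
  lam0 <- ev$vectors[, 1] * sqrt(max(ev$values[1] * 0.8, 0.1))
  if (mean(lam0) < 0) lam0 <- -lam0
  par0 <- c(lam0, sqrt(c(0.4, 0.2, 0.4)),
            rep(sqrt(pmax(diag(W0) - lam0^2, 0.05) / 3), 3))
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 3000, reltol = 1e-13))
  if (fit$convergence != 0) {
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-13))
  }
  if (fit$convergence != 0) stop("common pathway fit did not converge")
  q <- unpack(fit$par)
  if (mean(q$lam) < 0) q$lam <- -q$lam
  res_sh <- q$res / rowSums(q$res)
  dimnames(res_sh) <- list(indicators, c("a2", "c2", "e2"))
  list(latent = stats::setNames(q$ace, c("a2", "c2", "e2")),
       loadings = stats::setNames(q$lam, indicators),
       residual_var = q$res, residual = res_sh,
       m2ll = fit$value, n_mz = n_mz, n_dz = n_dz)
}

#' Cross-twin cross-trait correlation by zygosity
#'
#' Double-entered correlation of twin 1's `trait1` with twin 2's `trait2`
#' (pooling both orderings, so the estimate is symmetric in trait order and
#' member labels). Shared genetic influences show up as MZ cross-trait
#' correlations about twice the DZ ones.
#'
#' @param pairs a [pair_traits()] table.
#' @param trait1,trait2 trait names.
#' @return named vector with `MZ` and `DZ` cross-twin cross-trait
#'   correlations.
#' @export
cross_twin_cross_trait <- function(pairs, trait1, trait2) {
  out <- c(MZ = NA_real_, DZ = NA_real_)
  for (z in c("MZ", "DZ")) {
    d <- pairs[pairs$zygosity == z, , drop = FALSE]
    x1 <- d[[paste0(trait1, "_1")]]; x2 <- d[[paste0(trait1, "_2")]]
    y1 <- d[[paste0(trait2, "_1")]]; y2 <- d[[paste0(trait2, "_2")]]
    xx <- c(x1, x2); yy <- c(y2, y1)
    if (stats::sd(xx) == 0 || stats::sd(yy) == 0) stop("zero-variance trait")
    out[z] <- stats::cor(xx, yy)
  }
  out
}
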