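#' Fit a one-factor confirmatory factor model by maximum likelihood
#'
#' Single-factor model `Sigma = lambda lambda' + diag(theta)` fitted to the
#' Pearson correlation matrix of complete cases by minimizing the normal-
#' theory ML discrepancy
#' `F = log det(Sigma) + tr(R Sigma^-1) - log det(R) - p`.
#' The factor is identified by unit factor variance with the first loading
#' constrained positive. Residual variances are bounded at zero; a loading
#' whose residual hits the bound is flagged as a Heywood case.
#'
#' @param indicators numeric matrix / data frame (rows = individuals,
#'   columns = indicators); standardized internally.
#' @return An object of class `factor_model`: `loadings`, `theta`,
#'   `fit` (ML discrepancy), `logLik`, `n`, `converged`, `heywood`,
#'   `degenerate` (all loadings near zero), `indicator_names`.
#' @export
fit_one_factor_cfa <- function(indicators) {
  X <- as.matrix(indicators)
  if (ncol(X) < 3) stop("a single-factor model needs >= 3 indicators (under-identified)")
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  n <- nrow(X)
  if (n < 50) stop("fewer than 50 complete-case rows")
  p <- ncol(X)
  R <- stats::cor(X)

  obj <- function(par) {
    lam <- par[1:p]; th <- par[(p + 1):(2 * p)]
    S <- tcrossprod(lam) + diag(th, p)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    ldet + sum(diag(chol2inv(ch) %*% R))
  }

  lam0 <- sqrt(pmax(abs(R[1, ]) * abs(R[, 1]) / max(abs(R[1, 2]), 0.1), 0.1))
  lam0 <- pmin(lam0, 0.95)
  par0 <- c(lam0, pmax(1 - lam0^2, 0.05))
  fit <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = c(rep(-1.5, p), rep(1e-6, p)),
                      upper = c(rep(1.5, p), rep(2, p)),
                      control = list(maxit = 1000, factr = 1e4))
  if (fit$convergence != 0) {
    g <- tryCatch(sqrt(sum(.num_grad(obj, fit$par)^2)), error = function(e) NA)
    stop(sprintf("CFA did not converge (code %d, gradient norm %.3g)",
                 fit$convergence, g))
  }
  lam <- fit$par[1:p]; th <- fit$par[(p + 1):(2 * p)]
  if (lam[1] < 0) lam <- -lam
  const <- -log(det(R)) - p
  structure(list(
    loadings = stats::setNames(lam, colnames(X)),
    theta = stats::setNames(th, colnames(X)),
    fit = fit$value + const,
    logLik = -n / 2 * (fit$value + as.numeric(determinant(R)$modulus) + p),
    n = n, converged = TRUE,
    heywood = any(th <= 1e-5),
    # no common variance: all model-implied cross-covariances negligible
    # (covers both the all-zero case and the single-indicator ridge)
    degenerate = max(abs(tcrossprod(lam)[upper.tri(diag(p))])) < 0.05,
    indicator_names = colnames(X)
  ), class = "factor_model")
}

.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d indicators, n = %d, ML discrepancy %.4g%s\n",
              length(x$loadings), x$n, x$fit,
              if (x$heywood) " [Heywood]" else ""))
  print(round(rbind(loading = x$loadings, residual = x$theta), 3))
  invisible(x)
}

#' Regression-method factor scores
#'
#' Linear scores `lambda' Sigma^-1 x` on standardized indicators (the
#' regression / Thomson method). Scores shrink towards zero: their SD is at
#' most 1. Rows with every indicator missing get `NA`; partially missing
#' rows use the observed subset (the corresponding sub-model projection).
#'
#' @param model a [fit_one_factor_cfa()] object.
#' @param indicators matrix with the model's indicator columns.
#' @return Numeric vector of factor scores.
#' @export
factor_scores <- function(model, indicators) {
  stopifnot(inherits(model, "factor_model"))
  X <- as.matrix(indicators)
  if (!is.null(model$indicator_names) && !is.null(colnames(X))) {
    X <- X[, model$indicator_names, drop = FALSE]
  }
  X <- scale(X)
  lam <- model$loadings; th <- model$theta
  p <- length(lam)
  scores <- rep(NA_real_, nrow(X))
  obs_pat <- !is.na(X)
  pats <- unique(obs_pat)
  for (r in seq_len(nrow(pats))) {
    sel <- which(pats[r, ])
    if (!length(sel)) next
    rows <- which(apply(obs_pat, 1, function(z) all(z == pats[r, ])))
    S <- tcrossprod(lam[sel]) + diag(th[sel], length(sel))
    w <- solve(S, lam[sel])
    scores[rows] <- X[rows, sel, drop = FALSE] %*% w
  }
  as.vector(scores)
}

#' Mean composite of standardized cognitive test scores
#'
#' The general cognitive ability composite: the mean of the standardized
#' test scores (two verbal + two non-verbal in the synthetic cohort),
#' re-standardized. Individuals missing more than `max_missing` tests get
#' `NA`; those with some missing tests use the mean of the remaining ones
#' and are flagged.
#'
#' @param tests numeric matrix of test scores (columns = tests).
#' @param max_missing maximum number of missing tests tolerated per row.
#' @return Numeric vector with attribute `partial` (logical flag per row).
#' @export
g_composite <- function(tests, max_missing = 1L) {
  X <- scale(as.matrix(tests))
  n_miss <- rowSums(is.na(X))
  out <- rowMeans(X, na.rm = TRUE)
  out[n_miss > max_missing | n_miss == ncol(X)] <- NA
  ok <- is.finite(out)
  out[ok] <- (out[ok] - mean(out[ok])) / stats::sd(out[ok])
  attr(out, "partial") <- n_miss > 0 & is.finite(out)
  out
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y numeric vectors.
#' @param level confidence level.
#' @return list `r`, `ci` (length 2), `n`, `degenerate` (|r| = 1 flag).
#' @export
corr_with_ci <- function(x, y, level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    return(list(r = r, ci = c(r, r), n = n, degenerate = TRUE))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)), n = n, degenerate = FALSE)
}

#' Standardized multiple regression with classical inference
#'
#' OLS of the standardized outcome on standardized predictors (plus
#' optional covariates), the workhorse of the phenotypic analyses: the
#' association of non-cognitive skills with achievement beyond general
#' cognitive ability. Coefficients are standardized betas; p-values carry a
#' Benjamini-Hochberg adjusted column across the focal predictors.
#'
#' @param y outcome vector.
#' @param X data frame / matrix of focal predictors.
#' @param covariates optional data frame of covariates (standardized if
#'   numeric; factors expanded).
#' @param level confidence level.
#' @return An object of class `regression_result`: data frame `coef` with
#'   `term, beta, se, ci_lo, ci_hi, p, p_adj`, plus `n`, `r_squared`.
#' @export
standardized_multiple_regression <- function(y, X, covariates = NULL,
                                             level = 0.95) {
  X <- as.data.frame(X)
  df <- data.frame(.y = y, X, check.names = FALSE)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (j in names(df)) {
    if (is.numeric(df[[j]])) {
      if (stats::sd(df[[j]]) == 0) {
        stop(sprintf("zero-variance column '%s' in design", sub("^\\.y$", "y", j)))
      }
      df[[j]] <- as.vector(scale(df[[j]]))
    }
  }
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  q <- stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
  focal <- rownames(co) %in% names(X)
  p_adj <- rep(NA_real_, nrow(co))
  p_adj[focal] <- stats::p.adjust(co[focal, 4], method = "BH")
  res <- data.frame(term = rownames(co), beta = co[, 1], se = co[, 2],
                    ci_lo = co[, 1] - q * co[, 2], ci_hi = co[, 1] + q * co[, 2],
                    p = co[, 4], p_adj = p_adj, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(coef = res, n = nrow(df), r_squared = sm$r.squared),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(transform(x$coef, beta = round(beta, 3), se = round(se, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p = signif(p, 3), p_adj = signif(p_adj, 3)))
  invisible(x)
}
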