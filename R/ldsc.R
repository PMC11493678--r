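#' LD-score regression SNP heritability
#'
#' Weighted regression of per-SNP chi-square statistics on
#' `x_j = N_j l_j / M` with a free intercept:
#' `E[chi2_j] = 1 + N h2 l_j / M` plus an intercept shift for confounding.
#' Two-step weighting: initial weights `1 / max(l_j, 1)`, refreshed once to
#' `1 / (max(l_j, 1) * (1 + N h2_1 l_j / M)^2)` using the first-pass
#' heritability. Standard errors come from a delete-one-block jackknife
#' over contiguous SNP blocks.
#'
#' @param ss sumstats data frame (`SNP`, `N`, `Z`, ...).
#' @param ldscores per-SNP LD scores: numeric vector aligned with `ss`, or
#'   a data frame with `SNP` and `L2` columns.
#' @param M number of SNPs the heritability refers to (default: number of
#'   regression SNPs).
#' @param n_blocks jackknife blocks (contiguous by SNP order).
#' @param free_intercept estimate the intercept (default). An LD-free
#'   panel makes `l_j` constant, so intercept and slope are collinear;
#'   set `FALSE` to pin the intercept at 1 (the no-confounding value),
#'   which is required in that case.
#' @return list of class `ldsc_h2`: `h2`, `intercept`, `h2_se`,
#'   `intercept_se`, `mean_chi2`, `M`, `n_snps`, `n_blocks`.
#' @export
ldsc_h2 <- function(ss, ldscores, M = NULL, n_blocks = 200L,
                    free_intercept = TRUE) {
  l <- .align_ldscores(ss, ldscores)
  n_snp <- nrow(ss)
  if (n_snp < 200) stop("need at least 200 SNPs for LD-score regression")
  if (n_snp < n_blocks) stop("fewer SNPs than jackknife blocks")
  if (is.null(M)) M <- n_snp
  chi2 <- ss$Z^2
  x <- ss$N * l / M
  if (free_intercept && stats::sd(l) < 1e-10) {
    stop("constant LD scores make the intercept unidentifiable; use free_intercept = FALSE")
  }

  w1 <- 1 / pmax(l, 1)
  fit1 <- .wls2(x, chi2, w1, free_intercept)
  het <- pmax(x * fit1$slope + fit1$intercept, 0.1)
  w2 <- 1 / (pmax(l, 1) * het^2)
  jk <- .wls2_jackknife(x, chi2, w2, n_blocks, free_intercept)
  jk[] <- lapply(jk, unname)
  structure(list(h2 = jk$slope, intercept = jk$intercept,
                 h2_se = jk$slope_se, intercept_se = jk$intercept_se,
                 mean_chi2 = mean(chi2), M = M, n_snps = n_snp,
                 n_blocks = n_blocks), class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("<ldsc_h2> h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), mean chi2 = %.3f, M = %d\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$mean_chi2, x$M))
  invisible(x)
}

#' LD-score regression genetic correlation between two traits
#'
#' Cross-trait regression of `Z1 Z2` on `sqrt(N1 N2) l_j / M` with free
#' intercept gives the genetic covariance `rho_g`; the genetic correlation
#' is `rg = rho_g / sqrt(h2_1 h2_2)` with the per-trait heritabilities from
#' [ldsc_h2()]. The jackknife SE of `rg` re-estimates all three regressions
#' per deleted block.
#'
#' @param ss1,ss2 harmonized sumstats data frames on a shared SNP map.
#' @param ldscores LD scores as in [ldsc_h2()].
#' @param M,n_blocks as in [ldsc_h2()].
#' @return list of class `ldsc_rg`: `rho_g`, `rg`, `rg_se`, `h2_1`,
#'   `h2_2`, `intercept`.
#' @export
ldsc_rg <- function(ss1, ss2, ldscores, M = NULL, n_blocks = 200L) {
  if (!identical(ss1$SNP, ss2$SNP)) {
    stop("sumstats do not share a SNP map; harmonize() them first")
  }
  l <- .align_ldscores(ss1, ldscores)
  n_snp <- nrow(ss1)
  if (n_snp < n_blocks) stop("fewer SNPs than jackknife blocks")
  if (is.null(M)) M <- n_snp

  sys <- .rg_systems(ss1, ss2, l, M, n_blocks)
  est <- .rg_from_sums(lapply(sys, function(s) list(XtWX = s$XtWX_tot, XtWy = s$XtWy_tot)))

  # jackknife over blocks shared by the three regressions
  blocks <- .block_ids(n_snp, n_blocks)
  th <- vapply(seq_len(n_blocks), function(b) {
    del <- lapply(sys, function(s) list(
      XtWX = s$XtWX_tot - s$XtWX_blk[, , b],
      XtWy = s$XtWy_tot - s$XtWy_blk[, b]))
    .rg_from_sums(del)$rg
  }, numeric(1))
  rg_se <- sqrt((n_blocks - 1) / n_blocks * sum((th - mean(th))^2))
  structure(list(rho_g = est$rho_g, rg = est$rg, rg_se = rg_se,
                 h2_1 = est$h2_1, h2_2 = est$h2_2,
                 intercept = est$intercept), class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  cat(sprintf("<ldsc_rg> rg = %.4f (SE %.4f), rho_g = %.4f, h2 = %.4f / %.4f\n",
              x$rg, x$rg_se, x$rho_g, x$h2_1, x$h2_2))
  invisible(x)
}

# build the three weighted regressions (h2 trait1, h2 trait2, cross) with
# two-step weights, returning block-partitioned sufficient statistics
.rg_systems <- function(ss1, ss2, l, M, n_blocks = NULL) {
  lp <- pmax(l, 1)
  mk <- function(x, y, w) list(x = x, y = y, w = w)
  x1 <- ss1$N * l / M; x2 <- ss2$N * l / M
  xc <- sqrt(ss1$N * ss2$N) * l / M
  # step-1 fitted values (including intercepts) drive the weight update, so
  # the three regressions use mutually consistent expected second moments
  g1 <- .wls2(x1, ss1$Z^2, 1 / lp)
  g2 <- .wls2(x2, ss2$Z^2, 1 / lp)
  f1 <- .wls2(xc, ss1$Z * ss2$Z, 1 / lp)
  het1 <- pmax(x1 * g1$slope + g1$intercept, 0.1)
  het2 <- pmax(x2 * g2$slope + g2$intercept, 0.1)
  cr <- xc * f1$slope + f1$intercept
  regs <- list(mk(x1, ss1$Z^2, 1 / (lp * het1^2)),
               mk(x2, ss2$Z^2, 1 / (lp * het2^2)),
               mk(xc, ss1$Z * ss2$Z, 1 / (lp * (het1 * het2 + cr^2))))
  n_snp <- length(l)
  nb <- if (is.null(n_blocks)) max(1L, min(200L, n_snp %/% 50L)) else n_blocks
  blocks <- .block_ids(n_snp, nb)
  lapply(regs, function(r) {
    X <- cbind(1, r$x)
    WX <- X * r$w
    XtWX_tot <- crossprod(WX, X)
    XtWy_tot <- drop(crossprod(WX, r$y))
    XtWX_blk <- array(0, c(2, 2, nb))
    XtWy_blk <- matrix(0, 2, nb)
    for (b in seq_len(nb)) {
      i <- which(blocks == b)
      XtWX_blk[, , b] <- crossprod(WX[i, , drop = FALSE], X[i, , drop = FALSE])
      XtWy_blk[, b] <- drop(crossprod(WX[i, , drop = FALSE], r$y[i]))
    }
    list(XtWX_tot = XtWX_tot, XtWy_tot = XtWy_tot,
         XtWX_blk = XtWX_blk, XtWy_blk = XtWy_blk)
  })
}

.rg_from_sums <- function(sys) {
  est <- lapply(sys, function(s) unname(drop(solve(s$XtWX, s$XtWy))))
  h2_1 <- est[[1]][2]; h2_2 <- est[[2]][2]; rho <- est[[3]][2]
  denom <- sqrt(max(h2_1, 1e-12) * max(h2_2, 1e-12))
  list(h2_1 = h2_1, h2_2 = h2_2, rho_g = rho, rg = rho / denom,
       intercept = est[[3]][1])
}

.block_ids <- function(n, n_blocks) {
  as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
}

.wls2 <- function(x, y, w, free_intercept = TRUE) {
  if (!free_intercept) {
    return(list(intercept = 1,
                slope = sum(w * x * (y - 1)) / sum(w * x^2)))
  }
  X <- cbind(1, x)
  b <- solve(crossprod(X * w, X), crossprod(X * w, y))
  list(intercept = b[1], slope = b[2])
}

.wls2_jackknife <- function(x, y, w, n_blocks, free_intercept = TRUE) {
  blocks <- .block_ids(length(x), n_blocks)
  if (!free_intercept) {
    num_tot <- sum(w * x * (y - 1)); den_tot <- sum(w * x^2)
    th <- vapply(seq_len(n_blocks), function(b) {
      i <- which(blocks == b)
      (num_tot - sum(w[i] * x[i] * (y[i] - 1))) /
        (den_tot - sum(w[i] * x[i]^2))
    }, numeric(1))
    se <- sqrt((n_blocks - 1) / n_blocks * sum((th - mean(th))^2))
    return(list(intercept = 1, slope = num_tot / den_tot,
                intercept_se = 0, slope_se = se, jk = cbind(1, th)))
  }
  X <- cbind(1, x)
  WX <- X * w
  XtWX <- crossprod(WX, X)
  XtWy <- drop(crossprod(WX, y))
  b_full <- solve(XtWX, XtWy)
  th <- matrix(NA_real_, n_blocks, 2)
  for (b in seq_len(n_blocks)) {
    i <- which(blocks == b)
    Xb <- X[i, , drop = FALSE]
    XtWXb <- XtWX - crossprod(WX[i, , drop = FALSE], Xb)
    XtWyb <- XtWy - drop(crossprod(WX[i, , drop = FALSE], y[i]))
    th[b, ] <- solve(XtWXb, XtWyb)
  }
  se <- sqrt((n_blocks - 1) / n_blocks * colSums(sweep(th, 2, colMeans(th))^2))
  list(intercept = b_full[1], slope = b_full[2],
       intercept_se = se[1], slope_se = se[2], jk = th)
}

.align_ldscores <- function(ss, ldscores) {
  if (is.data.frame(ldscores)) {
    i <- match(ss$SNP, ldscores$SNP)
    if (anyNA(i)) stop("LD scores missing for some sumstats SNPs")
    ldscores$L2[i]
  } else {
    if (length(ldscores) != nrow(ss)) {
      stop("ldscores vector must align with the sumstats rows")
    }
    as.numeric(ldscores)
  }
}

#' Harmonize several sumstats tables to a shared allele orientation
#'
#' Aligns effect alleles of every trait to the first one: direct matches
#' are kept, A1/A2 swaps flip the Z sign, strand-ambiguous SNPs (A/T, C/G)
#' and unresolvable allele pairs are dropped across all traits. A drop
#' report is attached as attribute `report`.
#'
#' @param ss_list a `sumstats_set` or named list of sumstats data frames.
#' @return A harmonized `sumstats_set` (shared SNP map, aligned alleles).
#' @export
harmonize <- function(ss_list) {
  traits <- if (inherits(ss_list, "sumstats_set")) ss_list$traits else ss_list
  stopifnot(length(traits) >= 1)
  ref <- traits[[1]]
  amb <- function(a1, a2) paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
  keep <- !amb(ref$A1, ref$A2)
  n_amb <- sum(!keep)
  n_mismatch <- 0L
  flips <- vector("list", length(traits))
  common <- ref$SNP
  for (k in seq_along(traits)) common <- intersect(common, traits[[k]]$SNP)
  ref_idx <- match(common, ref$SNP)
  keep_c <- keep[ref_idx]
  aligned <- vector("list", length(traits))
  for (k in seq_along(traits)) {
    d <- traits[[k]][match(common, traits[[k]]$SNP), , drop = FALSE]
    same <- d$A1 == ref$A1[ref_idx] & d$A2 == ref$A2[ref_idx]
    swap <- d$A1 == ref$A2[ref_idx] & d$A2 == ref$A1[ref_idx]
    bad <- !(same | swap)
    n_mismatch <- n_mismatch + sum(bad & keep_c)
    d$Z[swap] <- -d$Z[swap]
    d$A1[swap | bad] <- ref$A1[ref_idx][swap | bad]
    d$A2[swap | bad] <- ref$A2[ref_idx][swap | bad]
    d$MAF[swap] <- 1 - d$MAF[swap]
    keep_c <- keep_c & !bad
    aligned[[k]] <- d
  }
  aligned <- lapply(aligned, function(d) {
    d <- d[keep_c, , drop = FALSE]; rownames(d) <- NULL; d
  })
  names(aligned) <- names(traits)
  out <- structure(list(traits = aligned, snp = aligned[[1]]$SNP),
                   class = "sumstats_set")
  attr(out, "report") <- list(n_ambiguous_dropped = n_amb,
                              n_mismatch_dropped = n_mismatch,
                              n_kept = sum(keep_c))
  out
}

#' Genetic covariance matrix S and its jackknife sampling covariance V
#'
#' Pairwise LD-score regressions over all trait pairs give the genetic
#' covariance matrix `S` (diagonal: per-trait heritabilities). The
#' sampling covariance `V` of the unique elements of `S` (half-vectorized,
#' column-major order of the lower triangle) comes from a joint
#' delete-one-block jackknife: every pairwise slope is re-estimated with
#' the same block deleted, so cross-element dependences are captured.
#'
#' @param ss_list a harmonized `sumstats_set` (or list of aligned tables).
#' @param ldscores LD scores as in [ldsc_h2()].
#' @param M,n_blocks as in [ldsc_h2()].
#' @return list of class `genetic_cov`: `S`, `V`, `traits`, `n_blocks`,
#'   `psd_projected` flag (S clipped to nearest PSD when needed; V always
#'   refers to the unprojected estimates).
#' @export
build_s_v <- function(ss_list, ldscores, M = NULL, n_blocks = 200L) {
  traits <- if (inherits(ss_list, "sumstats_set")) ss_list$traits else ss_list
  K <- length(traits)
  stopifnot(K >= 2)
  snp <- traits[[1]]$SNP
  for (k in seq_len(K)) {
    if (!identical(traits[[k]]$SNP, snp)) {
      stop(sprintf("trait '%s' is not on the shared SNP map; harmonize() first",
                   names(traits)[k]))
    }
  }
  l <- .align_ldscores(traits[[1]], ldscores)
  n_snp <- length(snp)
  if (n_snp < n_blocks) stop("fewer SNPs than jackknife blocks")
  if (is.null(M)) M <- n_snp
  lp <- pmax(l, 1)
  blocks <- .block_ids(n_snp, n_blocks)

  # first-pass chi2 fits (per trait) for the weight updates
  het <- lapply(traits, function(d) {
    f <- .wls2(d$N * l / M, d$Z^2, 1 / lp)
    pmax((d$N * l / M) * f$slope + f$intercept, 0.1)
  })

  pairs <- which(lower.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  n_el <- nrow(pairs)
  est <- numeric(n_el)
  th <- matrix(NA_real_, n_blocks, n_el)
  for (e in seq_len(n_el)) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    di <- traits[[i]]; dj <- traits[[j]]
    x <- sqrt(di$N * dj$N) * l / M
    y <- di$Z * dj$Z
    f1 <- .wls2(x, y, 1 / lp)
    cr <- x * f1$slope + f1$intercept
    w <- 1 / (lp * (het[[i]] * het[[j]] + cr^2))
    fit <- tryCatch(.wls2_jackknife(x, y, w, n_blocks), error = function(err)
      stop(sprintf("pairwise LDSC failed for traits '%s' x '%s': %s",
                   names(traits)[i], names(traits)[j], conditionMessage(err))))
    est[e] <- fit$slope
    th[, e] <- fit$jk[, 2]
  }
  S <- matrix(0, K, K)
  S[cbind(pairs[, 1], pairs[, 2])] <- est
  S[cbind(pairs[, 2], pairs[, 1])] <- est
  dimnames(S) <- list(names(traits), names(traits))
  V <- (n_blocks - 1) / n_blocks * crossprod(sweep(th, 2, colMeans(th)))

  psd_projected <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 0) {
    S <- ev$vectors %*% diag(pmax(ev$values, 0), K) %*% t(ev$vectors)
    dimnames(S) <- list(names(traits), names(traits))
    psd_projected <- TRUE
  }
  structure(list(S = S, V = V, traits = names(traits), n_blocks = n_blocks,
                 pairs = pairs, psd_projected = psd_projected),
            class = "genetic_cov")
}

#' @export
print.genetic_cov <- function(x, ...) {
  cat(sprintf("<genetic_cov> %d traits, %d jackknife blocks%s\n",
              length(x$traits), x$n_blocks,
              if (x$psd_projected) " [S projected to PSD]" else ""))
  print(round(x$S, 4))
  invisible(x)
}
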