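#' LDpred polygenic-score weights under the infinitesimal prior
#'
#' Closed-form infinitesimal LDpred: within each LD block the posterior
#' mean effect solves `(M / (N h2) I + D) beta_inf = beta_hat_marginal` on
#' the standardized-genotype scale, where `D` is the block LD matrix of the
#' reference panel. With identity LD this reduces to the scalar shrinkage
#' `beta_inf = beta_hat * N h2 / (N h2 + M)`. Weights are returned on the
#' per-allele scale of the input (standardized weights divided by
#' `sqrt(2 p (1 - p))`).
#'
#' @param ss sumstats data frame (`SNP`, `A1`, `N`, `Z`, ...).
#' @param panel the LD reference panel ([build_ld_panel()]).
#' @param h2 SNP heritability for the shrinkage; `NULL` estimates it from
#'   the input via [ldsc_h2()] (mirroring real usage where the truth is
#'   unknown).
#' @param N GWAS sample size (default: median of the `N` column).
#' @param trait label stored with the weights.
#' @return An object of class `pgs_weights`: data frame `weights`
#'   (`SNP, A1, BETA_INF, TRAIT`) plus `h2`, `N`, `M` used; SNPs absent
#'   from the panel are dropped with a count in attribute `n_dropped`.
#' @export
ldpred_inf <- function(ss, panel, h2 = NULL, N = NULL, trait = "trait") {
  stopifnot(inherits(panel, "ld_panel"))
  if (is.null(N)) N <- stats::median(ss$N)
  if (is.null(h2)) {
    h2 <- ldsc_h2(ss, panel$ldscore[match(ss$SNP, panel$snp)],
                  n_blocks = min(200L, nrow(ss) %/% 50L))$h2
    h2 <- min(max(h2, 0.01), 1)
  }
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")

  idx <- match(ss$SNP, panel$snp)
  n_dropped <- sum(is.na(idx))
  keep <- !is.na(idx)
  ss <- ss[keep, , drop = FALSE]
  idx <- idx[keep]
  M <- nrow(ss)
  beta_marg <- ss$Z / sqrt(ss$N)            # standardized scale
  shrink <- M / (N * h2)

  beta_inf <- numeric(M)
  pos_of <- match(seq_len(panel$n_snps), idx)  # panel position -> ss row
  for (b in seq_along(panel$blocks)) {
    pidx <- panel$block_index[[b]]
    rows <- pos_of[pidx]
    ok <- !is.na(rows)
    if (!any(ok)) next
    Dm <- panel$blocks[[b]][ok, ok, drop = FALSE]
    A <- Dm + diag(shrink, sum(ok))
    sol <- tryCatch(solve(A, beta_marg[rows[ok]]), error = function(e)
      stop("singular LDpred system (unexpected for h2 > 0 and PSD LD)"))
    beta_inf[rows[ok]] <- sol
  }
  p <- panel$maf[idx]
  w <- data.frame(SNP = ss$SNP, A1 = ss$A1,
                  BETA_INF = beta_inf / sqrt(2 * p * (1 - p)),
                  TRAIT = trait, stringsAsFactors = FALSE)
  structure(list(weights = w, h2 = h2, N = N, M = M,
                 beta_inf_std = beta_inf),
            class = "pgs_weights", n_dropped = n_dropped)
}

#' @export
print.pgs_weights <- function(x, ...) {
  cat(sprintf("<pgs_weights> '%s': %d SNPs, h2 = %.3f, N = %d\n",
              x$weights$TRAIT[1], nrow(x$weights), x$h2, as.integer(x$N)))
  invisible(x)
}

#' Score individuals with polygenic-score weights
#'
#' Raw score = sum over SNPs of `weight * dosage` after aligning the
#' weights' effect allele with the genotype coding: a weight whose effect
#' allele matches the genotype's other allele is applied to the flipped
#' dosage `2 - d`. Unresolvable alleles are dropped with a count. Scores
#' are standardized within the scored cohort.
#'
#' @param genotypes a [simulate_families()] object (or any list with
#'   integer `dosage`, `info`, and panel-compatible `snp`/`A1`/`A2`).
#' @param weights a [ldpred_inf()] object or a bare weights data frame
#'   (`SNP`, `A1`, `BETA_INF`).
#' @param offspring_only score offspring rows only (default `TRUE`).
#' @return A `score_table` data frame: `id`, `family_id`, `member`,
#'   `zygosity`, `score_raw`, `score_std`; attribute `n_dropped`.
#' @export
pgs_score <- function(genotypes, weights, offspring_only = TRUE) {
  w <- if (inherits(weights, "pgs_weights")) weights$weights else weights
  panel <- genotypes$panel
  idx <- match(w$SNP, panel$snp)
  n_dropped <- sum(is.na(idx))
  keep <- !is.na(idx)
  w <- w[keep, , drop = FALSE]; idx <- idx[keep]

  same <- w$A1 == panel$A1[idx]
  flip <- w$A1 == panel$A2[idx]
  bad <- !(same | flip)
  n_dropped <- n_dropped + sum(bad)
  w <- w[!bad, , drop = FALSE]; idx <- idx[!bad]
  sgn <- ifelse(w$A1 == panel$A1[idx], 1, -1)

  rows <- if (offspring_only) genotypes$info$role == "offspring"
          else rep(TRUE, nrow(genotypes$info))
  D <- genotypes$dosage[rows, idx, drop = FALSE]
  # flipped allele contributes -w * d; the 2w translation a full flip would
  # add is omitted (scores are translation-invariant after standardization)
  raw <- as.vector(D %*% (w$BETA_INF * sgn))
  info <- genotypes$info[rows, , drop = FALSE]
  std <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw * 0
  out <- data.frame(id = info$id, family_id = info$family_id,
                    member = info$member, zygosity = info$zygosity,
                    score_raw = raw, score_std = std,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("score_table", class(out))
  out
}

#' Write PGS weights / scores to their plain-text interfaces
#' @param x a `pgs_weights` or `score_table`.
#' @param path output path (TSV for weights, CSV for scores).
#' @return `path`, invisibly.
#' @export
write_pgs <- function(x, path) {
  if (inherits(x, "pgs_weights")) {
    utils::write.table(x$weights, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
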