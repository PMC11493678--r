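#' Simulate genotyped twin families on an LD panel
#'
#' Parent genotypes are drawn haplotype-wise under Hardy-Weinberg
#' equilibrium with block LD by thresholding correlated standard normals at
#' the MAF quantile; offspring are formed by Mendelian transmission of one
#' parental haplotype per LD block (crossover-free segments at block
#' granularity, so within-block LD is preserved in offspring and the
#' expected DZ relatedness is 0.5). MZ pairs duplicate a single offspring.
#'
#' An optional stratification axis (one standard-normal value per family)
#' shifts the liability threshold of every SNP by `strat_geno_shift * u`,
#' inducing a geography-like gradient in allele frequencies that the
#' phenotype stage can couple to.
#'
#' @param panel an [build_ld_panel()] object.
#' @param n_mz_pairs,n_dz_pairs numbers of MZ / DZ twin pairs.
#' @param seed integer seed.
#' @param keep_parents keep parental dosage rows (needed for indirect
#'   genetic effects downstream; set `FALSE` to halve memory).
#' @param strat_geno_shift liability-threshold shift per SD of the
#'   stratification axis (0 disables genotypic stratification).
#' @return An object of class `genotype_set`: list with integer `dosage`
#'   matrix (individuals x SNPs), `info` data frame (`id`, `family_id`,
#'   `member`, `zygosity`, `role`), `strat` (per-family axis), and the
#'   `panel`.
#' @export
simulate_families <- function(panel, n_mz_pairs, n_dz_pairs, seed = 1L,
                              keep_parents = TRUE, strat_geno_shift = 0) {
  stopifnot(inherits(panel, "ld_panel"), n_mz_pairs >= 0, n_dz_pairs >= 0,
            n_mz_pairs + n_dz_pairs >= 1)
  n_fam <- n_mz_pairs + n_dz_pairs
  M <- panel$n_snps
  zyg <- rep(c("MZ", "DZ"), c(n_mz_pairs, n_dz_pairs))

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  u_strat <- stats::rnorm(n_fam)

  n_off <- 2L * n_fam
  dos_off <- matrix(0L, n_off, M)
  dos_par <- if (keep_parents) matrix(0L, n_off, M) else NULL

  chols <- .panel_chol(panel)
  thr_base <- stats::qnorm(panel$maf)
  # row layout of the haplotype matrix per block:
  # father hap1/hap2 = rows 4f-3, 4f-2 ; mother hap1/hap2 = rows 4f-1, 4f
  fi1 <- seq(1L, 4L * n_fam, by = 4L)
  shift <- strat_geno_shift * u_strat

  for (b in seq_along(panel$blocks)) {
    idx <- panel$block_index[[b]]
    p <- length(idx)
    Z <- matrix(stats::rnorm(4L * n_fam * p), 4L * n_fam, p) %*% chols[[b]]
    thr <- matrix(thr_base[idx], 4L * n_fam, p, byrow = TRUE) +
      rep(shift, each = 4L)
    H <- Z < thr  # logical haplotype matrix
    storage.mode(H) <- "integer"

    # one transmitted haplotype per parent per block per offspring
    pickF1 <- sample(0:1, n_fam, replace = TRUE)
    pickM1 <- sample(0:1, n_fam, replace = TRUE)
    pickF2 <- sample(0:1, n_fam, replace = TRUE)
    pickM2 <- sample(0:1, n_fam, replace = TRUE)
    mz <- zyg == "MZ"
    pickF2[mz] <- pickF1[mz]
    pickM2[mz] <- pickM1[mz]

    t1 <- H[fi1 + pickF1, , drop = FALSE] + H[fi1 + 2L + pickM1, , drop = FALSE]
    t2 <- H[fi1 + pickF2, , drop = FALSE] + H[fi1 + 2L + pickM2, , drop = FALSE]
    dos_off[seq(1L, n_off, by = 2L), idx] <- t1
    dos_off[seq(2L, n_off, by = 2L), idx] <- t2
    if (keep_parents) {
      dos_par[seq(1L, n_off, by = 2L), idx] <-
        H[fi1, , drop = FALSE] + H[fi1 + 1L, , drop = FALSE]
      dos_par[seq(2L, n_off, by = 2L), idx] <-
        H[fi1 + 2L, , drop = FALSE] + H[fi1 + 3L, , drop = FALSE]
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  fam_ids <- sprintf("fam%05d", seq_len(n_fam))
  info_off <- data.frame(
    id = paste0(rep(fam_ids, each = 2L), "_t", rep(1:2, n_fam)),
    family_id = rep(fam_ids, each = 2L),
    member = rep(1:2, n_fam),
    zygosity = rep(zyg, each = 2L),
    role = "offspring",
    stringsAsFactors = FALSE
  )
  dosage <- dos_off
  info <- info_off
  if (keep_parents) {
    info_par <- data.frame(
      id = paste0(rep(fam_ids, each = 2L), "_p", rep(1:2, n_fam)),
      family_id = rep(fam_ids, each = 2L),
      member = rep(1:2, n_fam),
      zygosity = rep(zyg, each = 2L),
      role = "parent",
      stringsAsFactors = FALSE
    )
    dosage <- rbind(dos_off, dos_par)
    info <- rbind(info_off, info_par)
  }
  rownames(dosage) <- info$id

  structure(list(dosage = dosage, info = info, strat = u_strat,
                 family_id = fam_ids, zygosity = zyg, panel = panel),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d individuals (%d offspring) x %d SNPs, %d families\n",
              nrow(x$dosage), sum(x$info$role == "offspring"),
              ncol(x$dosage), length(x$family_id)))
  invisible(x)
}

#' Standardized polygenic value of each individual for a weight vector
#'
#' Internal helper: `g_i = sum_j w_j (d_ij - 2 p_j) / sqrt(2 p_j (1-p_j))`,
#' scaled by the theoretical SD `sqrt(w' D w)` implied by the panel LD so
#' that the population variance is 1.
#' @noRd
.genetic_value <- function(genotypes, weights, snp_idx) {
  panel <- genotypes$panel
  p <- panel$maf[snp_idx]
  sc <- 1 / sqrt(2 * p * (1 - p))
  D <- genotypes$dosage[, snp_idx, drop = FALSE]
  ctr <- 2 * p * sc
  raw <- D %*% (weights * sc) - sum(ctr * weights)
  # theoretical variance sum over blocks of w' D_b w
  v <- 0
  for (b in seq_along(panel$blocks)) {
    idx <- panel$block_index[[b]]
    sel <- match(intersect(idx, snp_idx), snp_idx)
    if (!length(sel)) next
    pos <- match(snp_idx[sel], idx)
    v <- v + drop(t(weights[sel]) %*% panel$blocks[[b]][pos, pos, drop = FALSE] %*% weights[sel])
  }
  drop(raw) / sqrt(v)
}
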