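#' Build a block-diagonal LD reference panel
#'
#' Constructs a synthetic linkage-disequilibrium panel with block-diagonal
#' correlation structure. Within a block, the SNP-SNP correlation decays
#' autoregressively, `r^(|i - j|)`, which is both positive definite by
#' construction and a reasonable caricature of local LD; blocks are
#' independent of each other. Per-SNP LD scores are the within-block row
#' sums of squared correlations, `l_j = sum_k r_jk^2` (so `l_j >= 1`, the
#' SNP's correlation with itself).
#'
#' @param n_snps total number of SNPs `M`.
#' @param block_size SNPs per LD block (last block may be smaller). A
#'   vector defines a repeating pattern of block sizes, letting a panel mix
#'   low- and high-LD regions the way real genomes do (and giving the LD
#'   scores the spread that LD-score regression needs for a
#'   well-identified intercept).
#' @param maf_range length-2 numeric, range of minor-allele frequencies
#'   drawn uniformly per SNP; must lie in `(0, 0.5]`.
#' @param decay AR(1) correlation parameter `r` in `[0, 1)`; `decay = 0`
#'   gives an LD-free (identity) panel. May be a vector parallel to
#'   `block_size`.
#' @param seed integer seed for MAF/allele draws.
#' @return An object of class `ld_panel`: list with `snp` (ids), `chr`,
#'   `bp`, `A1`, `A2`, `maf`, `ldscore`, `blocks` (list of correlation
#'   matrices), `block_index` (list of SNP index vectors), `n_snps`.
#' @export
build_ld_panel <- function(n_snps, block_size, maf_range = c(0.05, 0.5),
                           decay = 0.6, seed = 1L) {
  stopifnot(n_snps >= 1, all(block_size >= 1))
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair inside (0, 0.5]")
  }
  if (any(decay < 0) || any(decay >= 1)) stop("decay must be in [0, 1)")
  if (length(decay) == 1L) decay <- rep(decay, length(block_size))
  stopifnot(length(decay) == length(block_size))

  block_index <- list(); block_decay <- numeric(0)
  s <- 1L; k <- 0L
  while (s <= n_snps) {
    k <- k + 1L
    j <- (k - 1L) %% length(block_size) + 1L
    end <- min(s + as.integer(block_size[j]) - 1L, n_snps)
    block_index[[k]] <- s:end
    block_decay[k] <- decay[j]
    s <- end + 1L
  }
  blocks <- lapply(seq_along(block_index), function(b)
    .ar1_block(length(block_index[[b]]), block_decay[b]))

  ldscore <- unlist(lapply(blocks, function(B) rowSums(B^2)), use.names = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  # unambiguous allele pairs only (no A/T or C/G), so harmonization keeps all
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, n_snps, replace = TRUE)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  structure(list(
    snp = sprintf("rs%06d", seq_len(n_snps)),
    chr = rep(1L, n_snps),
    bp = seq_len(n_snps) * 1000L,
    A1 = pairs[pick, 1],
    A2 = pairs[pick, 2],
    maf = maf,
    ldscore = ldscore,
    blocks = blocks,
    block_index = block_index,
    n_snps = n_snps
  ), class = "ld_panel")
}

# AR(1) correlation matrix with positive-definiteness guard: jitter the
# diagonal and renormalize on (numerically impossible for |r|<1, but kept
# as a defensive path per contract) failure, at most 5 attempts.
.ar1_block <- function(p, r) {
  B <- r^abs(outer(seq_len(p), seq_len(p), "-"))
  B <- (B + t(B)) / 2
  for (attempt in 1:5) {
    ok <- tryCatch({ chol(B); TRUE }, error = function(e) FALSE)
    if (ok) return(B)
    B <- B + diag(1e-8 * 10^attempt, p)
    B <- stats::cov2cor(B)
  }
  stop("failed to construct a positive-definite LD block after 5 attempts")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d SNPs in %d blocks (max block %d), mean LD score %.2f\n",
              x$n_snps, length(x$blocks), max(lengths(x$block_index)),
              mean(x$ldscore)))
  invisible(x)
}

#' Cholesky factors of the panel blocks (cached helper)
#' @noRd
.panel_chol <- function(panel) lapply(panel$blocks, chol)
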