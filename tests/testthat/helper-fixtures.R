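# Shared fixtures. All stochastic tests draw from named substreams of one
# master seed so each test's data is reproducible and independent of test
# execution order.
MASTER_SEED <- 20240826L

test_seed <- function(name) substream_seed(MASTER_SEED, name)

# mixed low/high-LD panel: interleaves independent SNPs with AR(0.85)
# blocks of 8, giving LD scores spread over ~[1, 4.5] so the LDSC
# intercept is well identified
validation_panel <- function(M, seed = 5L) {
  build_ld_panel(M, block_size = c(1L, 1L, 1L, 1L, 8L),
                 decay = c(0, 0, 0, 0, 0.85), seed = seed)
}

# data matrix whose sample correlation equals `target` exactly (whiten,
# then color): turns parameter-recovery checks into deterministic oracles
exact_corr_data <- function(n, target, seed = 1L) {
  set.seed(seed)
  p <- ncol(target)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- scale(X, scale = FALSE)
  Xw <- X %*% t(chol(solve(stats::cov(X))))
  Xw %*% chol(target)
}

# minimal genotype_set-compatible object for scoring tests
fake_genotypes <- function(dosage, A1, A2, maf = rep(0.3, ncol(dosage))) {
  n <- nrow(dosage)
  list(dosage = dosage,
       info = data.frame(id = paste0("i", seq_len(n)),
                         family_id = paste0("f", rep(seq_len(ceiling(n / 2)),
                                                     each = 2))[seq_len(n)],
                         member = rep(1:2, length.out = n),
                         zygosity = "DZ", role = "offspring",
                         stringsAsFactors = FALSE),
       panel = list(snp = paste0("s", seq_len(ncol(dosage))),
                    A1 = A1, A2 = A2, maf = maf))
}

# absolute-error expectation (testthat tolerances are relative)
expect_within <- function(actual, expected, tol) {
  expect_lt(max(abs(unname(actual) - unname(expected))), tol)
}

# implied twin-pair covariance matrices for Cholesky path matrices
implied_twin_cov <- function(L_A, L_C, L_E) {
  A <- tcrossprod(L_A); C <- tcrossprod(L_C); E <- tcrossprod(L_E)
  W <- A + C + E
  list(MZ = rbind(cbind(W, A + C), cbind(A + C, W)),
       DZ = rbind(cbind(W, 0.5 * A + C), cbind(0.5 * A + C, W)))
}
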