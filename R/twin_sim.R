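#' Simulate univariate twin-pair data under an exact ACE model
#'
#' Direct generative draws from the classical twin model: the additive
#' genetic deviations of co-twins correlate 1 (MZ) or 0.5 (DZ), the shared
#' environment correlates 1, the non-shared environment 0. Used to validate
#' the twin-model estimators under known truth; the genotype-based cohort
#' simulator realizes the same structure through actual Mendelian
#' transmission.
#'
#' @param n_mz,n_dz numbers of pairs.
#' @param a2,c2,e2 variance shares (must sum to 1).
#' @param seed integer seed.
#' @return A `twin_pairs` data frame: `family_id`, `zygosity`, `t_1`, `t_2`
#'   (the [pair_traits()] column convention, trait name `t`).
#' @export
simulate_twin_pairs <- function(n_mz, n_dz, a2, c2, e2, seed = 1L) {
  stopifnot(abs(a2 + c2 + e2 - 1) < 1e-9, a2 >= 0, c2 >= 0, e2 >= 0)
  mv <- simulate_twin_pairs_mv(n_mz, n_dz,
                               L_A = matrix(sqrt(a2)),
                               L_C = matrix(sqrt(c2)),
                               L_E = matrix(sqrt(e2)),
                               traits = "t", seed = seed)
  attr(mv, "traits") <- "t"
  mv
}

#' Simulate multivariate twin-pair data from Cholesky path matrices
#'
#' Traits for each twin are `L_A %*% A + L_C %*% C + L_E %*% E` with
#' independent standard-normal factor vectors; across co-twins the A factors
#' correlate 1 (MZ) / 0.5 (DZ), C factors correlate 1, E factors 0. Row `i`
#' of the result holds twin-1 and twin-2 values of each trait
#' (`<trait>_1`, `<trait>_2`).
#'
#' @param n_mz,n_dz numbers of pairs.
#' @param L_A,L_C,L_E `p x p` (lower-triangular) path matrices.
#' @param traits trait names (default `tr1..trp`).
#' @param seed integer seed.
#' @return Data frame with `family_id`, `zygosity` and `2p` trait columns.
#' @export
simulate_twin_pairs_mv <- function(n_mz, n_dz, L_A, L_C, L_E,
                                   traits = NULL, seed = 1L) {
  p <- nrow(L_A)
  stopifnot(all(dim(L_A) == p), all(dim(L_C) == p), all(dim(L_E) == p))
  if (is.null(traits)) traits <- paste0("tr", seq_len(p))
  n <- n_mz + n_dz
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  rA <- ifelse(zyg == "MZ", 1, 0.5)

  draw <- function(k) matrix(stats::rnorm(n * k), n, k)
  A_shared <- draw(p); A_sp1 <- draw(p); A_sp2 <- draw(p)
  A1 <- sqrt(rA) * A_shared + sqrt(1 - rA) * A_sp1
  A2 <- sqrt(rA) * A_shared + sqrt(1 - rA) * A_sp2
  C <- draw(p)
  E1 <- draw(p); E2 <- draw(p)

  T1 <- A1 %*% t(L_A) + C %*% t(L_C) + E1 %*% t(L_E)
  T2 <- A2 %*% t(L_A) + C %*% t(L_C) + E2 %*% t(L_E)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  out <- data.frame(family_id = sprintf("fam%05d", seq_len(n)),
                    zygosity = zyg, stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    out[[paste0(traits[j], "_1")]] <- T1[, j]
    out[[paste0(traits[j], "_2")]] <- T2[, j]
  }
  attr(out, "traits") <- traits
  out
}
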