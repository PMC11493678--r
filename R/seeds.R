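#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' Every stochastic stage of the package draws its randomness from a named
#' substream of a single master seed, so that adding or re-ordering stages
#' never perturbs the draws of another stage. The substream seed is a
#' deterministic 31-bit hash of the master seed and the stream name.
#'
#' @param master integer master seed.
#' @param name character scalar naming the substream (e.g. `"genotypes"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(20240826, "panel")
substream_seed <- function(master, name) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(name), length(name) == 1L)
  mod <- 2147483629  # largest prime below 2^31
  h <- as.double(master) %% mod
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% mod
  as.integer(h %% (mod - 2) + 1)
}

#' Evaluate an expression under a named substream of a master seed
#'
#' Saves and restores the caller's RNG state, so substream draws do not
#' interfere with the ambient random stream.
#'
#' @param master integer master seed.
#' @param name substream name.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, name))
  expr
}
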