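#' Write / read a twin cohort phenotype table
#'
#' The observed surface of a [simulate_phenotypes()] cohort is persisted as
#' a single CSV, one row per family x member x age x rater (the external
#' interface of the phenotype file). The hidden truth table is not written;
#' round-tripping therefore yields a cohort whose `data` slot is identical
#' and whose `truth` slot is `NULL`.
#'
#' @param cohort a `twin_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  utils::write.csv(cohort$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param check_names required-column check (mandatory columns
#'   `family_id`, `member`, `zygosity`, `age`).
#' @export
read_cohort <- function(path, check_names = TRUE) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                                 conditionMessage(e))))
  if (check_names) {
    need <- c("family_id", "member", "zygosity", "age")
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      stop(sprintf("phenotype file '%s' is missing required column(s): %s",
                   path, paste(miss, collapse = ", ")))
    }
  }
  ages <- sort(unique(d$age))
  structure(list(data = d, truth = NULL, ages = ages, config = NULL),
            class = "twin_cohort")
}

#' Write / read GWAS summary statistics (LDSC-style TSV dialect)
#'
#' One TSV per trait with header `SNP CHR BP A1 A2 MAF N Z`; alleles
#' uppercase. On read, a file carrying `BETA` and `SE` instead of `Z` is
#' converted via `Z = BETA / SE`. Malformed files raise parse errors that
#' name the offending column or line.
#'
#' @param ss a `sumstats_set` (or a single trait data frame).
#' @param dir output directory (one `<trait>.sumstats.tsv` per trait), or a
#'   file path when `ss` is a single data frame.
#' @return Written paths, invisibly.
#' @export
write_sumstats <- function(ss, dir) {
  if (is.data.frame(ss)) {
    utils::write.table(ss, dir, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(dir))
  }
  stopifnot(inherits(ss, "sumstats_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(ss$traits), function(tr) {
    p <- file.path(dir, paste0(tr, ".sumstats.tsv"))
    utils::write.table(ss$traits[[tr]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_sumstats
#' @param paths named character vector of per-trait TSV paths (names become
#'   trait names; unnamed paths use the file stem).
#' @export
read_sumstats <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    names(paths) <- sub("\\.sumstats\\.tsv$", "", basename(paths))
  }
  traits <- lapply(seq_along(paths), function(i) .read_one_sumstats(paths[i]))
  names(traits) <- names(paths)
  snp <- traits[[1]]$SNP
  for (tr in names(traits)) {
    if (!identical(traits[[tr]]$SNP, snp)) {
      stop(sprintf("trait '%s' does not share the SNP map of '%s'",
                   tr, names(traits)[1]))
    }
  }
  structure(list(traits = traits, snp = snp), class = "sumstats_set")
}

.read_one_sumstats <- function(path) {
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) {
      msg <- conditionMessage(e)
      ln <- regmatches(msg, regexpr("line [0-9]+", msg))
      stop(sprintf("cannot parse sumstats '%s'%s: %s", path,
                   if (length(ln)) paste0(" (", ln, ")") else "", msg))
    })
  if (!("Z" %in% names(d)) && all(c("BETA", "SE") %in% names(d))) {
    if (any(d$SE <= 0, na.rm = TRUE)) {
      stop(sprintf("sumstats '%s': SE must be positive to form Z = BETA/SE", path))
    }
    d$Z <- d$BETA / d$SE
  }
  need <- c("SNP", "CHR", "BP", "A1", "A2", "MAF", "N", "Z")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("sumstats '%s' is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(d$Z))
  if (length(bad)) {
    stop(sprintf("sumstats '%s': non-finite Z at line %d", path, bad[1] + 1L))
  }
  if (any(d$N <= 0)) stop(sprintf("sumstats '%s': N must be positive", path))
  d$A1 <- toupper(d$A1); d$A2 <- toupper(d$A2)
  d[need]
}

#' Export an LD panel as plain-text tables
#'
#' Writes the SNP map with LD scores (`<stem>.snps.tsv`) and the non-zero
#' within-block correlations in long format (`<stem>.ld.tsv`: block, i, j,
#' r). `read_panel_snps()` reads the SNP table back (sufficient for LDSC;
#' full block reconstruction is supported via the long table).
#'
#' @param panel an `ld_panel`.
#' @param stem output path stem.
#' @return Written paths, invisibly.
#' @export
write_panel <- function(panel, stem) {
  stopifnot(inherits(panel, "ld_panel"))
  snps <- data.frame(SNP = panel$snp, CHR = panel$chr, BP = panel$bp,
                     A1 = panel$A1, A2 = panel$A2, MAF = panel$maf,
                     L2 = panel$ldscore,
                     BLOCK = rep(seq_along(panel$block_index),
                                 lengths(panel$block_index)))
  p1 <- paste0(stem, ".snps.tsv")
  utils::write.table(snps, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  ld <- do.call(rbind, lapply(seq_along(panel$blocks), function(b) {
    B <- panel$blocks[[b]]
    ut <- which(upper.tri(B, diag = TRUE), arr.ind = TRUE)
    data.frame(BLOCK = b, I = ut[, 1], J = ut[, 2], R = B[ut])
  }))
  p2 <- paste0(stem, ".ld.tsv")
  utils::write.table(ld, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_panel
#' @export
read_panel_snps <- function(stem) {
  utils::read.table(paste0(stem, ".snps.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
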