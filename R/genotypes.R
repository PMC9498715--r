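#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds a samples-by-SNPs matrix of ALT-allele dosages
#' (0, 1, 2, or `NA` for a missing call) together with per-SNP allele
#' frequencies. It is the input to [filter_snps_maf()] and [compute_grm()].
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param sample_ids,snp_ids Optional character vectors; default to the
#'   dimnames of `dosages` or generated ids.
#'
#' @return A `genotype_matrix`: the dosage matrix with row/column names set
#'   and an `allele_freqs` attribute (ALT-allele frequency per SNP, computed
#'   from non-missing dosages).
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(dosages)), arr.ind = TRUE)[1, ]
    stop_holo(sprintf(
      "dosage value %s at sample row %d, SNP column %d is not 0/1/2/NA",
      format(dosages[idx[1], idx[2]]), idx[1], idx[2]
    ), "holopred_invalid_dosage")
  }
  sample_ids <- sample_ids %||% rownames(dosages) %||%
    sprintf("S%03d", seq_len(nrow(dosages)))
  snp_ids <- snp_ids %||% colnames(dosages) %||%
    sprintf("snp%05d", seq_len(ncol(dosages)))
  if (anyDuplicated(sample_ids)) {
    stop_holo(sprintf("duplicate sample id: %s",
                      sample_ids[duplicated(sample_ids)][1]))
  }
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(dosages,
            allele_freqs = allele_frequencies(dosages),
            class = c("genotype_matrix", "matrix", "array"))
}

# ALT-allele frequency per SNP from non-missing dosages
allele_frequencies <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, %d missing calls\n",
              nrow(x), ncol(x), sum(is.na(x))))
  p <- attr(x, "allele_freqs")
  cat(sprintf("  ALT-allele frequency range: %.3f-%.3f\n",
              min(p), max(p)))
  invisible(x)
}

#' Filter SNPs by minor allele frequency
#'
#' Keeps SNPs whose minor allele frequency, `min(p, 1 - p)` with `p` the
#' ALT-allele frequency computed from the non-missing dosages, is at least
#' `threshold`. Column order is preserved and frequencies are recomputed on
#' the retained set.
#'
#' @param g A [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`; the usual array-QC value
#'   is 0.01.
#' @return A `genotype_matrix` with the retained SNPs.
#' @export
filter_snps_maf <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (threshold < 0 || threshold > 0.5) {
    stop_holo("`threshold` must lie in [0, 0.5]")
  }
  p <- allele_frequencies(unclass(g))
  maf <- pmin(p, 1 - p)
  keep <- maf >= threshold
  if (!any(keep)) {
    stop_holo(sprintf(
      "MAF filter at %.4g removed all %d SNPs", threshold, ncol(g)
    ), "holopred_empty_filter")
  }
  genotype_matrix(unclass(g)[, keep, drop = FALSE])
}

#' Impute missing dosages to their SNP mean
#'
#' Missing calls are replaced by `2 * p_m`, the expected dosage under the
#' observed ALT-allele frequency of that SNP — the standard mean imputation
#' compatible with VanRaden centring.
#'
#' @param g A [genotype_matrix()].
#' @return A numeric matrix (no longer constrained to 0/1/2) with the same
#'   dimnames.
#' @export
impute_dosages <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  z <- unclass(g)
  if (anyNA(z)) {
    p2 <- 2 * allele_frequencies(z)
    idx <- which(is.na(z), arr.ind = TRUE)
    z[idx] <- p2[idx[, 2]]
  }
  z
}
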