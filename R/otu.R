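#' Construct an OTU table
#'
#' A samples-by-OTUs matrix of either raw sequence counts (non-negative
#' integers) or relative abundances (rows summing to 1). It is the input to
#' [filter_otus_prevalence()] and [compute_mrm()].
#'
#' @param counts Numeric matrix, samples in rows, OTUs in columns.
#' @param sample_ids,otu_ids Optional ids; default to dimnames.
#' @param is_relative Logical; `TRUE` if the matrix already holds per-sample
#'   relative abundances (each row summing to 1 within 1e-8).
#' @return An `otu_table` matrix with an `is_relative` attribute.
#' @export
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL,
                      is_relative = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop_holo("OTU table must be non-negative with no missing values")
  }
  if (is_relative) {
    rs <- rowSums(counts)
    if (any(abs(rs - 1) > 1e-8)) {
      stop_holo(sprintf(
        "declared relative but row %d sums to %.6g, not 1",
        which(abs(rs - 1) > 1e-8)[1], rs[which(abs(rs - 1) > 1e-8)[1]]
      ))
    }
  }
  sample_ids <- sample_ids %||% rownames(counts) %||%
    sprintf("S%03d", seq_len(nrow(counts)))
  otu_ids <- otu_ids %||% colnames(counts) %||%
    sprintf("OTU%04d", seq_len(ncol(counts)))
  if (anyDuplicated(sample_ids)) {
    stop_holo(sprintf("duplicate sample id: %s",
                      sample_ids[duplicated(sample_ids)][1]))
  }
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(counts, is_relative = isTRUE(is_relative),
            class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs (%s)\n", nrow(x), ncol(x),
              if (attr(x, "is_relative")) "relative abundances" else "counts"))
  invisible(x)
}

#' Filter OTUs by prevalence
#'
#' Retains OTUs observed (nonzero) in at least `min_fraction` of the
#' samples. The usual holo-omic pre-filter keeps OTUs present in at least
#' 20% of animals.
#'
#' @param t An [otu_table()].
#' @param min_fraction Required fraction of samples with a nonzero entry,
#'   in `[0, 1]`; the comparison is `>=`.
#' @return An `otu_table` with the retained OTUs, original order preserved.
#' @export
filter_otus_prevalence <- function(t, min_fraction = 0.2) {
  stopifnot(inherits(t, "otu_table"))
  if (min_fraction < 0 || min_fraction > 1) {
    stop_holo("`min_fraction` must lie in [0, 1]")
  }
  prev <- colMeans(unclass(t) > 0)
  keep <- prev >= min_fraction
  if (!any(keep)) {
    stop_holo(sprintf(
      "prevalence filter at %.3g removed all %d OTUs", min_fraction, ncol(t)
    ), "holopred_empty_filter")
  }
  otu_table(unclass(t)[, keep, drop = FALSE],
            is_relative = attr(t, "is_relative"))
}

#' Convert an OTU table to relative abundances
#'
#' @param t An [otu_table()].
#' @return An `otu_table` with `is_relative = TRUE`; rows sum to 1.
#' @export
relative_abundance <- function(t) {
  stopifnot(inherits(t, "otu_table"))
  m <- unclass(t)
  if (attr(t, "is_relative")) return(t)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop_holo(sprintf("sample %s has zero total count",
                      rownames(m)[which(rs == 0)[1]]))
  }
  otu_table(m / rs, is_relative = TRUE)
}
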