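#' Read and write genotype dosage tables
#'
#' Tab-separated text: header row of SNP ids, first column of sample ids,
#' cells 0/1/2 or `NA`.
#'
#' @param path File path.
#' @return `read_genotypes()` returns a [genotype_matrix()];
#'   `write_genotypes()` returns `path` invisibly.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_holo(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!(m %in% c(0, 1, 2) | is.na(m)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(m))
    stop_holo(sprintf(
      "invalid dosage '%s' at sample '%s', SNP '%s' in %s",
      format(m[idx]), ids[idx[1]], colnames(m)[idx[2]], path),
      "holopred_invalid_dosage")
  }
  rownames(m) <- ids
  genotype_matrix(m)
}

#' @rdname read_genotypes
#' @param g A [genotype_matrix()].
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(sample_id = rownames(g), unclass(g), check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Converts the `GT` field of a VCF 4.x file into ALT-allele dosages
#' (0/1/2, `NA` for missing calls). Requires the `vcfR` package. Sites
#' must be biallelic.
#'
#' @param path Path to a (possibly gzipped) VCF file.
#' @return A [genotype_matrix()] with samples in rows and sites
#'   (`CHROM:POS` or the `ID` column when present) in columns.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_holo("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(x, "[/|]")[[1]]))
  })
  ids <- vcfR::getID(v)
  site <- ifelse(is.na(ids) | ids == ".",
                 paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v)), ids)
  m <- t(dos)
  colnames(m) <- site
  genotype_matrix(m)
}

#' Read and write OTU tables
#'
#' Tab-separated text: header row of OTU ids, first column of sample ids,
#' non-negative cells. Whether the table holds counts or relative
#' abundances is auto-detected: every row summing to 1 (within 1e-6) means
#' relative abundances; all-integer cells mean counts; anything else is
#' ambiguous and an error.
#'
#' @param path File path.
#' @return `read_otu_table()` returns an [otu_table()];
#'   `write_otu_table()` returns `path` invisibly.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop_holo(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0)) {
    stop_holo(sprintf("OTU table %s has negative or missing values", path))
  }
  rownames(m) <- ids
  rs <- rowSums(m)
  if (all(abs(rs - 1) < 1e-6)) {
    return(otu_table(m / rs, is_relative = TRUE))
  }
  if (all(abs(m - round(m)) < 1e-9)) {
    return(otu_table(m, is_relative = FALSE))
  }
  stop_holo(sprintf(
    "OTU table %s is ambiguous: non-integer values but rows do not all sum to 1",
    path))
}

#' @rdname read_otu_table
#' @param t An [otu_table()].
#' @export
write_otu_table <- function(t, path) {
  stopifnot(inherits(t, "otu_table"))
  df <- data.frame(sample_id = rownames(t), unclass(t), check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Comma-separated text with a `sample_id` column (or any first column of
#' ids), one or more trait columns (`NA` marks phenotypes to predict), and
#' optional covariate columns: numeric columns are treated downstream as
#' fixed covariates, character columns as class effects.
#'
#' @param path File path.
#' @return A tibble whose first column is `sample_id`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_holo(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop_holo(sprintf("duplicate sample id in %s: %s", path,
                      df$sample_id[duplicated(df$sample_id)][1]))
  }
  df
}
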