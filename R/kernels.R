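#' Sample-by-sample covariance kernels
#'
#' A `holo_kernel` is a named symmetric n-by-n similarity matrix over the
#' same set of samples: the genomic relationship matrix (`"GRM"`), the
#' microbial relationship matrix (`"MRM"`), their Hadamard interaction
#' (`"HADAMARD"`), or the symmetrised Cholesky cross-product used to model
#' covariance between the genomic and microbial random effects (`"CORE"`).
#' GRM, MRM and Hadamard kernels are positive semidefinite; a CORE kernel
#' may be indefinite, and its smallest eigenvalue is recorded.
#'
#' @param matrix Symmetric numeric matrix with sample ids as dimnames.
#' @param kind One of `"GRM"`, `"MRM"`, `"HADAMARD"`, `"CORE"`.
#' @param min_eigenvalue Optional known smallest eigenvalue.
#' @return A `holo_kernel` object.
#' @export
holo_kernel <- function(matrix, kind = c("GRM", "MRM", "HADAMARD", "CORE"),
                        min_eigenvalue = NULL) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop_holo("kernel has non-finite entries")
  if (nrow(matrix) != ncol(matrix) ||
      max(abs(matrix - t(matrix))) > 1e-10) {
    stop_holo("kernel must be square and symmetric within 1e-10")
  }
  matrix <- (matrix + t(matrix)) / 2
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- colnames(matrix) <- sprintf("S%03d", seq_len(nrow(matrix)))
  }
  colnames(matrix) <- rownames(matrix)
  structure(matrix,
            kind = kind,
            diag_mean = mean(diag(matrix)),
            min_eigenvalue = min_eigenvalue,
            class = c("holo_kernel", "matrix", "array"))
}

kernel_ids <- function(k) rownames(k)

#' @export
print.holo_kernel <- function(x, ...) {
  cat(sprintf("<holo_kernel %s> %d x %d, mean diagonal %.4f\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "diag_mean")))
  if (!is.null(attr(x, "min_eigenvalue"))) {
    cat(sprintf("  smallest eigenvalue: %.3e\n", attr(x, "min_eigenvalue")))
  }
  invisible(x)
}

check_aligned <- function(a, b, what = "kernels") {
  if (!identical(dim(a), dim(b))) {
    stop_holo(sprintf("%s differ in shape: %dx%d vs %dx%d", what,
                      nrow(a), ncol(a), nrow(b), ncol(b)))
  }
  ia <- rownames(a); ib <- rownames(b)
  if (!identical(ia, ib)) {
    first <- which(ia != ib)[1]
    stop_holo(sprintf("sample ids differ (first mismatch at %d: '%s' vs '%s')",
                      first, ia[first], ib[first]))
  }
  invisible(TRUE)
}

#' Genomic relationship matrix (VanRaden)
#'
#' Computes the additive genomic relationship matrix
#' \deqn{G = \frac{(Z - 2Q)(Z - 2Q)^\top}{\sum_m 2 p_m (1 - p_m)}}
#' where `Z` is the samples-by-SNPs dosage matrix and column `m` of `2Q` is
#' the constant `2 p_m`, the expected dosage under the ALT-allele frequency
#' `p_m`. With frequencies estimated from the sample itself the centred
#' matrix has zero column sums, so every row of `G` sums to zero.
#'
#' @param g A [genotype_matrix()]; no monomorphic SNPs allowed (they make
#'   no contribution to the numerator but would still be counted — remove
#'   them with [filter_snps_maf()]).
#' @param impute If `TRUE` (default) missing dosages are mean-imputed to
#'   `2 p_m` first; if `FALSE`, missing dosages are an error.
#' @param freqs Optional externally supplied allele frequencies (e.g. from
#'   a reference population); defaults to frequencies of the sample.
#' @return A `holo_kernel` of kind `"GRM"`.
#' @export
compute_grm <- function(g, impute = TRUE, freqs = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(unclass(g)) && !impute) {
    stop_holo("missing dosages present and `impute = FALSE`")
  }
  z <- impute_dosages(g)
  p <- freqs %||% allele_frequencies(z)
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop_holo(sprintf("monomorphic SNP present: %s (p = %g)",
                      colnames(z)[which(mono)[1]], p[which(mono)[1]]),
              "holopred_monomorphic")
  }
  zc <- sweep(z, 2, 2 * p)
  denom <- sum(2 * p * (1 - p))
  holo_kernel(tcrossprod(zc) / denom, kind = "GRM")
}

#' Microbial relationship matrix
#'
#' Builds the microbial relationship matrix \eqn{M = R R^\top / q} from an
#' OTU table: counts are converted to per-sample relative abundances, zeros
#' are replaced by half the smallest nonzero relative abundance of the whole
#' table, abundances are log-transformed, and each OTU column is centred and
#' scaled to unit variance before the cross-product over the `q` retained
#' OTUs. OTU columns with zero variance after the transform carry no
#' information and are dropped with a warning.
#'
#' @param t An [otu_table()] (counts or relative abundances).
#' @return A `holo_kernel` of kind `"MRM"`.
#' @export
compute_mrm <- function(t) {
  stopifnot(inherits(t, "otu_table"))
  ra <- unclass(relative_abundance(t))
  nz <- ra[ra > 0]
  if (length(nz) == 0) stop_holo("OTU table is all zero")
  ra[ra == 0] <- min(nz) / 2
  r <- log(ra)
  v <- apply(r, 2, var)
  drop <- v <= .Machine$double.eps * 100
  if (any(drop)) {
    warn(sprintf("dropping %d zero-variance OTU column(s) after log transform (first: %s)",
                 sum(drop), colnames(r)[which(drop)[1]]))
    r <- r[, !drop, drop = FALSE]
  }
  if (ncol(r) < 2) {
    stop_holo("fewer than 2 OTUs with positive variance after log transform")
  }
  r <- scale(r)
  holo_kernel(tcrossprod(r) / ncol(r), kind = "MRM")
}

#' Hadamard (entry-wise) interaction kernel
#'
#' The genome-by-microbiome interaction kernel `K[i, j] = G[i, j] * M[i, j]`.
#' By the Schur product theorem the entry-wise product of two positive
#' semidefinite kernels is positive semidefinite.
#'
#' @param g,m Two [holo_kernel()]s over the same samples in the same order.
#' @return A `holo_kernel` of kind `"HADAMARD"`.
#' @export
hadamard_kernel <- function(g, m) {
  stopifnot(inherits(g, "holo_kernel"), inherits(m, "holo_kernel"))
  check_aligned(g, m)
  holo_kernel(unclass(g) * unclass(m), kind = "HADAMARD")
}

#' Cholesky cross-product interaction kernel
#'
#' Models the covariance between the genomic and microbial random effects:
#' with `L_G`, `L_M` the lower Cholesky factors of `G` and `M`, the kernel
#' is the symmetrised cross-product
#' \deqn{K = \tfrac12 (L_G L_M^\top + L_M L_G^\top).}
#' The half keeps `core_greml_kernel(G, G) = G`. Unlike the other kernels
#' `K` may be indefinite; its smallest eigenvalue is recorded on the result.
#' If a factorisation fails numerically, a ridge `eps * I` is added with
#' `eps` growing tenfold from 1e-10 to 1e-6 before giving up.
#'
#' @param g,m Two positive semidefinite [holo_kernel()]s over the same
#'   samples in the same order.
#' @return A `holo_kernel` of kind `"CORE"`.
#' @export
core_greml_kernel <- function(g, m) {
  stopifnot(inherits(g, "holo_kernel"), inherits(m, "holo_kernel"))
  check_aligned(g, m)
  lg <- ridged_cholesky(unclass(g), "first kernel")
  lm_ <- ridged_cholesky(unclass(m), "second kernel")
  k <- (tcrossprod(lg, lm_) + tcrossprod(lm_, lg)) / 2
  k <- (k + t(k)) / 2
  dimnames(k) <- dimnames(g)
  holo_kernel(k, kind = "CORE",
              min_eigenvalue = min(eigen(k, symmetric = TRUE,
                                         only.values = TRUE)$values))
}

# lower Cholesky with a deterministic, logged ridge escalation
ridged_cholesky <- function(a, label) {
  eps_seq <- c(0, 10 ^ seq(-10, -6))
  for (eps in eps_seq) {
    ak <- a + diag(eps, nrow(a))
    l <- tryCatch(t(chol(ak)), error = function(e) NULL)
    if (!is.null(l)) {
      if (eps > 0) {
        inform(sprintf("Cholesky of %s needed ridge %.0e", label, eps))
      }
      return(l)
    }
  }
  ev <- min(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  stop_holo(sprintf(
    "Cholesky of %s failed even with ridge 1e-6 (smallest eigenvalue %.3e)",
    label, ev
  ), "holopred_cholesky")
}

#' Normalise a kernel to mean diagonal one
#'
#' Divides the kernel by its mean diagonal so that variance components
#' attached to different kernels are on a comparable scale. Eigenvector
#' directions are unchanged; eigenvalues are scaled by `1 / diag_mean`.
#'
#' @param k A [holo_kernel()] with nonzero mean diagonal.
#' @return A `holo_kernel` with `diag_mean` 1 (within 1e-10).
#' @export
normalise_kernel <- function(k) {
  stopifnot(inherits(k, "holo_kernel"))
  dm <- mean(diag(k))
  if (abs(dm) < 1e-14) stop_holo("kernel mean diagonal is zero")
  me <- attr(k, "min_eigenvalue")
  holo_kernel(unclass(k) / dm, kind = attr(k, "kind"),
              min_eigenvalue = if (!is.null(me)) me / dm)
}

#' Check a kernel for positive semidefiniteness
#'
#' @param k A [holo_kernel()].
#' @param tol Relative tolerance: PSD means the smallest eigenvalue is at
#'   least `-tol` times the largest.
#' @return `TRUE`/`FALSE`, with the smallest eigenvalue as attribute
#'   `"min_eigenvalue"`.
#' @export
is_psd <- function(k, tol = 1e-8) {
  ev <- eigen(unclass(k), symmetric = TRUE, only.values = TRUE)$values
  structure(min(ev) >= -tol * max(abs(ev)), min_eigenvalue = min(ev))
}

#' Write / read a kernel as TSV
#'
#' Square tab-separated matrix with a header row and a first column of
#' sample ids, full matrix, 12 significant digits.
#'
#' @param k A [holo_kernel()].
#' @param path File path.
#' @param kind Kernel kind to stamp on a kernel read back in.
#' @return `write_kernel` returns `path` invisibly; `read_kernel` a
#'   `holo_kernel`.
#' @export
write_kernel <- function(k, path) {
  stopifnot(inherits(k, "holo_kernel"))
  df <- data.frame(sample_id = rownames(k),
                   signif(unclass(k), 12), check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path, kind = "GRM") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- as.character(df[[1]])
  # symmetry can be off in the last digit after text round-trip
  m <- (m + t(m)) / 2
  holo_kernel(m, kind = kind)
}
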