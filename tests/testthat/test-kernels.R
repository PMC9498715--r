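test_that("MAF filter keeps exactly the SNPs above threshold, with hand-counted frequencies", {
  g <- toy_genotypes()
  # direct allele count oracle
  p <- colSums(unclass(g)) / (2 * nrow(g))
  expect_equal(unname(p), c(0.5, 1 / 12, 0))

  kept <- filter_snps_maf(g, 0.01)
  expect_identical(colnames(kept), c("snpA", "snpB"))

  # threshold 0 is the identity
  expect_equal(unclass(filter_snps_maf(g, 0)), unclass(g))

  # monomorphic SNP removed at any positive threshold
  expect_false("snpC" %in% colnames(filter_snps_maf(g, 0.001)))

  # removing everything is an error, not an empty object
  rare <- genotype_matrix(unclass(g)[, c("snpB", "snpC")])
  expect_error(filter_snps_maf(rare, 0.2), "removed all")
  expect_error(filter_snps_maf(g, 0.7), "\\[0, 0.5\\]")
})

test_that("prevalence filter retains OTUs by column-wise nonzero count", {
  counts <- matrix(0, 10, 3, dimnames = list(paste0("S", 1:10),
                                             c("A", "B", "C")))
  counts[1:2, "A"] <- 5   # prevalence 0.2
  counts[1, "B"] <- 3     # prevalence 0.1
  counts[, "C"] <- 1      # prevalence 1
  t <- otu_table(counts)

  kept <- filter_otus_prevalence(t, 0.2)
  expect_identical(colnames(kept), c("A", "C"))

  expect_equal(unclass(filter_otus_prevalence(t, 0)), unclass(t))
  rare <- otu_table(counts[, c("A", "B")])
  expect_error(filter_otus_prevalence(rare, 0.5), "removed all")
})

test_that("VanRaden GRM matches the naive double-loop oracle", {
  z <- matrix(c(0, 2, 1, 1, 2, 0), 3, 2, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), c("m1", "m2")))
  g <- compute_grm(genotype_matrix(z))
  expect_equal(unclass(g), oracle_grm(z), ignore_attr = TRUE,
               tolerance = 1e-12)

  # centring identity: sample-frequency GRM has zero row sums
  expect_lt(max(abs(rowSums(g))), 1e-12)

  # random dosage matrices up to 8x8 agree with the oracle
  for (n in c(4, 6, 8)) {
    set.seed(n)
    z <- matrix(rbinom(n * 8, 2, runif(8, 0.2, 0.8)[rep(1:8, each = n)]),
                n, 8)
    z[, 1] <- c(0, 1, rep(1, n - 2))  # guarantee polymorphism
    gm <- genotype_matrix(z)
    keep <- pmin(attr(gm, "allele_freqs"), 1 - attr(gm, "allele_freqs")) > 0
    gm <- genotype_matrix(z[, keep, drop = FALSE])
    expect_equal(unclass(compute_grm(gm)),
                 oracle_grm(unclass(gm)), ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
})

test_that("GRM handles missingness by mean imputation and rejects degenerate input", {
  z <- matrix(c(0, 2, NA, 1, 2, 0), 3, 2,
              dimnames = list(paste0("S", 1:3), c("m1", "m2")))
  g <- genotype_matrix(z)
  expect_error(compute_grm(g, impute = FALSE), "impute")
  # imputation replaces NA by 2p of the observed dosages
  zi <- impute_dosages(g)
  expect_equal(zi[3, 1], 2 * (mean(c(0, 2)) / 2))  # 2p of the observed dosages
  expect_silent(compute_grm(g))

  mono <- genotype_matrix(matrix(c(2, 2, 2, 0, 1, 2), 3, 2,
                                 dimnames = list(NULL, c("bad", "ok"))))
  expect_error(compute_grm(mono), "bad")
})

test_that("MRM matches the step-by-step hand pipeline and is exchangeable", {
  counts <- matrix(c(10, 5, 2, 4, 8, 1), 3, 2,
                   dimnames = list(paste0("S", 1:3), c("o1", "o2")))
  m <- compute_mrm(otu_table(counts))
  expect_equal(unclass(m), oracle_mrm(counts), ignore_attr = TRUE,
               tolerance = 1e-12)

  # identical abundance profiles give identical rows/columns
  c2 <- rbind(S1 = c(6, 3, 1), S2 = c(12, 6, 2), S3 = c(1, 5, 9))
  colnames(c2) <- paste0("o", 1:3)
  m2 <- compute_mrm(otu_table(c2))  # S1 and S2 have the same composition
  expect_equal(m2[1, 1], m2[2, 2], tolerance = 1e-10)
  expect_equal(m2[1, 1], m2[1, 2], tolerance = 1e-10)

  # all-zero OTU columns are dropped with a warning
  c3 <- cbind(c2, dead = 0)
  expect_warning(m3 <- compute_mrm(otu_table(c3)), "zero-variance")
  expect_equal(unclass(m3), unclass(m2), ignore_attr = TRUE)

  # larger random tables agree with the oracle too
  set.seed(9)
  c4 <- matrix(rpois(8 * 6, 20), 8, 6)
  expect_equal(unclass(compute_mrm(otu_table(c4))), oracle_mrm(c4),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Hadamard kernel is the entry-wise product, commutative, and PSD for PSD inputs", {
  id <- holo_kernel(diag(4), "GRM")
  expect_equal(unclass(hadamard_kernel(id, holo_kernel(diag(4), "MRM"))),
               diag(4), ignore_attr = TRUE)

  G <- holo_kernel(random_psd(6, 1), "GRM")
  M <- holo_kernel(random_psd(6, 2), "MRM")
  K <- hadamard_kernel(G, M)
  expect_equal(unclass(K), oracle_hadamard(unclass(G), unclass(M)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(hadamard_kernel(M, G)), unclass(K),
               ignore_attr = TRUE)

  # Schur product theorem, checked by dense eigendecomposition
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)

  bad <- holo_kernel(random_psd(5, 3), "MRM")
  expect_error(hadamard_kernel(G, bad), "shape")
  M2 <- unclass(M)
  rownames(M2) <- colnames(M2) <- paste0("X", 1:6)
  expect_error(hadamard_kernel(G, holo_kernel(M2, "MRM")), "mismatch")
})

test_that("Cholesky cross-product kernel matches its oracle and has core(G, G) = G", {
  G <- holo_kernel(random_psd(4, 5), "GRM")
  M <- holo_kernel(random_psd(4, 6), "MRM")
  K <- core_greml_kernel(G, M)
  expect_equal(unclass(K), oracle_core(unclass(G), unclass(M)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_type(attr(K, "min_eigenvalue"), "double")

  # self-covariance identity, across several random PSD matrices
  for (s in 1:4) {
    Gs <- holo_kernel(random_psd(5 + s, 10 + s), "GRM")
    expect_equal(unclass(core_greml_kernel(Gs, Gs)), unclass(Gs),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }

  id <- holo_kernel(diag(4), "GRM")
  expect_equal(unclass(core_greml_kernel(id, holo_kernel(diag(4), "MRM"))),
               diag(4), ignore_attr = TRUE)
})

test_that("kernel normalisation rescales to unit mean diagonal without rotating eigenvectors", {
  k <- holo_kernel(2 * diag(3), "GRM")
  expect_equal(unclass(normalise_kernel(k)), diag(3), ignore_attr = TRUE)

  K <- holo_kernel(random_psd(6, 7), "MRM")
  Kn <- normalise_kernel(K)
  expect_equal(attr(Kn, "diag_mean"), 1, tolerance = 1e-10)
  # idempotence
  expect_equal(unclass(normalise_kernel(Kn)), unclass(Kn),
               tolerance = 1e-12, ignore_attr = TRUE)
  # eigenvalues scale by 1/diag_mean, eigenvectors unchanged
  e0 <- eigen(unclass(K), symmetric = TRUE)
  e1 <- eigen(unclass(Kn), symmetric = TRUE)
  expect_equal(e1$values, e0$values / attr(K, "diag_mean"), tolerance = 1e-10)
  expect_equal(abs(diag(crossprod(e0$vectors, e1$vectors))), rep(1, 6),
               tolerance = 1e-8)
})

test_that("every constructor preserves symmetry and sample ids", {
  sim <- quick_sim(n = 40, seed = 3)
  gk <- compute_grm(filter_snps_maf(sim$genotypes, 0.01))
  mk <- suppressWarnings(compute_mrm(sim$otus))
  hk <- hadamard_kernel(normalise_kernel(gk), normalise_kernel(mk))
  ck <- core_greml_kernel(normalise_kernel(gk), normalise_kernel(mk))
  for (k in list(gk, mk, hk, ck)) {
    expect_lt(max(abs(unclass(k) - t(unclass(k)))), 1e-10)
    expect_identical(rownames(k), rownames(sim$genotypes))
    expect_identical(rownames(k), colnames(k))
  }
})

test_that("kernels survive a TSV round trip at 12 significant digits", {
  k <- normalise_kernel(holo_kernel(random_psd(7, 21), "GRM"))
  path <- tempfile(fileext = ".tsv")
  write_kernel(k, path)
  k2 <- read_kernel(path, kind = "GRM")
  expect_equal(unclass(k2), unclass(k), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(rownames(k2), rownames(k))
})
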