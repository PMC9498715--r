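#' Simulation parameters for a synthetic holo-omic dataset
#'
#' Defines the generative model for [simulate_holoomics()]: dense biallelic
#' SNP dosages, compositional OTU counts, and a phenotype composed of fixed
#' and class effects plus genomic, microbial, genome-by-microbiome
#' interaction, and residual components with prescribed variance fractions
#' that sum to one.
#'
#' @param n_samples,n_snps,n_otus Problem dimensions (all at least 1).
#'   Defaults emulate a mid-sized livestock cohort: 400 animals, 1000 SNPs,
#'   200 OTUs.
#' @param maf_range Range of per-SNP ALT-allele frequencies, within
#'   `(0, 0.5]`.
#' @param otu_concentration Dirichlet concentration per OTU (total
#'   concentration is `otu_concentration * n_otus`); smaller values give
#'   sparser, more overdispersed compositions so the 20% prevalence filter
#'   has bite.
#' @param sequencing_depth Reads per sample for the multinomial draw.
#' @param var_g,var_m,var_gm,var_e Variance fractions of the genomic,
#'   microbial, interaction (Hadamard-kernel) and residual components; must
#'   sum to 1 within 1e-9.
#' @param fixed_effect_levels Number of levels of the farm-like fixed
#'   effect (1 = no effect).
#' @param class_effect_levels Number of levels of the diet-like class
#'   effect fitted with a BayesB prior (1 = no effect).
#' @param gm_correlation Optional mixing weight in `[0, 1)` that makes the
#'   microbial component borrow part of the genomic draw, inducing a
#'   genome-microbiome correlation for exercising the covariance
#'   (CORE-style) interaction term. Default 0: independent.
#' @param missing_rate Fraction of genotype calls set to `NA`, to exercise
#'   mean imputation. Default 0.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the parameter set.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_samples = 400, n_snps = 1000, n_otus = 200,
                       maf_range = c(0.05, 0.5), otu_concentration = 0.1,
                       sequencing_depth = 10000,
                       var_g = 0.3, var_m = 0.3, var_gm = 0.1, var_e = 0.3,
                       fixed_effect_levels = 3, class_effect_levels = 3,
                       gm_correlation = 0, missing_rate = 0, seed = 1) {
  p <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
            n_otus = as.integer(n_otus), maf_range = as.numeric(maf_range),
            otu_concentration = otu_concentration,
            sequencing_depth = as.integer(sequencing_depth),
            var_g = var_g, var_m = var_m, var_gm = var_gm, var_e = var_e,
            fixed_effect_levels = as.integer(fixed_effect_levels),
            class_effect_levels = as.integer(class_effect_levels),
            gm_correlation = gm_correlation, missing_rate = missing_rate,
            seed = as.integer(seed))
  vsum <- var_g + var_m + var_gm + var_e
  if (abs(vsum - 1) > 1e-9) {
    stop_holo(sprintf(
      "variance fractions must sum to 1: var_g=%g, var_m=%g, var_gm=%g, var_e=%g (sum %g)",
      var_g, var_m, var_gm, var_e, vsum))
  }
  if (any(c(var_g, var_m, var_gm, var_e) < 0)) {
    stop_holo("variance fractions must be non-negative")
  }
  if (length(p$maf_range) != 2 || p$maf_range[1] <= 0 ||
      p$maf_range[2] > 0.5 || p$maf_range[1] > p$maf_range[2]) {
    stop_holo("`maf_range` must be an increasing pair within (0, 0.5]")
  }
  if (any(c(p$n_samples, p$n_snps, p$n_otus, p$sequencing_depth,
            p$fixed_effect_levels, p$class_effect_levels) < 1)) {
    stop_holo("all counts must be at least 1")
  }
  if (gm_correlation < 0 || gm_correlation >= 1) {
    stop_holo("`gm_correlation` must lie in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_holo("`missing_rate` must lie in [0, 1)")
  }
  structure(p, class = "sim_params")
}

# zero-mean Gaussian vector with covariance var_frac * K, drawn in the
# eigenbasis of K (negative eigenvalues truncated at zero)
draw_kernel_effect <- function(eig, var_frac) {
  d <- pmax(eig$values, 0)
  as.numeric(eig$vectors %*% (sqrt(d) * rnorm(length(d)))) * sqrt(var_frac)
}

#' Simulate a holo-omic dataset
#'
#' Generates genotypes (per-SNP `Binomial(2, p_m)` with `p_m` uniform in
#' `maf_range`; SNPs whose realised MAF falls below 0.01 are redrawn),
#' Dirichlet-multinomial OTU counts, and phenotypes built from the exact
#' variance structure of the multi-kernel holo-omic model: the genomic,
#' microbial and interaction components are zero-mean Gaussian vectors with
#' covariances `var_g * G`, `var_m * M` and `var_gm * (G o M)`, where the
#' kernels are computed from the simulated data themselves and normalised
#' to mean diagonal one, and the interaction kernel is the Hadamard
#' product. The stored true components satisfy the bookkeeping identity
#' `y = fixed + class + g + m + interaction + e` exactly.
#'
#' @param params A [sim_params()].
#' @return A `holo_sim` list with elements `genotypes`
#'   ([genotype_matrix()]), `otus` ([otu_table()] of counts), `phenotypes`
#'   (tibble: `sample_id`, `y`, `farm`, `diet`), `true_components` (tibble
#'   of the per-sample fixed, class, g, m, interaction and e vectors),
#'   `true_variances` (the four target fractions), `kernels` (the
#'   normalised G, M and Hadamard kernels used for generation) and
#'   `params`.
#' @export
simulate_holoomics <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  ## genotypes: redraw SNPs whose realised MAF drops below the 0.01 QC floor
  draw_snp <- function(m) {
    for (try in 1:25) {
      pm <- runif(1, params$maf_range[1], params$maf_range[2])
      x <- rbinom(n, 2, pm)
      f <- mean(x) / 2
      if (min(f, 1 - f) >= 0.01) return(x)
    }
    x  # tiny n can make 0.01 unreachable; keep the last draw
  }
  z <- vapply(seq_len(params$n_snps), draw_snp, numeric(n))
  dimnames(z) <- list(ids, sprintf("snp%05d", seq_len(params$n_snps)))
  if (params$missing_rate > 0) {
    nmiss <- round(params$missing_rate * length(z))
    z[sample(length(z), nmiss)] <- NA
  }
  genotypes <- genotype_matrix(z)

  ## OTU counts: Dirichlet-multinomial around a heterogeneous base composition
  q <- params$n_otus
  base <- rgamma(q, shape = 0.3)
  base <- base / sum(base)
  alpha <- params$otu_concentration * q * base
  counts <- t(vapply(seq_len(n), function(i) {
    w <- rgamma(q, shape = alpha)
    s <- sum(w)
    pr <- if (s > 0) w / s else rep(1 / q, q)
    as.numeric(rmultinom(1, params$sequencing_depth, pr))
  }, numeric(q)))
  dimnames(counts) <- list(ids, sprintf("OTU%04d", seq_len(q)))
  otus <- otu_table(counts)

  ## kernels from the simulated data, on the unit-diagonal scale; the
  ## microbial component lives on the measured community, i.e. the OTUs
  ## that survive the standard 20% prevalence filter, exactly as the
  ## analysis pipeline will see it
  gk <- normalise_kernel(compute_grm(genotypes))
  mk <- normalise_kernel(suppressWarnings(
    compute_mrm(filter_otus_prevalence(otus, 0.2))))
  hk <- normalise_kernel(hadamard_kernel(gk, mk))

  g <- draw_kernel_effect(eigen(unclass(gk), symmetric = TRUE), params$var_g)
  m <- draw_kernel_effect(eigen(unclass(mk), symmetric = TRUE), params$var_m)
  if (params$gm_correlation > 0) {
    rho <- params$gm_correlation
    m0 <- if (params$var_m > 0) m / sqrt(params$var_m) else m
    g0 <- if (params$var_g > 0) g / sqrt(params$var_g) else g
    m <- sqrt(params$var_m) * (sqrt(1 - rho^2) * m0 + rho * g0)
  }
  gm <- draw_kernel_effect(eigen(unclass(hk), symmetric = TRUE), params$var_gm)
  e <- rnorm(n, 0, sqrt(params$var_e))

  level_effects <- function(L, half_width) {
    if (L == 1) return(0) else seq(-half_width, half_width, length.out = L)
  }
  farm_lev <- sprintf("farm%d", seq_len(params$fixed_effect_levels))
  farm <- sample(farm_lev, n, replace = TRUE)
  farm_eff <- level_effects(params$fixed_effect_levels, 0.5)
  diet_lev <- sprintf("diet%d", seq_len(params$class_effect_levels))
  diet <- sample(diet_lev, n, replace = TRUE)
  diet_eff <- level_effects(params$class_effect_levels, 0.3)

  fixed_part <- farm_eff[match(farm, farm_lev)]
  class_part <- diet_eff[match(diet, diet_lev)]
  y <- fixed_part + class_part + g + m + gm + e

  structure(list(
    genotypes = genotypes,
    otus = otus,
    phenotypes = tibble(sample_id = ids, y = y, farm = farm, diet = diet),
    true_components = tibble(sample_id = ids, fixed = fixed_part,
                             class = class_part, g = g, m = m,
                             interaction = gm, e = e),
    true_variances = c(var_g = params$var_g, var_m = params$var_m,
                       var_gm = params$var_gm, var_e = params$var_e),
    kernels = list(G = gk, M = mk, GM = hk),
    params = params
  ), class = "holo_sim")
}

#' @export
print.holo_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<holo_sim> %d samples, %d SNPs, %d OTUs; fractions g/m/gm/e = %g/%g/%g/%g (seed %d)\n",
    p$n_samples, p$n_snps, p$n_otus, p$var_g, p$var_m, p$var_gm, p$var_e,
    p$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `genotypes.tsv`, `otus.tsv` and `phenotypes.csv` in the formats
#' that [read_genotypes()], [read_otu_table()] and [read_phenotypes()]
#' read, preserving sample order across all three files. Reading the files
#' back reproduces the matrices exactly.
#'
#' @param ds A `holo_sim` from [simulate_holoomics()].
#' @param dir Output directory (created, recursively, if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "holo_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_holo(sprintf("cannot create directory '%s'", dir))
  }
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             otus = file.path(dir, "otus.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"))
  write_genotypes(ds$genotypes, paths[["genotypes"]])
  write_otu_table(ds$otus, paths[["otus"]])
  readr::write_csv(ds$phenotypes, paths[["phenotypes"]])
  invisible(paths)
}
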