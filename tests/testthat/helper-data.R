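# small fixture builders shared across test files

toy_genotypes <- function() {
  # 6 samples x 3 SNPs with hand-computable allele frequencies:
  # snpA p = 6/12 = 0.5, snpB p = 1/12 ~ 0.083, snpC p = 0 (monomorphic)
  z <- cbind(snpA = c(1, 1, 1, 1, 1, 1),
             snpB = c(1, 0, 0, 0, 0, 0),
             snpC = c(0, 0, 0, 0, 0, 0))
  rownames(z) <- paste0("S", 1:6)
  genotype_matrix(z)
}

quick_sim <- function(n = 120, seed = 1, ...) {
  simulate_holoomics(sim_params(n_samples = n, n_snps = 200, n_otus = 60,
                                seed = seed, ...))
}

quick_settings <- function(seed = 1, n_iter = 600, burn_in = 200, ...) {
  mcmc_settings(n_iter = n_iter, burn_in = burn_in, thin = 2, seed = seed, ...)
}

# minimal stand-in CV result for compare_models unit tests
fake_cv <- function(label, r2s) {
  structure(list(label = label,
                 per_fold = tibble::tibble(repeat_index = seq_along(r2s),
                                           fold = 1L, n_val = 10L, r2 = r2s),
                 per_repeat = tibble::tibble(repeat_index = seq_along(r2s),
                                             r2 = r2s),
                 mean_r2 = mean(r2s), sd_r2 = stats::sd(r2s),
                 fingerprint = "fake"),
            class = "holo_cv")
}
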