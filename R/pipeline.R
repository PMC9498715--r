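#' Configure a full holo-omic prediction run
#'
#' Exactly one data source must be given: either `simulate` (a
#' [sim_params()]) or the three input files. The pipeline is a
#' deterministic function of the configuration: all randomness flows from
#' the three named seeds (data, folds, mcmc).
#'
#' @param simulate Optional [sim_params()] describing a synthetic dataset.
#' @param genotype_file,otu_file,phenotype_file Input paths (TSV dosages,
#'   TSV counts, CSV phenotypes) when running on real data.
#' @param trait Trait column name.
#' @param models Model labels to evaluate (subset of [model_labels()]).
#' @param maf MAF filter threshold for SNPs.
#' @param prevalence Prevalence filter threshold for OTUs.
#' @param cv_k,cv_repeats Cross-validation geometry.
#' @param fold_seed,mcmc_seed Seeds for fold assignment and the Gibbs
#'   chains (the data seed lives inside `simulate`).
#' @param settings [mcmc_settings()] template for every fit (its seed is
#'   superseded by `mcmc_seed`).
#' @param alpha Significance level for the model comparison.
#' @param out_dir Output directory.
#' @return A `holo_config`.
#' @export
run_config <- function(simulate = NULL, genotype_file = NULL,
                       otu_file = NULL, phenotype_file = NULL,
                       trait = "y", models = c("genomic", "microbial",
                                               "direct", "core", "hadamard"),
                       maf = 0.01, prevalence = 0.2,
                       cv_k = 10, cv_repeats = 10,
                       fold_seed = 2, mcmc_seed = 3,
                       settings = mcmc_settings(), alpha = 0.05,
                       out_dir = tempfile("holopred_run_")) {
  files_given <- !is.null(genotype_file) || !is.null(otu_file) ||
    !is.null(phenotype_file)
  if (is.null(simulate) == !files_given) {
    stop_holo("provide exactly one of `simulate` or the three input files")
  }
  if (files_given &&
      (is.null(genotype_file) || is.null(otu_file) || is.null(phenotype_file))) {
    stop_holo("all three of genotype_file, otu_file, phenotype_file are required")
  }
  bad <- setdiff(models, model_labels())
  if (length(bad)) {
    stop_holo(sprintf("unknown model label '%s'; valid labels: %s",
                      bad[1], paste(model_labels(), collapse = ", ")))
  }
  structure(list(simulate = simulate, genotype_file = genotype_file,
                 otu_file = otu_file, phenotype_file = phenotype_file,
                 trait = trait, models = models, maf = maf,
                 prevalence = prevalence, cv_k = cv_k,
                 cv_repeats = cv_repeats, fold_seed = as.integer(fold_seed),
                 mcmc_seed = as.integer(mcmc_seed), settings = settings,
                 alpha = alpha, out_dir = out_dir),
            class = "holo_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `simulate` and
#' `settings` are nested maps passed to [sim_params()] and
#' [mcmc_settings()].
#'
#' @param path YAML file.
#' @return A `holo_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_holo(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) raw$simulate <- do.call(sim_params, raw$simulate)
  if (!is.null(raw$settings)) raw$settings <- do.call(mcmc_settings, raw$settings)
  do.call(run_config, raw)
}

#' Build the kernel set a collection of model labels needs
#'
#' Filters the inputs (MAF, prevalence), builds the GRM and MRM, normalises
#' every kernel to mean diagonal one, and adds the Hadamard and/or
#' Cholesky cross-product interaction kernels when requested.
#'
#' @param genotypes A [genotype_matrix()].
#' @param otus An [otu_table()].
#' @param models Model labels to be served.
#' @param maf,prevalence Filter thresholds.
#' @return Named list of normalised [holo_kernel()]s (`G`, `M`, and
#'   `GM_hadamard` / `GM_core` as needed).
#' @export
build_kernel_set <- function(genotypes, otus, models = model_labels(),
                             maf = 0.01, prevalence = 0.2) {
  gflt <- filter_snps_maf(genotypes, maf)
  oflt <- filter_otus_prevalence(otus, prevalence)
  gk <- normalise_kernel(compute_grm(gflt))
  mk <- normalise_kernel(compute_mrm(oflt))
  ks <- list(G = gk, M = mk)
  if ("hadamard" %in% models) {
    ks$GM_hadamard <- normalise_kernel(hadamard_kernel(gk, mk))
  }
  if ("core" %in% models) {
    ks$GM_core <- normalise_kernel(core_greml_kernel(gk, mk))
  }
  ks
}

#' Run the full holo-omic prediction pipeline
#'
#' Filter -> kernels -> repeated k-fold CV per model -> ANOVA comparison,
#' writing all artifacts (kernel TSVs, CV CSVs, comparison CSV, and a
#' metadata YAML sufficient to re-run the pipeline identically) to the
#' configured output directory. Re-running with the same configuration
#' reproduces every numeric output bit for bit.
#'
#' @param cfg A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `cv` (named list of `holo_cv`),
#'   `comparison` (`holo_comparison` or `NULL` for a single model),
#'   `kernels`, `summary` (tibble), and `out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "holo_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_holo(sprintf("[%s] %s", what, conditionMessage(e)))
    })
  }

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  say("stage data: %s", if (is.null(cfg$simulate)) "reading input files"
      else "simulating dataset")
  data <- stage("data", {
    if (is.null(cfg$simulate)) {
      list(genotypes = read_genotypes(cfg$genotype_file),
           otus = read_otu_table(cfg$otu_file),
           phenotypes = read_phenotypes(cfg$phenotype_file))
    } else {
      sim <- simulate_holoomics(cfg$simulate)
      list(genotypes = sim$genotypes, otus = sim$otus,
           phenotypes = sim$phenotypes, sim = sim)
    }
  })

  say("stage kernels: MAF >= %g, prevalence >= %g", cfg$maf, cfg$prevalence)
  kernels <- stage("kernels", suppressWarnings(
    build_kernel_set(data$genotypes, data$otus, cfg$models,
                     maf = cfg$maf, prevalence = cfg$prevalence)))
  for (nm in names(kernels)) {
    write_kernel(kernels[[nm]], file.path(cfg$out_dir,
                                          paste0("kernel_", nm, ".tsv")))
  }

  folds <- stage("folds", make_folds(nrow(data$phenotypes), k = cfg$cv_k,
                                     repeats = cfg$cv_repeats,
                                     seed = cfg$fold_seed))

  st <- cfg$settings
  st$seed <- cfg$mcmc_seed
  cv <- list()
  for (lb in cfg$models) {
    say("stage cv: model '%s' (%d repeats x %d folds)", lb,
        cfg$cv_repeats, cfg$cv_k)
    cv[[lb]] <- stage(paste0("cv:", lb),
                      cross_validate(data$phenotypes, lb, kernels, folds,
                                     settings = st, trait = cfg$trait))
  }

  cv_long <- purrr::map_dfr(cv, tidy)
  readr::write_csv(cv_long, file.path(cfg$out_dir, "cv_results.csv"))
  summary_df <- purrr::map_dfr(cv, glance)
  readr::write_csv(summary_df, file.path(cfg$out_dir, "cv_summary.csv"))

  comparison <- NULL
  if (length(cv) >= 2) {
    say("stage compare: one-way ANOVA across %d models", length(cv))
    comparison <- stage("compare", compare_models(cv, alpha = cfg$alpha))
    readr::write_csv(tidy(comparison),
                     file.path(cfg$out_dir, "comparison.csv"))
  }

  meta <- list(
    package = "holopred",
    version = as.character(utils::packageVersion("holopred")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    trait = cfg$trait, models = cfg$models,
    maf = cfg$maf, prevalence = cfg$prevalence,
    cv = list(k = cfg$cv_k, repeats = cfg$cv_repeats),
    seeds = list(data = if (!is.null(cfg$simulate)) cfg$simulate$seed,
                 folds = cfg$fold_seed, mcmc = cfg$mcmc_seed),
    mcmc = cfg$settings[c("n_iter", "burn_in", "thin", "bayesb_pi",
                          "bayesb_df", "vc_df", "resid_df", "r2_prior",
                          "class_effects")],
    simulate = if (!is.null(cfg$simulate)) unclass(cfg$simulate),
    inputs = if (is.null(cfg$simulate)) {
      list(genotypes = cfg$genotype_file, otus = cfg$otu_file,
           phenotypes = cfg$phenotype_file)
    }
  )
  yaml::write_yaml(meta, file.path(cfg$out_dir, "run_metadata.yaml"))
  say("pipeline complete: %s", cfg$out_dir)

  invisible(list(cv = cv, comparison = comparison, kernels = kernels,
                 summary = summary_df, out_dir = cfg$out_dir))
}
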