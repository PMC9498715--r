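#' MCMC settings for the Gibbs sampler
#'
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before collection (`burn_in < n_iter`).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed; identical settings and data give identical
#'   chains.
#' @param bayesb_pi Prior probability that a BayesB effect is exactly zero.
#' @param bayesb_df,bayesb_scale Scaled-inverse-chi-squared hyperparameters
#'   of the per-effect BayesB variances; `NULL` scale is set from the data
#'   by the expected-proportion-of-variance rule.
#' @param vc_df,vc_scale Hyperparameters of the kernel variance components;
#'   `NULL` scale set as above.
#' @param resid_df Residual-variance prior degrees of freedom.
#' @param resid_scale Residual-variance prior scale; `NULL` (default)
#'   derives it from `r2_prior` and the phenotypic variance.
#' @param r2_prior Prior guess of the proportion of phenotypic variance
#'   explained jointly by the random terms; used only to set default prior
#'   scales.
#' @param fix_variances Optional named list pinning variance components at
#'   fixed values (names among the model's kernel-term names and `"e"`),
#'   e.g. `list(g = 0.4, e = 0.6)` — used for closed-form BLUP checks.
#' @param class_effects `"bayesb"` (default: class-effect dummy columns get
#'   the BayesB mixture prior) or `"gaussian"` (one common Gaussian
#'   variance per class term).
#' @param eig_tol Relative eigenvalue truncation threshold for kernel
#'   eigendecompositions.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_iter = 12000, burn_in = 2000, thin = 5,
                          seed = 42, bayesb_pi = 0.5, bayesb_df = 5,
                          bayesb_scale = NULL, vc_df = 5, vc_scale = NULL,
                          resid_df = 5, resid_scale = NULL, r2_prior = 0.5,
                          fix_variances = NULL,
                          class_effects = c("bayesb", "gaussian"),
                          eig_tol = 1e-8) {
  class_effects <- match.arg(class_effects)
  if (burn_in >= n_iter) stop_holo("`burn_in` must be smaller than `n_iter`")
  if (thin < 1) stop_holo("`thin` must be at least 1")
  if (bayesb_pi < 0 || bayesb_pi >= 1) stop_holo("`bayesb_pi` must lie in [0, 1)")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 bayesb_pi = bayesb_pi, bayesb_df = bayesb_df,
                 bayesb_scale = bayesb_scale, vc_df = vc_df,
                 vc_scale = vc_scale, resid_df = resid_df,
                 resid_scale = resid_scale,
                 r2_prior = r2_prior, fix_variances = fix_variances,
                 class_effects = class_effects, eig_tol = eig_tol),
            class = "mcmc_settings")
}

model_kernel_requirements <- list(
  genomic  = c(g = "GRM"),
  microbial = c(m = "MRM"),
  direct   = c(g = "GRM", m = "MRM"),
  core     = c(g = "GRM", m = "MRM", gm = "CORE"),
  hadamard = c(g = "GRM", m = "MRM", gm = "HADAMARD")
)

#' Model labels understood by the pipeline
#' @return Character vector of the five model labels.
#' @export
model_labels <- function() names(model_kernel_requirements)

#' Declare a holo-omic prediction model
#'
#' Maps a model label to the kernel random effects it needs and attaches
#' the covariate structure found in the phenotype table:
#' \describe{
#'   \item{`genomic`}{`y = Xb + class + g + e` (GRM only)}
#'   \item{`microbial`}{`y = Xb + class + m + e` (MRM only)}
#'   \item{`direct`}{`y = Xb + class + g + m + e`}
#'   \item{`core`}{adds the Cholesky cross-product covariance kernel}
#'   \item{`hadamard`}{adds the Hadamard interaction kernel}
#' }
#' Unless given explicitly, covariates are auto-detected from `pheno` the
#' way the two livestock dataset styles use them: numeric columns (age,
#' weight, ...) and a `farm` column become fixed covariates, while the
#' remaining character/factor columns (diet, pen, slaughter day, ...)
#' become class effects fitted under the BayesB prior.
#'
#' @param pheno Phenotype tibble with a `sample_id` column and the trait;
#'   `NA` trait values mark samples to predict.
#' @param label One of [model_labels()].
#' @param kernels List of [holo_kernel()]s; the ones required by `label`
#'   are located by their `kind` attribute and aligned to `pheno`'s sample
#'   order.
#' @param trait Name of the trait column (default `"y"`).
#' @param fixed,class Optional character vectors of covariate column names
#'   overriding auto-detection.
#' @return A `holo_model_spec`.
#' @export
build_model <- function(pheno, label, kernels, trait = "y",
                        fixed = NULL, class = NULL) {
  if (!label %in% names(model_kernel_requirements)) {
    stop_holo(sprintf("unknown model label '%s'; valid labels: %s",
                      label, paste(model_labels(), collapse = ", ")))
  }
  if (!"sample_id" %in% names(pheno)) {
    stop_holo("phenotype table must have a 'sample_id' column")
  }
  if (!trait %in% names(pheno)) {
    stop_holo(sprintf("trait column '%s' not found in phenotype table", trait))
  }
  ids <- as.character(pheno$sample_id)
  if (sum(!is.na(pheno[[trait]])) < 1) {
    stop_holo("at least one non-missing phenotype is required")
  }

  if (inherits(kernels, "holo_kernel")) kernels <- list(kernels)
  kinds <- vapply(kernels, function(k) attr(k, "kind"), character(1))
  req <- model_kernel_requirements[[label]]
  kterm <- list()
  for (i in seq_along(req)) {
    hit <- which(kinds == req[[i]])
    if (!length(hit)) {
      stop_holo(sprintf("model '%s' needs a %s kernel but none was supplied",
                        label, req[[i]]))
    }
    k <- kernels[[hit[1]]]
    missing_ids <- setdiff(ids, kernel_ids(k))
    if (length(missing_ids)) {
      stop_holo(sprintf("sample '%s' absent from the %s kernel",
                        missing_ids[1], req[[i]]))
    }
    km <- unclass(k)[ids, ids]
    kterm[[names(req)[i]]] <- holo_kernel(km, kind = req[[i]])
  }

  covars <- setdiff(names(pheno), c("sample_id", trait))
  if (is.null(fixed) && is.null(class)) {
    # numeric covariates (age, weight, ...) and farm are fixed; other
    # categorical columns (diet, pen, slaughter day, ...) are class effects
    is_num <- vapply(pheno[covars], is.numeric, logical(1))
    fixed <- covars[is_num | covars %in% "farm"]
    class <- setdiff(covars, fixed)
  } else {
    fixed <- fixed %||% character(0)
    class <- class %||% character(0)
    missing_cols <- setdiff(c(fixed, class), names(pheno))
    if (length(missing_cols)) {
      stop_holo(sprintf("covariate column '%s' not found", missing_cols[1]))
    }
  }
  # a constant class column carries no contrast to fit
  class <- class[vapply(class,
                        function(tm) length(unique(pheno[[tm]])) > 1,
                        logical(1))]
  structure(list(label = label, trait = trait, fixed_terms = fixed,
                 class_terms = class, kernels = kterm, sample_ids = ids),
            class = "holo_model_spec")
}

#' @export
print.holo_model_spec <- function(x, ...) {
  cat(sprintf("<holo_model_spec '%s'> trait '%s', %d samples\n",
              x$label, x$trait, length(x$sample_ids)))
  cat(sprintf("  kernel terms: %s\n",
              paste(names(x$kernels), collapse = ", ")))
  cat(sprintf("  fixed: %s | class: %s\n",
              paste(x$fixed_terms, collapse = ", "),
              paste(x$class_terms, collapse = ", ")))
  invisible(x)
}

# design matrix for the flat-prior fixed part: intercept + numeric columns
# + treatment-coded categorical fixed terms; aliased columns dropped
build_fixed_design <- function(pheno, fixed_terms) {
  n <- nrow(pheno)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (term in fixed_terms) {
    v <- pheno[[term]]
    if (is.numeric(v)) {
      X <- cbind(X, setNames(data.frame(v), term))
    } else {
      f <- factor(v)
      if (nlevels(f) > 1) {
        mm <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(term, levels(f)[-1])
        X <- cbind(X, mm)
      }
    }
  }
  X <- as.matrix(X)
  rownames(X) <- NULL
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  X
}

# full-dummy design for one class term (BayesB block)
build_class_block <- function(pheno, term) {
  f <- factor(pheno[[term]])
  mm <- model.matrix(~ 0 + f)
  colnames(mm) <- paste0(term, levels(f))
  rownames(mm) <- NULL
  mm
}

#' Fit a holo-omic mixed model by Gibbs sampling
#'
#' Samples the joint posterior of a linear mixed model with flat-prior
#' fixed effects, BayesB mixture-prior class-effect blocks, and any number
#' of kernel (RKHS) random effects, each kernel effect sampled jointly in
#' the orthonormal eigenbasis of its kernel. Missing phenotypes are handled
#' by data augmentation: the samples stay in the kernels but their
#' phenotype is redrawn from its predictive distribution every sweep, so
#' they contribute nothing to the posterior of the parameters while still
#' receiving predictions.
#'
#' @param spec A [build_model()] spec.
#' @param pheno Phenotype tibble matching `spec` (same samples, same
#'   order); `NA` trait entries are predicted.
#' @param settings An [mcmc_settings()].
#' @param eig_cache Optional precomputed kernel eigendecompositions (from
#'   [kernel_eigens()] on the same spec); cross-validation uses this to
#'   avoid re-factorising identical kernels for every fold refit.
#' @return A `holo_fit` with posterior summaries: `var_components`
#'   (tibble: term, post_mean, post_sd), `fixed_effects`, `yhat`
#'   (posterior-mean linear predictor for every sample), `predictions`
#'   (tibble for the `NA` entries), `component_means`, MCMC bookkeeping and
#'   the random seed. Methods: [tidy()], [glance()], [predict()],
#'   [variance_fractions()].
#' @export
holo_fit <- function(spec, pheno, settings = mcmc_settings(),
                     eig_cache = NULL) {
  stopifnot(inherits(spec, "holo_model_spec"),
            inherits(settings, "mcmc_settings"))
  if (!identical(as.character(pheno$sample_id), spec$sample_ids)) {
    stop_holo("phenotype table does not match the samples the model was built on")
  }
  y <- as.numeric(pheno[[spec$trait]])
  n <- length(y)
  if (sum(!is.na(y)) < 20) {
    stop_holo("need at least 20 non-missing phenotypes to fit")
  }

  X <- build_fixed_design(pheno, spec$fixed_terms)
  blocks <- lapply(spec$class_terms, function(tm) build_class_block(pheno, tm))
  names(blocks) <- spec$class_terms

  eigs <- eig_cache %||% kernel_eigens(spec, settings$eig_tol)
  if (!identical(names(eigs), names(spec$kernels))) {
    stop_holo("eig_cache does not match the model's kernel terms")
  }
  if (any(vapply(eigs, function(e) length(e$d) == 0, logical(1)))) {
    bad <- names(eigs)[vapply(eigs, function(e) length(e$d) == 0, logical(1))][1]
    stop_holo(sprintf("kernel term '%s' is degenerate (no positive eigenvalues)",
                      bad))
  }

  out <- gibbs_sampler(y, X, blocks, eigs, settings)

  vc_terms <- c(names(spec$kernels),
                if (settings$class_effects == "gaussian") names(blocks),
                "e")
  vs <- out$var_samples
  var_components <- tibble(
    term = paste0("sigma2_", colnames(vs)),
    post_mean = colMeans(vs),
    post_sd = apply(vs, 2, sd)
  )
  miss <- which(is.na(y))
  predictions <- tibble(sample_id = spec$sample_ids[miss],
                        y_obs = y[miss],
                        y_hat = unname(out$lp_mean[miss]))
  structure(list(
    label = spec$label, trait = spec$trait, spec = spec,
    var_components = var_components,
    var_samples = vs,
    fixed_effects = tibble(term = colnames(X), post_mean = out$beta_mean),
    class_effect_means = out$block_means,
    yhat = setNames(out$lp_mean, spec$sample_ids),
    component_means = out$u_means,
    predictions = predictions,
    n_kept = out$n_kept,
    eig_truncated = vapply(eigs, `[[`, integer(1), "n_trunc"),
    last_state = out$last_state,
    settings = settings
  ), class = "holo_fit")
}

#' Eigendecompositions of a model's kernels
#'
#' Spectral decomposition of every kernel term of a model spec, with
#' eigenvalues below `tol` times the largest truncated (negative
#' eigenvalues of an indefinite CORE kernel are dropped with a message).
#' The Gibbs sampler works in these bases; pass the result as `eig_cache`
#' to [holo_fit()] when fitting the same kernels repeatedly.
#'
#' @param spec A [build_model()] spec.
#' @param tol Relative truncation threshold.
#' @return Named list (one per kernel term) of `U`, `d`, truncation counts.
#' @export
kernel_eigens <- function(spec, tol = 1e-8) {
  lapply(spec$kernels, function(k) {
    ev <- eigen(unclass(k), symmetric = TRUE)
    keep <- ev$values > tol * max(ev$values)
    n_neg <- sum(ev$values < -tol * max(abs(ev$values)))
    if (n_neg > 0) {
      inform(sprintf("kernel '%s': %d negative eigenvalue(s) truncated to zero",
                     attr(k, "kind"), n_neg))
    }
    list(U = ev$vectors[, keep, drop = FALSE], d = ev$values[keep],
         n_trunc = sum(!keep), n_neg = n_neg)
  })
}

#' @export
print.holo_fit <- function(x, ...) {
  cat(sprintf("<holo_fit '%s'> trait '%s', %d samples (%d predicted), %d kept draws\n",
              x$label, x$trait, length(x$yhat), nrow(x$predictions),
              x$n_kept))
  print(as.data.frame(x$var_components), row.names = FALSE)
  invisible(x)
}

#' Posterior predictions for masked phenotypes
#'
#' @param object A [holo_fit()] result.
#' @param samples Optional character vector restricting (and ordering) the
#'   returned predictions; must be samples the model was fitted on.
#' @param ... Unused.
#' @return Tibble `sample_id`, `y_hat` — the posterior-mean linear
#'   predictor of each masked sample, in input order.
#' @export
predict.holo_fit <- function(object, samples = NULL, ...) {
  preds <- object$predictions
  if (is.null(samples)) return(preds[, c("sample_id", "y_hat")])
  unknown <- setdiff(samples, names(object$yhat))
  if (length(unknown)) {
    stop_holo(sprintf("sample '%s' was not part of the fit", unknown[1]))
  }
  tibble(sample_id = samples,
         y_hat = unname(object$yhat[samples]))
}

#' Posterior variance fractions
#'
#' The posterior mean (and SD) of each variance component divided by the
#' total of all components, computed per posterior draw — the genomic
#' fraction is the heritability analogue, the microbial fraction the
#' microbiability.
#'
#' @param fit A [holo_fit()] result.
#' @return Tibble: `term`, `fraction`, `sd`.
#' @export
variance_fractions <- function(fit) {
  stopifnot(inherits(fit, "holo_fit"))
  vs <- fit$var_samples
  fr <- vs / rowSums(vs)
  tibble(term = colnames(vs), fraction = colMeans(fr),
         sd = apply(fr, 2, sd))
}

#' @exportS3Method generics::tidy
tidy.holo_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$var_components, type = "variance"),
    dplyr::mutate(dplyr::rename(x$fixed_effects, post_mean = "post_mean"),
                  post_sd = NA_real_, type = "fixed")
  )[, c("term", "post_mean", "post_sd", "type")]
}

#' @exportS3Method generics::glance
glance.holo_fit <- function(x, ...) {
  vf <- variance_fractions(x)
  tibble(label = x$label, n = length(x$yhat),
         n_predicted = nrow(x$predictions), n_kept = x$n_kept,
         sigma2_e = x$var_components$post_mean[x$var_components$term == "sigma2_e"],
         frac_g = if ("g" %in% vf$term) vf$fraction[vf$term == "g"] else NA_real_,
         frac_m = if ("m" %in% vf$term) vf$fraction[vf$term == "m"] else NA_real_,
         frac_gm = if ("gm" %in% vf$term) vf$fraction[vf$term == "gm"] else NA_real_)
}
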