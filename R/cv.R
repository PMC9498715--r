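#' Random balanced cross-validation folds
#'
#' Builds `repeats` independent balanced partitions of `n` samples into
#' `k` folds (fold sizes differ by at most one). Deterministic given
#' `seed`; different repeats use different partitions.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 10).
#' @param repeats Number of independent repeats (default 10).
#' @param seed Integer seed.
#' @return A `holo_folds` tibble with columns `repeat_index`,
#'   `sample_index`, `fold`, and attributes `n`, `k`, `repeats`, `seed`.
#' @export
make_folds <- function(n, k = 10, repeats = 10, seed = 1) {
  if (k > n) stop_holo(sprintf("cannot make %d folds from %d samples", k, n))
  if (k < 2) stop_holo("`k` must be at least 2")
  out <- purrr::map_dfr(seq_len(repeats), function(r) {
    set.seed(child_seed(seed, 7, r))
    tibble(repeat_index = r, sample_index = seq_len(n),
           fold = sample(rep_len(seq_len(k), n)))
  })
  structure(out, n = n, k = k, repeats = repeats, seed = seed,
            class = c("holo_folds", class(out)))
}

#' Squared Pearson correlation
#'
#' The prediction-accuracy criterion: the square of the correlation
#' coefficient between observed and predicted phenotypes.
#'
#' @param obs,pred Equal-length numeric vectors (length at least 3), each
#'   with nonzero variance.
#' @return A number in `[0, 1]`.
#' @export
r_squared <- function(obs, pred) {
  if (length(obs) != length(pred)) stop_holo("`obs` and `pred` differ in length")
  if (length(obs) < 3) stop_holo("need at least 3 pairs for r-squared")
  if (anyNA(obs) || anyNA(pred)) stop_holo("missing values in `obs` or `pred`")
  if (var(obs) == 0 || var(pred) == 0) {
    stop_holo("zero variance in `obs` or `pred`; r-squared undefined")
  }
  cor(obs, pred)^2
}

#' Repeated k-fold cross-validated prediction accuracy
#'
#' For every repeat and fold, refits the model with that fold's phenotypes
#' masked (`NA`), predicts them from the posterior linear predictor, and
#' scores the fold by the squared correlation between predictions and the
#' raw observed phenotypes. Per-repeat accuracy is the mean over folds; the
#' model's accuracy is the mean over repeats.
#'
#' @param pheno Phenotype tibble (`sample_id`, trait, covariates); all
#'   trait values must be observed.
#' @param label A model label (see [model_labels()]).
#' @param kernels List of [holo_kernel()]s covering the label's needs.
#' @param folds A [make_folds()] assignment for `nrow(pheno)` samples.
#' @param settings [mcmc_settings()] used for every refit; each
#'   repeat-by-fold fit gets a distinct chain seed derived from
#'   `settings$seed`.
#' @param trait,fixed,class Passed to [build_model()].
#' @return A `holo_cv` with `per_fold` (tibble: repeat_index, fold, n_val,
#'   r2), `per_repeat` (tibble: repeat_index, r2), `mean_r2`, `sd_r2` and a
#'   settings fingerprint. Methods: [tidy()], [glance()], [autoplot()].
#' @export
cross_validate <- function(pheno, label, kernels, folds,
                           settings = mcmc_settings(), trait = "y",
                           fixed = NULL, class = NULL) {
  stopifnot(inherits(folds, "holo_folds"))
  n <- nrow(pheno)
  if (attr(folds, "n") != n) {
    stop_holo(sprintf("folds were built for %d samples, data has %d",
                      attr(folds, "n"), n))
  }
  if (anyNA(pheno[[trait]])) {
    stop_holo("cross-validation needs fully observed phenotypes")
  }
  sizes <- dplyr::count(folds, .data$repeat_index, .data$fold)
  if (any(sizes$n < 3)) {
    stop_holo("a fold has fewer than 3 validation samples; r-squared would be unstable — use fewer folds")
  }

  # the kernels are identical across folds (masked animals stay in them),
  # so their eigendecompositions are computed once and reused
  full_spec <- build_model(pheno, label, kernels, trait = trait,
                           fixed = fixed, class = class)
  eigs <- kernel_eigens(full_spec, settings$eig_tol)

  per_fold <- purrr::map_dfr(seq_len(attr(folds, "repeats")), function(r) {
    fid <- folds$fold[folds$repeat_index == r]
    purrr::map_dfr(sort(unique(fid)), function(f) {
      val <- which(fid == f)
      ph <- pheno
      ph[[trait]][val] <- NA
      spec <- build_model(ph, label, kernels, trait = trait,
                          fixed = fixed, class = class)
      st <- settings
      st$seed <- child_seed(settings$seed, 11, r, f)
      fit <- holo_fit(spec, ph, st, eig_cache = eigs)
      pred <- predict(fit, samples = as.character(pheno$sample_id)[val])
      tibble(repeat_index = r, fold = f, n_val = length(val),
             r2 = r_squared(pheno[[trait]][val], pred$y_hat))
    })
  })

  per_repeat <- per_fold |>
    dplyr::group_by(.data$repeat_index) |>
    dplyr::summarise(r2 = mean(.data$r2), .groups = "drop")

  structure(list(
    label = label,
    per_fold = per_fold,
    per_repeat = per_repeat,
    mean_r2 = mean(per_repeat$r2),
    sd_r2 = sd(per_repeat$r2),
    fingerprint = sprintf("k=%d repeats=%d fold_seed=%d mcmc_seed=%d iter=%d",
                          attr(folds, "k"), attr(folds, "repeats"),
                          attr(folds, "seed"), settings$seed,
                          settings$n_iter)
  ), class = "holo_cv")
}

#' @export
print.holo_cv <- function(x, ...) {
  cat(sprintf("<holo_cv '%s'> mean r2 = %.3f +/- %.3f over %d repeats x %d folds\n",
              x$label, x$mean_r2, x$sd_r2, nrow(x$per_repeat),
              max(x$per_fold$fold)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.holo_cv <- function(x, ...) {
  dplyr::mutate(x$per_fold, label = x$label, .before = 1)
}

#' @exportS3Method generics::glance
glance.holo_cv <- function(x, ...) {
  tibble(label = x$label, mean_r2 = x$mean_r2, sd_r2 = x$sd_r2,
         se_r2 = x$sd_r2 / sqrt(nrow(x$per_repeat)),
         repeats = nrow(x$per_repeat))
}

#' Compare model accuracies by one-way ANOVA with Tukey HSD
#'
#' Tests whether the per-repeat cross-validated r-squared values differ
#' across models: a one-way ANOVA on model label, followed by Tukey honest
#' significant difference pairwise comparisons at level `alpha`.
#'
#' @param results List of [cross_validate()] results (at least 2), each
#'   with the same number of repeats.
#' @param alpha Significance level for the pairwise flags (default 0.05).
#' @return A `holo_comparison` with `F_statistic`, `p_value`, and
#'   `pairwise` (tibble: pair, diff, p_adj, significant).
#' @export
compare_models <- function(results, alpha = 0.05) {
  if (length(results) < 2) stop_holo("need at least 2 models to compare")
  stopifnot(all(vapply(results, inherits, logical(1), "holo_cv")))
  reps <- vapply(results, function(x) nrow(x$per_repeat), integer(1))
  if (length(unique(reps)) != 1) {
    stop_holo(sprintf("models have unequal repeat counts: %s",
                      paste(reps, collapse = ", ")))
  }
  labels <- vapply(results, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  long <- purrr::map2_dfr(results, labels, function(x, lb) {
    tibble(model = lb, r2 = x$per_repeat$r2)
  })
  long$model <- factor(long$model, levels = labels)

  grand <- mean(long$r2)
  gm <- tapply(long$r2, long$model, mean)
  ssb <- sum(reps[1] * (gm - grand)^2)
  fit <- aov(r2 ~ model, data = long)
  sm <- summary(fit)[[1]]
  if (ssb <= .Machine$double.eps * max(1, sum(long$r2^2))) {
    # identical group means: no between-model signal by construction
    Fst <- 0; pval <- 1
  } else {
    Fst <- sm[["F value"]][1]
    pval <- sm[["Pr(>F)"]][1]
  }
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$model
  pw <- tibble(pair = rownames(tk),
               diff = tk[, "diff"],
               lwr = tk[, "lwr"], upr = tk[, "upr"],
               p_adj = ifelse(is.nan(tk[, "p adj"]) & tk[, "diff"] == 0,
                              1, tk[, "p adj"]))
  pw$significant <- pw$p_adj < alpha
  structure(list(F_statistic = Fst, p_value = pval, alpha = alpha,
                 pairwise = pw, per_repeat = long),
            class = "holo_comparison")
}

#' @export
print.holo_comparison <- function(x, ...) {
  cat(sprintf("<holo_comparison> one-way ANOVA F = %.3f, p = %.3g (alpha = %g)\n",
              x$F_statistic, x$p_value, x$alpha))
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.holo_comparison <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.holo_comparison <- function(x, ...) {
  tibble(F_statistic = x$F_statistic, p_value = x$p_value,
         n_models = nlevels(x$per_repeat$model), alpha = x$alpha)
}
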