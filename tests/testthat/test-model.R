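test_that("model labels map to the kernel terms they require", {
  sim <- quick_sim(n = 40, seed = 1)
  ks <- suppressWarnings(build_kernel_set(sim$genotypes, sim$otus))

  spec_g <- build_model(sim$phenotypes, "genomic", ks)
  expect_identical(names(spec_g$kernels), "g")
  spec_d <- build_model(sim$phenotypes, "direct", ks)
  expect_identical(names(spec_d$kernels), c("g", "m"))
  spec_h <- build_model(sim$phenotypes, "hadamard", ks)
  expect_identical(names(spec_h$kernels), c("g", "m", "gm"))

  # hadamard without its interaction kernel is an error naming the kind
  expect_error(build_model(sim$phenotypes, "hadamard", ks[c("G", "M")]),
               "HADAMARD")
  expect_error(build_model(sim$phenotypes, "kronecker", ks), "valid labels")
  expect_error(build_model(sim$phenotypes, "direct", ks, fixed = "age"),
               "age")

  # farm is picked up as a fixed covariate, diet as a class effect
  expect_identical(spec_d$fixed_terms, "farm")
  expect_identical(spec_d$class_terms, "diet")
})

test_that("mcmc settings are validated", {
  expect_error(mcmc_settings(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_settings(thin = 0), "thin")
  expect_error(mcmc_settings(bayesb_pi = 1), "bayesb_pi")
})

test_that("the intercept-only model recovers the phenotype mean", {
  set.seed(11)
  ph <- tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                       y = rnorm(100, 3, 1))
  # a kernel term with its variance pinned to ~0 makes this intercept-only
  spec <- build_model(ph, "genomic", list(holo_kernel(diag(100), "GRM")))
  fit <- holo_fit(spec, ph, quick_settings(seed = 2,
                                           fix_variances = list(g = 1e-10)))
  expect_equal(fit$fixed_effects$post_mean[1], mean(ph$y), tolerance = 0.02)
})

test_that("chains are exactly reproducible under a fixed seed", {
  sim <- quick_sim(n = 60, seed = 4)
  ks <- suppressWarnings(build_kernel_set(sim$genotypes, sim$otus,
                                          models = "direct"))
  spec <- build_model(sim$phenotypes, "direct", ks)
  f1 <- holo_fit(spec, sim$phenotypes, quick_settings(seed = 5))
  f2 <- holo_fit(spec, sim$phenotypes, quick_settings(seed = 5))
  expect_identical(f1$var_samples, f2$var_samples)
  expect_identical(f1$yhat, f2$yhat)
  f3 <- holo_fit(spec, sim$phenotypes, quick_settings(seed = 6))
  expect_false(identical(f1$var_samples, f3$var_samples))
})

test_that("fitted components and residuals reconstruct the phenotype at the last sweep", {
  sim <- quick_sim(n = 60, seed = 8)
  ks <- suppressWarnings(build_kernel_set(sim$genotypes, sim$otus,
                                          models = "hadamard"))
  spec <- build_model(sim$phenotypes, "hadamard", ks)
  ph <- sim$phenotypes
  ph$y[1:6] <- NA  # masked samples participate via data augmentation
  fit <- holo_fit(spec, ph, quick_settings(seed = 3))
  st <- fit$last_state
  recon <- st$fixed + Reduce(`+`, st$blocks, rep(0, 60)) +
    Reduce(`+`, st$kernels, rep(0, 60)) + st$residual
  expect_equal(unname(recon), unname(st$y_full), tolerance = 1e-8)
  # observed entries of the augmented phenotype are the data themselves
  expect_equal(st$y_full[-(1:6)], ph$y[-(1:6)], tolerance = 1e-12)
})

test_that("with fixed variance components the posterior mean equals the closed-form BLUP", {
  sim <- simulate_holoomics(sim_params(
    n_samples = 100, n_snps = 300, n_otus = 60, var_g = 0.5, var_m = 0,
    var_gm = 0, var_e = 0.5, fixed_effect_levels = 1,
    class_effect_levels = 1, seed = 12))
  ph <- sim$phenotypes[, c("sample_id", "y")]
  G <- sim$kernels$G
  spec <- build_model(ph, "genomic", list(G))
  fit <- holo_fit(spec, ph, mcmc_settings(
    n_iter = 4000, burn_in = 1000, thin = 2, seed = 13,
    fix_variances = list(g = 0.5, e = 0.5)))
  oracle <- oracle_blup(ph$y, unclass(G), matrix(1, 100, 1), 0.5, 0.5)
  expect_lt(sqrt(mean((fit$component_means$g - oracle$u)^2)), 0.02)
})

test_that("BayesB with pi = 0 and rigid effect variance reduces to ridge regression", {
  set.seed(42)
  n <- 100; L <- 25
  ph <- tibble::tibble(sample_id = sprintf("S%03d", 1:n), y = NA_real_,
                       pen = sample(sprintf("p%02d", 1:L), n, replace = TRUE))
  W <- model.matrix(~ 0 + factor(ph$pen))
  ph$y <- 1 + as.numeric(W %*% rnorm(ncol(W), 0, 0.5)) + rnorm(n, 0, 0.6)
  s2a <- 0.25; s2e <- 0.36
  spec <- build_model(ph, "genomic", list(holo_kernel(diag(n), "GRM")),
                      fixed = character(0), class = "pen")
  fit <- holo_fit(spec, ph, mcmc_settings(
    n_iter = 6000, burn_in = 1000, thin = 2, seed = 5,
    bayesb_pi = 0, bayesb_df = 1e8, bayesb_scale = s2a,
    fix_variances = list(g = 1e-8, e = s2e)))
  # closed-form ridge at matched lambda = s2e / s2a, intercept unpenalised
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + diag(s2e / s2a, ncol(W))))
  a_ridge <- solve(C, c(crossprod(X, ph$y), crossprod(W, ph$y)))[-1]
  a_hat <- fit$class_effect_means[[1]]
  expect_lt(sqrt(mean((a_hat - a_ridge)^2)) / sd(a_ridge), 0.05)
})

test_that("a kernel whose simulated variance is zero is shrunk towards zero", {
  # needs a study-scale n so the likelihood dominates the variance prior
  fr <- sapply(1:3, function(s) {
    sim <- simulate_holoomics(sim_params(
      n_samples = 400, n_snps = 300, n_otus = 80, var_g = 0.5, var_m = 0,
      var_gm = 0, var_e = 0.5, seed = 20 + s))
    ks <- suppressWarnings(build_kernel_set(sim$genotypes, sim$otus,
                                            models = "direct"))
    spec <- build_model(sim$phenotypes, "direct", ks)
    fit <- holo_fit(spec, sim$phenotypes,
                    quick_settings(seed = 30 + s, n_iter = 2000,
                                   burn_in = 500))
    vf <- variance_fractions(fit)
    vf$fraction[vf$term == "m"]
  })
  expect_lt(mean(fr), 0.1)
})

test_that("posterior variance components are calibrated against their prior (prior-predictive check)", {
  # draw variances from the prior, simulate data, refit with the same
  # prior: averaged over replicates the posterior means must match the
  # prior mean (coarse tolerance; this is a distributional identity)
  n <- 60
  G <- holo_kernel(random_psd(n, 99), "GRM")
  Gn <- normalise_kernel(G)
  eg <- eigen(unclass(Gn), symmetric = TRUE)
  df <- 6; S <- 0.5
  prior_mean <- df * S / (df - 2)
  set.seed(321)
  reps <- replicate(50, {
    s2g <- df * S / rchisq(1, df)
    s2e <- df * S / rchisq(1, df)
    g <- as.numeric(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n))) *
      sqrt(s2g)
    ph <- tibble::tibble(sample_id = rownames(Gn),
                         y = 2 + g + rnorm(n, 0, sqrt(s2e)))
    spec <- build_model(ph, "genomic", list(Gn))
    fit <- holo_fit(spec, ph, mcmc_settings(
      n_iter = 700, burn_in = 200, thin = 2,
      seed = sample.int(1e6, 1), vc_df = df, vc_scale = S,
      resid_df = df, resid_scale = S))
    c(post = fit$var_components$post_mean[fit$var_components$term == "sigma2_g"],
      truth = s2g)
  })
  # paired comparison (posterior mean tracks the drawn truth, so the
  # replicate-averaged difference is the low-variance unbiasedness check)
  expect_equal(mean(reps[1, ] - reps[2, ]), 0,
               tolerance = 0.2 * prior_mean)
  expect_equal(mean(reps[1, ]), prior_mean,
               tolerance = 0.45 * prior_mean)
})

test_that("predictions cover exactly the masked samples, in any requested order", {
  sim <- quick_sim(n = 60, seed = 14)
  ks <- suppressWarnings(build_kernel_set(sim$genotypes, sim$otus,
                                          models = "genomic"))
  ph <- sim$phenotypes
  spec <- build_model(ph, "genomic", ks)
  fit0 <- holo_fit(spec, ph, quick_settings(seed = 1))
  expect_equal(nrow(predict(fit0)), 0)

  masked <- c(5, 12, 33)
  ph$y[masked] <- NA
  spec <- build_model(ph, "genomic", ks)
  fit <- holo_fit(spec, ph, quick_settings(seed = 1))
  pr <- predict(fit)
  expect_identical(pr$sample_id, ph$sample_id[masked])
  # permutation invariance
  shuffled <- rev(ph$sample_id[masked])
  pr2 <- predict(fit, samples = shuffled)
  expect_equal(pr2$y_hat, unname(pr$y_hat[match(shuffled, pr$sample_id)]))
  expect_error(predict(fit, samples = "nobody"), "not part of the fit")
})

test_that("noiseless genomic signal in a low-dimensional SNP space is predicted almost perfectly", {
  # with many more samples than SNPs, the genomic effect of a masked
  # animal lies in the span learnt from the training set
  sim <- simulate_holoomics(sim_params(
    n_samples = 300, n_snps = 80, n_otus = 40, var_g = 1, var_m = 0,
    var_gm = 0, var_e = 0, fixed_effect_levels = 1, class_effect_levels = 1,
    seed = 15))
  ph <- sim$phenotypes[, c("sample_id", "y")]
  set.seed(16)
  masked <- sort(sample(300, 30))
  truth <- ph$y[masked]
  ph$y[masked] <- NA
  spec <- build_model(ph, "genomic", list(sim$kernels$G))
  fit <- holo_fit(spec, ph, mcmc_settings(n_iter = 2000, burn_in = 500,
                                          thin = 2, seed = 17))
  expect_gt(r_squared(truth, predict(fit)$y_hat), 0.9)
})
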