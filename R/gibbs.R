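# Gibbs sampler for the multi-kernel Bayesian linear mixed model.
#
# y = X beta + sum_b W_b a_b + sum_k u_k + e
#   beta  ~ flat               (joint conjugate update)
#   a_bj  ~ BayesB mixture     (point mass at 0 w.p. pi, else N(0, s2_bj)
#                               with s2_bj ~ scaled-inv-chi2(df, S)), or a
#                               common Gaussian variance per block
#   u_k   ~ N(0, s2_k K_k)     sampled jointly in the orthonormal eigenbasis
#                               of K_k (u_k = U alpha, alpha_i ~ N(0, d_i s2_k))
#   e     ~ N(0, s2_e I)
#
# Missing phenotypes are data-augmented: redrawn from N(lp, s2_e) each sweep,
# which is exact Gibbs for the posterior given the observed entries only.

rinvchisq <- function(df, scale) df * scale / rchisq(1, df)

gibbs_sampler <- function(y, X, blocks, eigs, settings) {
  set.seed(settings$seed)
  n <- length(y)
  miss <- which(is.na(y))
  obs <- setdiff(seq_len(n), miss)
  y_full <- y
  y_full[miss] <- mean(y[obs])
  vy <- var(y[obs])
  if (!is.finite(vy) || vy <= 0) vy <- 1

  n_random <- length(eigs) + length(blocks)
  target <- settings$r2_prior * vy / max(1, n_random)

  df_vc <- settings$vc_df
  S_vc <- settings$vc_scale %||% (target * (df_vc + 2) / df_vc)
  df_e <- settings$resid_df
  S_e <- settings$resid_scale %||%
    ((1 - settings$r2_prior) * vy * (df_e + 2) / df_e)
  df_b <- settings$bayesb_df
  pi_b <- settings$bayesb_pi
  gaussian_blocks <- settings$class_effects == "gaussian"

  fixv <- settings$fix_variances %||% list()

  ## fixed part
  f <- ncol(X)
  XtX <- crossprod(X)
  Rx <- chol(XtX)
  beta <- rep(0, f)
  Xb <- rep(0, n)

  ## BayesB / Gaussian blocks
  nb <- length(blocks)
  block_state <- lapply(blocks, function(W) {
    msx <- sum(apply(W, 2, var))
    Sb <- settings$bayesb_scale %||%
      (target * (df_b + 2) / df_b /
         max(msx * (if (gaussian_blocks) 1 else 1 - pi_b), 1e-8))
    list(W = W, cxx = colSums(W^2), a = rep(0, ncol(W)),
         s2 = rep(Sb, ncol(W)), Sb = Sb, contrib = rep(0, n),
         s2_common = Sb)
  })

  ## kernel terms
  nk <- length(eigs)
  kn <- names(eigs)
  u <- lapply(eigs, function(e) rep(0, n))
  s2_k <- setNames(rep(target, max(nk, 1))[seq_len(nk)], kn)
  for (tm in kn) if (!is.null(fixv[[tm]])) s2_k[tm] <- fixv[[tm]]
  s2_e <- if (!is.null(fixv[["e"]])) fixv[["e"]] else (1 - settings$r2_prior) * vy

  e_vec <- y_full - Xb

  n_kept <- 0L
  vc_names <- c(kn, if (gaussian_blocks) names(blocks), "e")
  kept_total <- (settings$n_iter - settings$burn_in) %/% settings$thin
  var_samples <- matrix(NA_real_, kept_total, length(vc_names),
                        dimnames = list(NULL, vc_names))
  beta_acc <- rep(0, f)
  lp_acc <- rep(0, n)
  u_acc <- lapply(seq_len(nk), function(i) rep(0, n))
  block_acc <- lapply(blocks, function(W) rep(0, ncol(W)))

  for (it in seq_len(settings$n_iter)) {
    ## fixed effects (flat prior, joint conjugate draw)
    r <- e_vec + Xb
    mu_b <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, r)))
    beta <- as.numeric(mu_b + sqrt(s2_e) * backsolve(Rx, rnorm(f)))
    Xb <- as.numeric(X %*% beta)
    e_vec <- r - Xb

    ## class-effect blocks
    for (b in seq_len(nb)) {
      st <- block_state[[b]]
      for (j in seq_along(st$a)) {
        w <- st$W[, j]
        rj <- if (st$a[j] != 0) e_vec + w * st$a[j] else e_vec
        rhs <- sum(w * rj)
        s2j <- if (gaussian_blocks) st$s2_common else st$s2[j]
        prec <- st$cxx[j] / s2_e + 1 / s2j
        mu <- rhs / s2_e / prec
        include <- TRUE
        if (!gaussian_blocks && pi_b > 0) {
          logbf <- 0.5 * (-log(s2j * prec) + mu^2 * prec)
          logit <- log((1 - pi_b) / pi_b) + logbf
          include <- runif(1) < 1 / (1 + exp(-logit))
        }
        st$a[j] <- if (include) rnorm(1, mu, sqrt(1 / prec)) else 0
        e_vec <- rj - if (st$a[j] != 0) w * st$a[j] else 0
        if (!gaussian_blocks) {
          st$s2[j] <- rinvchisq(df_b + include,
                                (st$a[j]^2 + df_b * st$Sb) / (df_b + include))
        }
      }
      if (gaussian_blocks) {
        tmv <- names(blocks)[b]
        if (is.null(fixv[[tmv]])) {
          st$s2_common <- rinvchisq(
            df_vc + length(st$a),
            (sum(st$a^2) + df_vc * S_vc) / (df_vc + length(st$a)))
        } else st$s2_common <- fixv[[tmv]]
      }
      st$contrib <- as.numeric(st$W %*% st$a)
      block_state[[b]] <- st
    }

    ## kernel (RKHS) effects, jointly in the eigenbasis
    for (k in seq_len(nk)) {
      eg <- eigs[[k]]
      rk <- e_vec + u[[k]]
      z <- crossprod(eg$U, rk)
      prec <- 1 / s2_e + 1 / (eg$d * s2_k[k])
      alpha <- z / s2_e / prec + rnorm(length(eg$d)) / sqrt(prec)
      u[[k]] <- as.numeric(eg$U %*% alpha)
      e_vec <- rk - u[[k]]
      if (is.null(fixv[[kn[k]]])) {
        ss <- sum(alpha^2 / eg$d)
        s2_k[k] <- rinvchisq(df_vc + length(eg$d),
                             (ss + df_vc * S_vc) / (df_vc + length(eg$d)))
      }
    }

    ## residual variance
    if (is.null(fixv[["e"]])) {
      s2_e <- rinvchisq(df_e + n, (sum(e_vec^2) + df_e * S_e) / (df_e + n))
    }
    if (!is.finite(s2_e) || s2_e <= 0) {
      stop_holo("residual variance became non-finite; check kernel conditioning")
    }

    ## data augmentation for masked phenotypes
    if (length(miss)) {
      lp_miss <- y_full[miss] - e_vec[miss]
      draw <- rnorm(length(miss), 0, sqrt(s2_e))
      y_full[miss] <- lp_miss + draw
      e_vec[miss] <- draw
    }

    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thin == 0) {
      n_kept <- n_kept + 1L
      var_samples[n_kept, ] <- c(
        s2_k,
        if (gaussian_blocks) vapply(block_state, `[[`, numeric(1), "s2_common"),
        s2_e)
      beta_acc <- beta_acc + beta
      lp_acc <- lp_acc + (y_full - e_vec)
      for (k in seq_len(nk)) u_acc[[k]] <- u_acc[[k]] + u[[k]]
      for (b in seq_len(nb)) block_acc[[b]] <- block_acc[[b]] + block_state[[b]]$a
    }
  }

  if (n_kept == 0) stop_holo("no posterior draws kept; increase n_iter")
  list(
    var_samples = var_samples[seq_len(n_kept), , drop = FALSE],
    beta_mean = beta_acc / n_kept,
    lp_mean = lp_acc / n_kept,
    u_means = setNames(lapply(u_acc, function(v) v / n_kept), kn),
    block_means = lapply(block_acc, function(v) v / n_kept),
    n_kept = n_kept,
    last_state = list(
      y_full = y_full,
      fixed = Xb,
      blocks = lapply(block_state, `[[`, "contrib"),
      kernels = u,
      residual = e_vec
    )
  )
}
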