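# Independent brute-force oracles, deliberately naive: double loops and
# step-by-step arithmetic, sharing no code with the package internals.

# VanRaden GRM by explicit double loop over sample pairs
oracle_grm <- function(Z, p = NULL) {
  if (is.null(p)) p <- colMeans(Z) / 2
  n <- nrow(Z)
  denom <- 0
  for (m in seq_along(p)) denom <- denom + 2 * p[m] * (1 - p[m])
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (m in seq_along(p)) {
      s <- s + (Z[i, m] - 2 * p[m]) * (Z[j, m] - 2 * p[m])
    }
    G[i, j] <- s / denom
  }
  G
}

# MRM by the hand pipeline: relative abundance -> pseudocount -> log ->
# per-OTU standardisation -> RR'/q
oracle_mrm <- function(counts) {
  ra <- counts / rowSums(counts)
  half_min <- min(ra[ra > 0]) / 2
  ra[ra == 0] <- half_min
  r <- log(ra)
  keep <- apply(r, 2, function(x) var(x) > 0)
  r <- r[, keep, drop = FALSE]
  for (j in seq_len(ncol(r))) {
    r[, j] <- (r[, j] - mean(r[, j])) / sd(r[, j])
  }
  (r %*% t(r)) / ncol(r)
}

oracle_hadamard <- function(G, M) {
  K <- matrix(0, nrow(G), ncol(G))
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
    K[i, j] <- G[i, j] * M[i, j]
  }
  K
}

oracle_core <- function(G, M) {
  LG <- t(chol(G))
  LM <- t(chol(M))
  (LG %*% t(LM) + LM %*% t(LG)) / 2
}

# mixed-model-equation BLUP with known variance components
oracle_blup <- function(y, G, X, s2g, s2e) {
  V <- s2g * G + diag(s2e, length(y))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2g * G %*% Vi %*% (y - X %*% beta)
  list(beta = as.numeric(beta), u = as.numeric(u))
}

# one-way ANOVA F by manual sum-of-squares decomposition
oracle_anova_F <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# random PSD matrix with unit-scale diagonal
random_psd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 2)), n, n + 2)
  K <- A %*% t(A) / (n + 2)
  (K + t(K)) / 2
}
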