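# Independent oracle implementations used to cross-check the package.
# These are deliberately written from first principles (loops, textbook
# formulas) and share no code with the implementation under test.

# One-way random-effects Gibbs sampler (single trait, Gaussian errors,
# balanced replicates, conjugate inverse-gamma priors): the no-marker limit
# of the hierarchical model. Textbook Gibbs scan.
oracle_oneway_gibbs <- function(y, group, n_iter, burnin, seed,
                                prior_df = 2, prior_scale = 1e-4,
                                mu_var = 1e6) {
  set.seed(seed)
  groups <- unique(group)
  J <- length(groups)
  idx <- lapply(groups, function(g) which(group == g))
  nj <- lengths(idx)
  mu <- mean(y)
  alpha <- vapply(idx, function(i) mean(y[i]), 0)
  s2a <- var(alpha)
  s2e <- var(y - alpha[match(group, groups)])
  keep_a <- keep_e <- numeric(n_iter - burnin)
  for (it in seq_len(n_iter)) {
    # group means
    for (j in seq_len(J)) {
      prec <- nj[j] / s2e + 1 / s2a
      m <- (sum(y[idx[[j]]]) / s2e + mu / s2a) / prec
      alpha[j] <- rnorm(1, m, sqrt(1 / prec))
    }
    # grand mean
    prec <- J / s2a + 1 / mu_var
    mu <- rnorm(1, sum(alpha) / s2a / prec, sqrt(1 / prec))
    # variance components (conjugate scaled-inverse-chi-squared)
    ssa <- sum((alpha - mu)^2)
    s2a <- 1 / rgamma(1, (prior_df + J) / 2, (prior_scale + ssa) / 2)
    sse <- sum((y - alpha[match(group, groups)])^2)
    s2e <- 1 / rgamma(1, (prior_df + length(y)) / 2, (prior_scale + sse) / 2)
    if (it > burnin) {
      keep_a[it - burnin] <- s2a
      keep_e[it - burnin] <- s2e
    }
  }
  list(s2a = keep_a, s2e = keep_e)
}

# Brute-force VanRaden kinship via explicit loops.
oracle_vanraden <- function(X) {
  n <- nrow(X); m <- ncol(X)
  p <- colSums(X) / (2 * n)
  denom <- 2 * sum(p * (1 - p))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) s <- s + (X[i, k] - 2 * p[k]) * (X[j, k] - 2 * p[k])
    K[i, j] <- s / denom
  }
  K
}

# Brute-force centered cross-product kernel via triple loop.
oracle_crossproduct <- function(X) {
  n <- nrow(X); m <- ncol(X)
  cm <- colSums(X) / n
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) s <- s + (X[i, k] - cm[k]) * (X[j, k] - cm[k])
    K[i, j] <- s / n
  }
  K
}

# Closed-form simple linear regression (slope, t, two-sided p).
oracle_ols <- function(y, x) {
  n <- length(y)
  xc <- x - mean(x); yc <- y - mean(y)
  b <- sum(xc * yc) / sum(xc^2)
  res <- yc - b * xc
  se <- sqrt(sum(res^2) / (n - 2) / sum(xc^2))
  t <- b / se
  list(slope = b, se = se, t = t, p = 2 * pt(-abs(t), n - 2))
}

# Closed-form BLUP prediction with fixed variance components.
oracle_blup <- function(y1, K11, K21, lambda) {
  n1 <- length(y1)
  A <- K11 + diag(lambda, n1)
  Ai <- solve(A)
  one <- rep(1, n1)
  mu <- sum(Ai %*% y1) / sum(Ai %*% one)
  as.vector(mu + K21 %*% Ai %*% (y1 - mu))
}

# Small simulated panel shared across tests.
toy_panel <- function(n_acc = 60, n_snps = 300, h2 = 0.5, bg = 0,
                      n_rep = 6, seed = 42, n_causal = 20,
                      causal_range = c(0.2, 0.5), in_panel = TRUE,
                      maf = list(dist = "uniform", min = 0.05, max = 0.5),
                      error_df = Inf) {
  spec <- sim_spec(n_accessions = n_acc, n_snps = n_snps,
                   n_causal = n_causal, causal_maf_range = causal_range,
                   causal_in_panel = in_panel, maf = maf,
                   target_marker_h2 = h2, target_background_var = bg,
                   error_var = 1, n_replicates = n_rep, error_df = error_df,
                   seed = seed)
  G <- simulate_genotypes(spec)
  sim <- simulate_phenotypes(G, spec)
  list(spec = spec, G = G, phenotypes = sim$phenotypes, truth = sim$truth)
}
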