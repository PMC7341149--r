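# Internal numerical helpers shared across modules.

# Draw n rows from N_d(0, Sigma) via Cholesky (eigen fallback for
# semidefinite Sigma, including the all-zero degenerate case).
rmvn <- function(n, Sigma) {
  d <- nrow(Sigma)
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen(Sigma, symmetric = TRUE)
    L <- t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), d))
  }
  matrix(stats::rnorm(n * d), n, d) %*% L
}

# Draw from inverse-Wishart IW(df, S): X ~ W(df, S^-1), return X^-1.
riwish <- function(df, S) {
  Sinv <- chol2inv(chol(S))
  W <- stats::rWishart(1L, df, Sinv)[, , 1L]
  chol2inv(chol(W))
}

# Symmetrize a nearly-symmetric matrix (guards accumulated round-off).
symm <- function(M) (M + t(M)) / 2

check_symmetric <- function(M, what = "matrix", tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M) ||
      max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop(what, " must be a symmetric square matrix", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Univariate slice sampler (Neal 2003: stepping out + shrinkage).
# logf must return -Inf outside the support.
slice_sample1 <- function(x0, logf, w = 1, max_step = 30) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started outside support", call. = FALSE)
  y <- f0 + log(stats::runif(1))
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_step * stats::runif(1))
  k <- max_step - 1 - j
  while (j > 0 && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}
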