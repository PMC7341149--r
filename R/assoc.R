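# Two-step genome-wide association: a maximum-likelihood mixed model on
# posterior accession modes corrects for population structure via the
# genomic relationship matrix; its residuals feed per-SNP regressions.

#' Per-accession response vector from posterior samples
#'
#' Extracts posterior modes of the accession means for one trait
#' (`transform = "identity"`), or the log10 ratio of two traits' modes
#' (`transform = "log_ratio"` — e.g. treated over control root length, an
#' aluminum-tolerance index).
#'
#' @param samples An `hb_samples` object.
#' @param transform `"identity"` or `"log_ratio"`.
#' @param trait Trait (numerator under `log_ratio`).
#' @param trait2 Denominator trait under `log_ratio`.
#' @return Named numeric vector over accessions.
#' @export
accession_responses <- function(samples, transform = c("identity", "log_ratio"),
                                trait = 1, trait2 = NULL) {
  transform <- match.arg(transform)
  p <- trait_index(samples, trait)
  modes <- apply(samples$mu_acc[, , p, drop = FALSE], 2, posterior_mode)
  names(modes) <- samples$accessions
  if (transform == "identity") return(modes)
  if (is.null(trait2)) stop("log_ratio requires trait2", call. = FALSE)
  q <- trait_index(samples, trait2)
  modes2 <- apply(samples$mu_acc[, , q, drop = FALSE], 2, posterior_mode)
  bad <- modes <= 0 | modes2 <= 0
  if (any(bad))
    stop("non-positive posterior mode under log_ratio for accession(s): ",
         paste(utils::head(samples$accessions[bad], 5), collapse = ", "),
         call. = FALSE)
  stats::setNames(log10(modes) - log10(modes2), samples$accessions)
}

#' Fit the null mixed model for association scanning
#'
#' Maximum-likelihood fit of \eqn{y = 1\mu + u + e} with
#' \eqn{u \sim N(0, K\sigma^2_u)}, \eqn{e \sim N(0, I\sigma^2_e)}, via 1-D
#' optimization of the profile likelihood over the variance ratio on the
#' spectral decomposition of `K` (the EMMA device). Returns the ML variance
#' components, the BLUP of `u`, and the residuals `y - 1mu - u` used by
#' [snp_scan()]. Boundary optima (a variance component at zero) are valid
#' fits and flagged in the result.
#'
#' @param y Numeric response vector (posterior accession modes).
#' @param K A `relationship_kernel` or PSD matrix matching `y` in order.
#' @return An object of class `mixed_model_fit` with `mu`, `sigma_u2`,
#'   `sigma_e2`, `lambda` (= sigma_e2/sigma_u2), `residuals`, `loglik`,
#'   `boundary`.
#' @export
fit_null <- function(y, K) {
  M <- if (inherits(K, "relationship_kernel")) K$K else K
  check_symmetric(M, "kernel")
  n <- length(y)
  stopifnot(nrow(M) == n)
  e <- eigen(symm(M), symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop("kernel is not positive semidefinite", call. = FALSE)
  vals <- pmax(e$values, 0)
  yt <- crossprod(e$vectors, y)[, 1]
  ot <- crossprod(e$vectors, rep(1, n))[, 1]
  # Restrict the likelihood to eigen-directions with non-zero eigenvalue:
  # genomic kernels built from centered dosages have the intercept direction
  # in their null space, where the fixed effect absorbs the data exactly and
  # full ML is unbounded as sigma_e2 -> 0. For full-rank kernels (e.g.
  # K = I) nothing is dropped and this is plain ML.
  keep <- vals > 1e-10 * max(vals, 1)
  m <- sum(keep)
  vk <- vals[keep]; yk <- yt[keep]; ok <- ot[keep]
  # when the intercept direction lies in the dropped null space (as it does
  # for centered genomic kernels) it is orthogonal to the retained
  # coordinates; estimate mu from the data mean instead of a 0/0 GLS ratio
  mu_estimable <- sum(ok^2) > 1e-8 * n
  est_mu <- function(dv) {
    if (mu_estimable) sum(ok * yk / dv) / sum(ok^2 / dv) else mean(y)
  }

  # profile negative log-likelihood in delta = sigma_e2 / sigma_u2
  nll <- function(log_delta) {
    delta <- exp(log_delta)
    dv <- vk + delta
    mu <- est_mu(dv)
    rt <- yk - mu * ok
    s2u <- sum(rt^2 / dv) / m          # ML estimate of sigma_u2
    0.5 * (m * log(2 * pi * s2u) + sum(log(dv)) + m)
  }
  opt <- stats::optimize(nll, c(-14, 14), tol = 1e-10)
  # compare against the OLS boundary (sigma_u2 -> 0), same subspace
  mu_ols <- if (mu_estimable) sum(ok * yk) / sum(ok^2) else mean(y)
  s2_ols <- sum((yk - mu_ols * ok)^2) / m
  ll_ols <- -0.5 * (m * log(2 * pi * s2_ols) + m)
  ll_mm <- -opt$objective
  boundary <- FALSE
  if (ll_ols >= ll_mm) {
    mu <- mu_ols; s2u <- 0; s2e <- s2_ols; delta <- Inf
    resid <- y - mu
    ll <- ll_ols
    boundary <- TRUE
  } else {
    delta <- exp(opt$minimum)
    dv <- vk + delta
    mu <- est_mu(dv)
    rt <- yk - mu * ok
    s2u <- sum(rt^2 / dv) / m
    s2e <- delta * s2u
    # BLUP of u: sigma_u2 K V^{-1} (y - 1 mu); in spectral coordinates
    # u_t = vals/(vals+delta) * rt (zero automatically in the null space)
    rt_full <- yt - mu * ot
    ut <- vals / (vals + delta) * rt_full
    resid <- as.vector(e$vectors %*% (rt_full - ut))
    ll <- ll_mm
    boundary <- abs(opt$minimum) > 13.9
  }
  structure(list(mu = mu, sigma_u2 = s2u, sigma_e2 = s2e, lambda = delta,
                 residuals = stats::setNames(resid, names(y)),
                 loglik = ll, boundary = boundary,
                 eigen = list(values = vals, vectors = e$vectors)),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("mixed_model_fit: mu = %.4g, sigma_u2 = %.4g, sigma_e2 = %.4g, logLik = %.3f%s\n",
              x$mu, x$sigma_u2, x$sigma_e2, x$loglik,
              if (x$boundary) " (boundary optimum)" else ""))
  invisible(x)
}

#' Per-SNP regression scan on mixed-model residuals
#'
#' Simple linear regression of the null-model residuals on each SNP's dosage;
#' two-sided p-values from the t distribution with `Nacc - 2` degrees of
#' freedom, reported as -log10(p) effect scores. Monomorphic SNPs get an
#' `NA` score with a reason. The genotype matrix must be complete (impute
#' first) and is matched to the fit by accession id when rownames are
#' available.
#'
#' @param fit A `mixed_model_fit`.
#' @param G A complete [genotype_matrix()].
#' @param trait Optional trait label carried into the output.
#' @return A data.frame (class `gwa_result`) with columns `snp_id`, `chrom`,
#'   `pos`, `effect`, `se`, `neglog10p`, `reason`.
#' @export
snp_scan <- function(fit, G, trait = NA_character_) {
  X <- G$dosage
  if (any(is.na(X)))
    stop("snp_scan requires a complete dosage matrix; run impute_missing()",
         call. = FALSE)
  r <- fit$residuals
  if (!is.null(names(r)) && !is.null(rownames(X)) &&
      all(names(r) %in% rownames(X))) {
    X <- X[names(r), , drop = FALSE]
  }
  n <- length(r)
  stopifnot(nrow(X) == n)
  # shared quantities computed once per genotype matrix
  xc <- sweep(X, 2, colMeans(X))
  ssx <- colSums(xc^2)
  poly <- ssx > 0
  beta <- se <- tval <- rep(NA_real_, ncol(X))
  sxy <- as.vector(crossprod(xc, r - mean(r)))
  beta[poly] <- sxy[poly] / ssx[poly]
  ssr <- sum((r - mean(r))^2)
  df <- n - 2
  sse <- pmax(ssr - beta[poly]^2 * ssx[poly], 0)
  se[poly] <- sqrt(sse / df / ssx[poly])
  tval[poly] <- ifelse(se[poly] > 0, beta[poly] / se[poly], Inf)
  logp <- rep(NA_real_, ncol(X))
  logp[poly] <- -(stats::pt(abs(tval[poly]), df, lower.tail = FALSE,
                            log.p = TRUE) + log(2)) / log(10)
  logp[poly] <- pmax(logp[poly], 0)
  out <- data.frame(
    snp_id = colnames(X),
    chrom = G$variants$chrom[match(colnames(X), G$variants$id)],
    pos = G$variants$pos[match(colnames(X), G$variants$id)],
    effect = beta, se = se, neglog10p = logp,
    reason = ifelse(poly, NA_character_, "monomorphic"),
    trait = trait, stringsAsFactors = FALSE
  )
  class(out) <- c("gwa_result", class(out))
  out
}

#' Genome-wide significance threshold
#'
#' @param result A `gwa_result` (used for the SNP count) or an integer SNP
#'   count.
#' @param method `"bonferroni"` (threshold `-log10(alpha / Nsnp)`) or
#'   `"none"` (an `Inf` sentinel: report-only).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Threshold on the -log10(p) scale.
#' @export
significance_threshold <- function(result, method = c("bonferroni", "none"),
                                   alpha = 0.05) {
  method <- match.arg(method)
  if (method == "none") return(Inf)
  n <- if (is.data.frame(result)) sum(!is.na(result$neglog10p)) else
    as.integer(result)
  -log10(alpha / n)
}

#' Manhattan-style plot of scan scores
#'
#' @param result A `gwa_result`.
#' @param threshold Optional horizontal reference line (-log10 p).
#' @return A ggplot object.
#' @export
plot_gwa <- function(result, threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_gwa requires ggplot2", call. = FALSE)
  result$index <- seq_len(nrow(result))
  p <- ggplot2::ggplot(result, ggplot2::aes(x = index, y = neglog10p)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "SNP index", y = expression(-log[10](p)))
  if (!is.null(threshold) && is.finite(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  p
}
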