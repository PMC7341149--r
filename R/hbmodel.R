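# Multi-trait Bayesian hierarchical model of replicated measurements on
# inbred accessions, with eigenvector-regression marker effects:
#
#   y_i.      ~ t_{nu_e,d}( mu^acc_{j[i]}. + x_i^year B ; Sigma_e )
#   mu^acc_j. ~ N_d( mu + u_j. Gamma ; Sigma_s )
#   gamma_j.  ~ t_{nu_g,d}( 0 ; Sigma_a )
#
# Student-t layers are Gamma scale mixtures of Gaussians, giving closed-form
# Gibbs updates for all location parameters. The background and marker
# covariances (Sigma_s, Sigma_a) compete for the same accession-level
# variance and their conjugate conditionals mix catastrophically (a
# quasi-absorbing state at zero marker variance); they are therefore drawn
# from their joint conditional with Gamma integrated out — tractable because
# the eigenbasis makes the marginal a product of independent d-variate
# Gaussians — by coordinate-wise slice sampling, after which Gamma is redrawn
# (a partially collapsed Gibbs scheme). The error covariance keeps its
# conjugate inverse-Wishart update.

#' Model configuration for the hierarchical fit
#'
#' @param error_df Degrees of freedom of the multivariate Student-t error
#'   distribution; default 3 (dampens outliers); `Inf` gives Gaussian errors.
#' @param marker_df Degrees of freedom of the Student-t prior on rows of the
#'   marker coefficient matrix; default 3 (a multivariate BayesA analog that
#'   avoids over-shrinking leading principal components); 1000 is near
#'   Gaussian; `Inf` exactly Gaussian.
#' @param wishart_df Named vector of inverse-Wishart prior degrees of freedom
#'   for the error (`e`), background (`s`) and marker (`a`) covariance
#'   matrices; defaults `c(e = 2, s = 2, a = 4)`.
#' @param prior_scale Scalar multiplying the identity to form the
#'   inverse-Wishart prior scale matrices. The default `NULL` scales to the
#'   data — identity times half the per-trait phenotypic variance — which
#'   keeps the prior weakly informative regardless of measurement units; a
#'   fixed small scalar instead concentrates prior mass at near-zero
#'   variances and can pin the marker layer there.
#' @param fixed_effect_var Prior variance of the intercept and year
#'   coefficients (default 1e6, effectively flat).
#' @param year_level Where year batch effects enter: `"measurement"` attaches
#'   contrasts to individual measurements; `"accession"` attaches them to
#'   accession means (for designs where year and accession are partially
#'   confounded); `"none"` omits them.
#' @param block_zero_error If `TRUE` the off-diagonal of the error covariance
#'   is constrained to exactly zero in every draw — appropriate when the
#'   "traits" are treatment/control pseudo-traits measured on different
#'   plants, which share no measurement error.
#' @param cov_prior Prior family for the background and marker covariances:
#'   `"wishart"` (default) places a Wishart density on the covariance itself
#'   — finite at zero with an exponential tail, the best-calibrated choice
#'   for interior values of the marker/background split; `"halfcauchy"`
#'   places half-Cauchy priors on the component scales — an integrable spike
#'   at zero plus a polynomial tail, sharper when a component is truly zero
#'   but prone to snapping interior splits to an edge; `"invwishart"` is the
#'   conjugate inverse-Wishart, whose polynomial spike near zero pulls
#'   variance components down, provided mainly for oracle comparisons.
#'   The error covariance always uses the conjugate inverse-Wishart update
#'   (its posterior is dominated by the measurement rows).
#' @param base_year Reference level for year contrasts (default: first level
#'   in sort order).
#' @return An object of class `hb_spec`.
#' @export
hb_spec <- function(error_df = 3, marker_df = 3,
                    wishart_df = c(e = 2, s = 2, a = 4),
                    prior_scale = NULL, fixed_effect_var = 1e6,
                    year_level = c("measurement", "accession", "none"),
                    block_zero_error = FALSE, base_year = NULL,
                    cov_prior = c("wishart", "halfcauchy", "invwishart")) {
  year_level <- match.arg(year_level)
  cov_prior <- match.arg(cov_prior)
  stopifnot(error_df > 2 || !is.finite(error_df),
            marker_df > 0, fixed_effect_var > 0,
            is.null(prior_scale) || prior_scale > 0,
            all(wishart_df >= 1))
  structure(list(error_df = error_df, marker_df = marker_df,
                 wishart_df = wishart_df, prior_scale = prior_scale,
                 fixed_effect_var = fixed_effect_var, year_level = year_level,
                 block_zero_error = block_zero_error, base_year = base_year,
                 cov_prior = cov_prior),
            class = "hb_spec")
}

# Long phenotype table -> measurement x trait matrix + row metadata.
pivot_phenotypes <- function(phenos) {
  need <- c("accession", "trait", "value")
  if (!all(need %in% names(phenos)))
    stop("phenotype table needs columns accession, trait, value", call. = FALSE)
  if (is.null(phenos$year)) phenos$year <- "year1"
  if (is.null(phenos$replicate))
    phenos$replicate <- stats::ave(seq_len(nrow(phenos)),
                                   phenos$accession, phenos$trait,
                                   FUN = seq_along)
  if (is.null(phenos$treatment)) phenos$treatment <- "none"
  key <- paste(phenos$accession, phenos$replicate, phenos$year,
               phenos$treatment, sep = "\r")
  ukey <- unique(key)
  traits <- unique(phenos$trait)
  Y <- matrix(NA_real_, length(ukey), length(traits),
              dimnames = list(NULL, traits))
  Y[cbind(match(key, ukey), match(phenos$trait, traits))] <- phenos$value
  first <- match(ukey, key)
  list(Y = Y, accession = phenos$accession[first],
       year = phenos$year[first], traits = traits)
}

#' Build a hierarchical model object
#'
#' Validates and assembles the phenotype matrix, accession index, year
#' contrasts and marker eigenbasis into a model handle for [run_mcmc()].
#' Every accession appearing in the phenotypes must be present in the basis.
#'
#' @param phenos Long-format phenotype data.frame (columns accession, trait,
#'   value, and optionally year, treatment, replicate). Measurements sharing
#'   accession/replicate/year/treatment form one multi-trait row; traits not
#'   measured on a row are treated as missing and imputed during sampling.
#' @param basis An [eigenbasis()] built from a relationship kernel over (at
#'   least) the phenotyped accessions, or `NULL` for a no-marker model
#'   (accession means carry only the iid background layer — the classic
#'   replicated one-way random-effects model).
#' @param spec An [hb_spec()].
#' @return An object of class `hb_model`.
#' @export
hb_model <- function(phenos, basis, spec = hb_spec()) {
  stopifnot(inherits(spec, "hb_spec"))
  pv <- pivot_phenotypes(phenos)
  accs <- unique(pv$accession)
  if (!is.null(basis)) {
    stopifnot(inherits(basis, "eigen_basis"))
    missing_acc <- setdiff(accs, basis$accessions)
    if (length(missing_acc) > 0)
      stop("accessions absent from the eigenbasis: ",
           paste(utils::head(missing_acc, 5), collapse = ", "),
           if (length(missing_acc) > 5) ", ...", call. = FALSE)
    U <- basis$U[match(accs, basis$accessions), , drop = FALSE]
  } else {
    U <- matrix(0, length(accs), 0)
  }
  acc_idx <- match(pv$accession, accs)
  d <- ncol(pv$Y)
  if (spec$block_zero_error && d < 2)
    stop("block_zero_error requires at least 2 traits", call. = FALSE)

  years <- sort(unique(pv$year))
  base <- spec$base_year %||% years[1]
  if (!base %in% years) stop("base_year not found among year labels", call. = FALSE)
  year_level <- spec$year_level
  if (length(years) < 2) year_level <- "none"
  Xy_meas <- NULL; Xy_acc <- NULL
  if (year_level == "measurement") {
    f <- factor(pv$year, levels = c(base, setdiff(years, base)))
    Xy_meas <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(Xy_meas) <- levels(f)[-1]
  } else if (year_level == "accession") {
    acc_year <- tapply(pv$year, acc_idx, function(x) unique(x))
    if (any(lengths(acc_year) > 1))
      stop("year_level = 'accession' requires each accession measured in a single year",
           call. = FALSE)
    f <- factor(unlist(acc_year)[order(as.integer(names(acc_year)))],
                levels = c(base, setdiff(years, base)))
    Xy_acc <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(Xy_acc) <- levels(f)[-1]
  }

  lambda <- colSums(U^2)  # retained eigenvalues (U'U is diagonal)
  # Weakly-informative prior scale matrices, matched to the layer each
  # covariance lives on: error from the within-accession variance,
  # background from the between-accession variance, marker the same but in
  # regression-coefficient units (divided by the mean eigenvalue) so both
  # genetic layers have comparable prior modes in variance-contribution
  # units. A fixed identity scale concentrates mass at near-zero variances
  # and biases the marker/background split.
  if (is.null(spec$prior_scale)) {
    accm <- apply(pv$Y, 2, function(col)
      tapply(col, acc_idx, mean, na.rm = TRUE))
    va <- pmax(apply(matrix(accm, ncol = d), 2, stats::var, na.rm = TRUE),
               1e-8)
    vw <- pmax(apply(pv$Y, 2, stats::var, na.rm = TRUE) - va, 1e-8)
    S0_e <- diag(0.5 * vw, d)
    if (spec$cov_prior %in% c("wishart", "halfcauchy")) {
      # Wishart scale set so the prior MEAN (df * S) of each genetic layer
      # equals half the observed accession-level variance (an even prior
      # split between marker and background, in each layer's natural units)
      S0_s <- diag(0.5 * va / spec$wishart_df[["s"]], d)
      S0_a <- diag(0.5 * va / (max(mean(lambda), 1e-8) *
                                 spec$wishart_df[["a"]]), d)
    } else {
      S0_s <- diag(0.5 * va, d)
      S0_a <- diag(0.5 * va / max(mean(lambda), 1e-8), d)
    }
  } else {
    S0_e <- S0_s <- S0_a <- diag(spec$prior_scale, d)
  }
  structure(list(Y = pv$Y, acc = acc_idx, accessions = accs,
                 traits = pv$traits, d = d, U = U, q = ncol(U),
                 lambda = lambda,
                 Xy_meas = Xy_meas, Xy_acc = Xy_acc,
                 year_level = year_level, spec = spec,
                 S0_e = S0_e, S0_s = S0_s, S0_a = S0_a),
            class = "hb_model")
}

#' @export
print.hb_model <- function(x, ...) {
  cat("hb_model:", nrow(x$Y), "measurement rows,", length(x$accessions),
      "accessions,", x$d, "trait(s),", x$q, "eigenvectors; year level:",
      x$year_level, "\n")
  invisible(x)
}

# ---- batch sampling from row-wise Gaussian full conditionals ---------------
# P_j = s1[j] * M1 + s2[j] * M2 ; draws ~ N(P_j^{-1} b_j, P_j^{-1})
sample_rows_canonical <- function(s1, M1, s2, M2, B) {
  n <- nrow(B); d <- ncol(B)
  if (d == 1L) {
    P <- s1 * M1[1, 1] + s2 * M2[1, 1]
    return(matrix(stats::rnorm(n, B[, 1] / P, 1 / sqrt(P)), n, 1))
  }
  if (d == 2L) {
    a <- s1 * M1[1, 1] + s2 * M2[1, 1]
    b <- s1 * M1[1, 2] + s2 * M2[1, 2]
    cc <- s1 * M1[2, 2] + s2 * M2[2, 2]
    det <- a * cc - b * b
    S11 <- cc / det; S12 <- -b / det; S22 <- a / det
    m1 <- S11 * B[, 1] + S12 * B[, 2]
    m2 <- S12 * B[, 1] + S22 * B[, 2]
    l11 <- sqrt(S11); l21 <- S12 / l11; l22 <- sqrt(pmax(S22 - l21^2, 1e-300))
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    return(cbind(m1 + l11 * z1, m2 + l21 * z1 + l22 * z2))
  }
  out <- matrix(0, n, d)
  for (j in seq_len(n)) {
    P <- s1[j] * M1 + s2[j] * M2
    R <- chol(P)
    mu <- backsolve(R, forwardsolve(t(R), B[j, ]))
    out[j, ] <- mu + backsolve(R, stats::rnorm(d))
  }
  out
}

hb_init <- function(model) {
  Y <- model$Y
  d <- model$d
  n <- nrow(Y)
  acc_mean <- apply(Y, 2, function(col) tapply(col, model$acc, mean, na.rm = TRUE))
  acc_mean <- matrix(acc_mean, ncol = d)
  gm <- colMeans(Y, na.rm = TRUE)
  for (p in seq_len(d)) acc_mean[!is.finite(acc_mean[, p]), p] <- gm[p]
  nas <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(nas) > 0) Y[nas] <- acc_mean[cbind(model$acc[nas[, 1]], nas[, 2])]
  resid_var <- pmax(colMeans((Y - acc_mean[model$acc, , drop = FALSE])^2),
                    1e-6)
  # start from a balanced split of the accession-mean variance between the
  # marker and background layers (Gamma at half its least-squares solution)
  M0 <- sweep(acc_mean, 2, gm)
  Gamma0 <- if (model$q > 0) 0.5 * crossprod(model$U, M0) / model$lambda
            else matrix(0, 0, d)
  acc_var <- pmax(apply(acc_mean, 2, stats::var), 1e-6)
  list(
    Y = Y, has_missing = nrow(nas) > 0, na_idx = nas,
    mu = matrix(gm, 1, d),
    B_meas = if (!is.null(model$Xy_meas))
      matrix(0, ncol(model$Xy_meas), d) else NULL,
    B_acc = if (!is.null(model$Xy_acc))
      matrix(0, ncol(model$Xy_acc), d) else NULL,
    mu_acc = acc_mean,
    Gamma = Gamma0,
    Sigma_e = diag(resid_var, d),
    Sigma_s = diag(acc_var / 2, d),
    Sigma_a = if (model$q > 0)
      symm(crossprod(Gamma0) / model$q) + diag(1e-6 + 1e-4 * acc_var, d)
      else diag(1e-4, d),
    w = rep(1, n), v = rep(1, max(model$q, 1))
  )
}

# measurement-level systematic part excluding the accession mean
meas_offset <- function(model, state) {
  if (is.null(state$B_meas)) 0 else model$Xy_meas %*% state$B_meas
}

# prior mean of accession means
acc_prior_mean <- function(model, state) {
  M <- matrix(state$mu, nrow(state$mu_acc), model$d, byrow = TRUE)
  if (model$q > 0) M <- M + model$U %*% state$Gamma
  if (!is.null(state$B_acc)) M <- M + model$Xy_acc %*% state$B_acc
  M
}

# accession means minus everything except the marker term
acc_residual_for_markers <- function(model, state) {
  M <- state$mu_acc - matrix(state$mu, nrow(state$mu_acc), model$d,
                             byrow = TRUE)
  if (!is.null(state$B_acc)) M <- M - model$Xy_acc %*% state$B_acc
  M
}

#' Update Student-t latent scale variables (one Gibbs step)
#'
#' Draws the Gamma-distributed latent scales of the scale-mixture
#' representation of the Student-t error and marker-prior layers from their
#' full conditionals. With infinite degrees of freedom the scales are exactly
#' 1 (the Gaussian limit). Rows with large standardized residuals receive
#' stochastically smaller scales, i.e. are downweighted. Exposed for testing;
#' normally called inside [run_mcmc()].
#'
#' @param model An [hb_model()].
#' @param state A sampler state list.
#' @return The state with elements `w` (per-measurement) and `v` (per
#'   eigenvector) replaced by fresh draws.
#' @export
#' @keywords internal
update_latent_scales <- function(model, state) {
  d <- model$d
  nu_e <- model$spec$error_df
  if (is.finite(nu_e)) {
    R <- state$Y - state$mu_acc[model$acc, , drop = FALSE] - meas_offset(model, state)
    Sei <- chol2inv(chol(state$Sigma_e))
    q <- rowSums((R %*% Sei) * R)
    state$w <- stats::rgamma(nrow(R), (nu_e + d) / 2, (nu_e + q) / 2)
  } else state$w <- rep(1, nrow(state$Y))
  nu_g <- model$spec$marker_df
  if (model$q > 0) {
    if (is.finite(nu_g)) {
      Sai <- chol2inv(chol(state$Sigma_a))
      qg <- rowSums((state$Gamma %*% Sai) * state$Gamma)
      state$v <- stats::rgamma(model$q, (nu_g + d) / 2, (nu_g + qg) / 2)
    } else state$v <- rep(1, model$q)
  }
  state
}

# inverse-Wishart draw for a (possibly weighted) residual matrix
draw_iw <- function(df0, S0, R, wts = NULL) {
  n <- nrow(R)
  S <- if (is.null(wts)) crossprod(R) else crossprod(R * sqrt(wts))
  riwish(df0 + n, S0 + symm(S))
}

log_iw_prior <- function(S, df, S0) {
  d <- nrow(S)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  -(df + d + 1) / 2 * 2 * sum(log(diag(R))) -
    0.5 * sum(S0 * chol2inv(R))
}

# Wishart density on the covariance itself (d = 1: a Gamma prior on the
# variance): finite at zero, exponential tail.
log_wish_prior <- function(S, df, S0) {
  d <- nrow(S)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  (df - d - 1) / 2 * 2 * sum(log(diag(R))) -
    0.5 * sum(chol2inv(chol(S0)) * S)
}

# Half-Cauchy prior on the scale (square root) of each diagonal element,
# flat over the positive-definite region otherwise: an integrable spike at
# zero and a polynomial tail, hence nearly neutral at both edges of the
# variance-partition ridge. The Cauchy scale^2 is df * S0 (the same
# data-scaled magnitude the Wishart family uses for its mean).
log_hc_prior <- function(S, df, S0) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  c2 <- df * diag(S0)
  sum(-log1p(diag(S) / c2) - 0.5 * log(diag(S)))
}

log_cov_prior <- function(S, df, S0, family) {
  switch(family,
         wishart = log_wish_prior(S, df, S0),
         halfcauchy = log_hc_prior(S, df, S0),
         log_iw_prior(S, df, S0))
}

# log marginal likelihood of (Sigma_a, Sigma_s) with Gamma integrated out:
# eigen-coordinates of the marker-layer residual are independent d-variate
# Gaussians with covariance (lambda_j / v_j) Sigma_a + Sigma_s; the
# complement of the eigenspace contributes a pure Sigma_s term.
genetic_marg_loglik <- function(Sa, Ss, Mt, lam_v, Cperp, m_perp) {
  d <- nrow(Ss)
  if (d == 1L) {
    vv <- lam_v * Sa[1, 1] + Ss[1, 1]
    if (any(vv <= 0) || Ss[1, 1] <= 0) return(-Inf)
    ll <- -0.5 * sum(log(vv) + Mt[, 1]^2 / vv)
    if (m_perp > 0)
      ll <- ll - 0.5 * (m_perp * log(Ss[1, 1]) + Cperp[1, 1] / Ss[1, 1])
    return(ll)
  }
  if (d == 2L) {
    a <- lam_v * Sa[1, 1] + Ss[1, 1]
    b <- lam_v * Sa[1, 2] + Ss[1, 2]
    cc <- lam_v * Sa[2, 2] + Ss[2, 2]
    det <- a * cc - b * b
    if (any(det <= 0) || any(a <= 0)) return(-Inf)
    qf <- (cc * Mt[, 1]^2 - 2 * b * Mt[, 1] * Mt[, 2] + a * Mt[, 2]^2) / det
    ll <- -0.5 * sum(log(det) + qf)
    if (m_perp > 0) {
      Rs <- tryCatch(chol(Ss), error = function(e) NULL)
      if (is.null(Rs)) return(-Inf)
      ll <- ll - 0.5 * (m_perp * 2 * sum(log(diag(Rs))) +
                          sum(chol2inv(Rs) * Cperp))
    }
    return(ll)
  }
  ll <- 0
  for (j in seq_along(lam_v)) {
    C <- lam_v[j] * Sa + Ss
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    z <- forwardsolve(t(R), Mt[j, ])
    ll <- ll - sum(log(diag(R))) - 0.5 * sum(z^2)
  }
  if (m_perp > 0) {
    Rs <- tryCatch(chol(Ss), error = function(e) NULL)
    if (is.null(Rs)) return(-Inf)
    ll <- ll - 0.5 * (m_perp * 2 * sum(log(diag(Rs))) +
                        sum(chol2inv(Rs) * Cperp))
  }
  ll
}

# slice-sample every free element of the two genetic covariance matrices
# under the collapsed likelihood (diagonals on the log scale)
update_genetic_block <- function(model, state) {
  d <- model$d
  sp <- model$spec
  M <- acc_residual_for_markers(model, state)
  UtM <- crossprod(model$U, M)
  Mt <- UtM / sqrt(model$lambda)
  lam_v <- model$lambda / state$v
  Cperp <- symm(crossprod(M) - crossprod(Mt))
  diag(Cperp) <- pmax(diag(Cperp), 0)
  m_perp <- nrow(M) - model$q
  Sa <- state$Sigma_a
  Ss <- state$Sigma_s

  logpost <- function(Sa, Ss) {
    genetic_marg_loglik(Sa, Ss, Mt, lam_v, Cperp, m_perp) +
      log_cov_prior(Sa, sp$wishart_df[["a"]], model$S0_a, sp$cov_prior) +
      log_cov_prior(Ss, sp$wishart_df[["s"]], model$S0_s, sp$cov_prior)
  }
  for (i in seq_len(d)) {
    Sa[i, i] <- exp(slice_sample1(log(Sa[i, i]), function(x) {
      S <- Sa; S[i, i] <- exp(x); logpost(S, Ss) + x
    }, w = 1))
    Ss[i, i] <- exp(slice_sample1(log(Ss[i, i]), function(x) {
      S <- Ss; S[i, i] <- exp(x); logpost(Sa, S) + x
    }, w = 1))
  }
  if (d > 1) {
    for (i in seq_len(d - 1)) for (j in seq(i + 1, d)) {
      wa <- 0.3 * sqrt(Sa[i, i] * Sa[j, j])
      Sa[i, j] <- Sa[j, i] <- slice_sample1(Sa[i, j], function(x) {
        S <- Sa; S[i, j] <- S[j, i] <- x; logpost(S, Ss)
      }, w = wa)
      ws <- 0.3 * sqrt(Ss[i, i] * Ss[j, j])
      Ss[i, j] <- Ss[j, i] <- slice_sample1(Ss[i, j], function(x) {
        S <- Ss; S[i, j] <- S[j, i] <- x; logpost(Sa, S)
      }, w = ws)
    }
  }
  state$Sigma_a <- Sa
  state$Sigma_s <- Ss
  state
}

#' Update the covariance matrices (one Gibbs step)
#'
#' The error covariance is drawn from its conjugate (weighted)
#' inverse-Wishart full conditional; under `block_zero_error` each trait's
#' error variance is drawn from its own scaled-inverse-chi-squared
#' conditional so constrained off-diagonals are exactly zero. The background
#' and marker covariances are drawn jointly from their conditional with the
#' marker coefficients integrated out (coordinate-wise slice sampling on the
#' collapsed likelihood); in a no-marker model the background covariance
#' falls back to its conjugate inverse-Wishart update. Exposed for testing;
#' [run_mcmc()] redraws `Gamma` immediately after this step, as the
#' partially collapsed scheme requires.
#'
#' @inheritParams update_latent_scales
#' @return The state with `Sigma_e`, `Sigma_s`, `Sigma_a` replaced.
#' @export
#' @keywords internal
update_covariances <- function(model, state) {
  d <- model$d
  sp <- model$spec
  Re <- state$Y - state$mu_acc[model$acc, , drop = FALSE] - meas_offset(model, state)
  if (sp$block_zero_error) {
    n <- nrow(Re)
    ssq <- colSums(Re^2 * state$w)
    sig <- 1 / stats::rgamma(d, (sp$wishart_df[["e"]] + n) / 2,
                             (diag(model$S0_e) + ssq) / 2)
    state$Sigma_e <- diag(sig, d)
  } else {
    state$Sigma_e <- draw_iw(sp$wishart_df[["e"]], model$S0_e, Re, state$w)
  }
  if (model$q > 0) {
    state <- update_genetic_block(model, state)
  } else {
    Rs <- state$mu_acc - acc_prior_mean(model, state)
    if (sp$cov_prior == "invwishart") {
      state$Sigma_s <- draw_iw(sp$wishart_df[["s"]], model$S0_s, Rs)
    } else {
      # Wishart prior is non-conjugate: slice-sample the elements under the
      # Gaussian residual likelihood
      CRs <- crossprod(Rs)
      n <- nrow(Rs)
      Ss <- state$Sigma_s
      lp <- function(S) {
        R <- tryCatch(chol(S), error = function(e) NULL)
        if (is.null(R)) return(-Inf)
        -0.5 * (n * 2 * sum(log(diag(R))) + sum(chol2inv(R) * CRs)) +
          log_cov_prior(S, sp$wishart_df[["s"]], model$S0_s, sp$cov_prior)
      }
      for (i in seq_len(d)) {
        Ss[i, i] <- exp(slice_sample1(log(Ss[i, i]), function(x) {
          S <- Ss; S[i, i] <- exp(x); lp(S) + x
        }, w = 1))
      }
      if (d > 1) {
        for (i in seq_len(d - 1)) for (j in seq(i + 1, d)) {
          ws <- 0.3 * sqrt(Ss[i, i] * Ss[j, j])
          Ss[i, j] <- Ss[j, i] <- slice_sample1(Ss[i, j], function(x) {
            S <- Ss; S[i, j] <- S[j, i] <- x; lp(S)
          }, w = ws)
        }
      }
      state$Sigma_s <- Ss
    }
  }
  state
}

update_gamma <- function(model, state) {
  if (model$q == 0) return(state)
  M <- acc_residual_for_markers(model, state)
  Ssi <- chol2inv(chol(state$Sigma_s))
  Sai <- chol2inv(chol(state$Sigma_a))
  Bg <- crossprod(model$U, M) %*% Ssi
  state$Gamma <- sample_rows_canonical(model$lambda, Ssi, state$v, Sai, Bg)
  state
}

update_acc_means <- function(model, state) {
  Sei <- chol2inv(chol(state$Sigma_e))
  Ssi <- chol2inv(chol(state$Sigma_s))
  Radj <- state$Y - meas_offset(model, state)
  Wsum <- as.vector(rowsum(state$w, model$acc))
  Swy <- rowsum(Radj * state$w, model$acc)
  Mprior <- acc_prior_mean(model, state)
  B <- Swy %*% Sei + Mprior %*% Ssi
  state$mu_acc <- sample_rows_canonical(Wsum, Sei, rep(1, length(Wsum)), Ssi, B)
  state
}

update_fixed_effects <- function(model, state) {
  d <- model$d
  sp <- model$spec
  Ssi <- chol2inv(chol(state$Sigma_s))
  Nacc <- nrow(state$mu_acc)
  Moff <- matrix(0, Nacc, d)
  if (model$q > 0) Moff <- Moff + model$U %*% state$Gamma
  if (!is.null(state$B_acc)) Moff <- Moff + model$Xy_acc %*% state$B_acc
  Pmu <- Nacc * Ssi + diag(1 / sp$fixed_effect_var, d)
  bmu <- Ssi %*% colSums(state$mu_acc - Moff)
  Rmu <- chol(Pmu)
  state$mu <- matrix(backsolve(Rmu, forwardsolve(t(Rmu), bmu)) +
                       backsolve(Rmu, stats::rnorm(d)), 1, d)
  if (!is.null(state$B_meas)) {
    Sei <- chol2inv(chol(state$Sigma_e))
    R <- state$Y - state$mu_acc[model$acc, , drop = FALSE]
    state$B_meas <- draw_coef_matrix(model$Xy_meas, R, Sei, state$w,
                                     sp$fixed_effect_var)
  }
  if (!is.null(state$B_acc)) {
    R <- state$mu_acc -
      matrix(state$mu, Nacc, d, byrow = TRUE)
    if (model$q > 0) R <- R - model$U %*% state$Gamma
    state$B_acc <- draw_coef_matrix(model$Xy_acc, R, Ssi, NULL,
                                    sp$fixed_effect_var)
  }
  state
}

# vec(B) Gaussian update for a k x d coefficient matrix in rows R = X B + E,
# E rows ~ N(0, Sigma / w_i)
draw_coef_matrix <- function(X, R, Sigi, w, prior_var) {
  k <- ncol(X); d <- ncol(R)
  XtWX <- if (is.null(w)) crossprod(X) else crossprod(X * sqrt(w))
  XtWR <- if (is.null(w)) crossprod(X, R) else crossprod(X, R * w)
  P <- kronecker(Sigi, XtWX) + diag(1 / prior_var, k * d)
  b <- as.vector(XtWR %*% Sigi)
  Rc <- chol(symm(P))
  vb <- backsolve(Rc, forwardsolve(t(Rc), b)) + backsolve(Rc, stats::rnorm(k * d))
  matrix(vb, k, d)
}

# conditional-Gaussian imputation of missing trait cells, row by row
impute_cells <- function(model, state) {
  if (!state$has_missing) return(state)
  idx <- state$na_idx
  Mu <- state$mu_acc[model$acc, , drop = FALSE] + meas_offset(model, state)
  d <- model$d
  if (d == 1) stop("missing values with a single trait: drop those rows instead",
                   call. = FALSE)
  Se <- state$Sigma_e
  for (i in unique(idx[, 1])) {
    m <- idx[idx[, 1] == i, 2]
    o <- setdiff(seq_len(d), m)
    sc <- Se / state$w[i]
    if (length(o) == 0) {
      state$Y[i, m] <- Mu[i, m] + rmvn(1, sc[m, m, drop = FALSE])
    } else {
      A <- sc[m, o, drop = FALSE] %*% chol2inv(chol(sc[o, o, drop = FALSE]))
      cmu <- Mu[i, m] + A %*% (state$Y[i, o] - Mu[i, o])
      cS <- sc[m, m, drop = FALSE] - A %*% sc[o, m, drop = FALSE]
      state$Y[i, m] <- cmu + rmvn(1, symm(cS))
    }
  }
  state
}

#' MCMC schedule
#'
#' @param n_iter Total iterations (default 55000, the full production
#'   schedule; tests and examples use reduced schedules).
#' @param burnin Burn-in iterations discarded (default 5000).
#' @param thin Thinning interval (default 5).
#' @param seed Integer seed.
#' @return An object of class `mcmc_schedule`.
#' @export
mcmc_schedule <- function(n_iter = 55000, burnin = 5000, thin = 5, seed = 1L) {
  stopifnot(burnin < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_schedule")
}

#' Fit the hierarchical model by Gibbs sampling
#'
#' Runs the full scan — missing-cell imputation, latent Student-t scales,
#' accession means, the collapsed background/marker covariance step followed
#' immediately by the marker coefficients, fixed effects, error covariance —
#' and returns thinned post-burn-in draws. Chains are exactly reproducible
#' given the schedule's seed. The genomic estimated breeding values
#' (GEBV = U Gamma) are materialized per draw.
#'
#' @param model An [hb_model()].
#' @param schedule An [mcmc_schedule()].
#' @param verbose Print progress every 1000 iterations.
#' @return An object of class `hb_samples`: arrays `mu` (S x d), `mu_acc`
#'   (S x Nacc x d), `Gamma` (S x q x d), `gebv` (S x Nacc x d), `Sigma_e`,
#'   `Sigma_s`, `Sigma_a` (S x d x d), optional year coefficient arrays, plus
#'   trait/accession labels and the schedule.
#' @export
run_mcmc <- function(model, schedule = mcmc_schedule(), verbose = FALSE) {
  stopifnot(inherits(model, "hb_model"), inherits(schedule, "mcmc_schedule"))
  set.seed(schedule$seed)
  state <- hb_init(model)
  d <- model$d
  Nacc <- nrow(state$mu_acc)
  q <- model$q
  keep <- seq(schedule$burnin + schedule$thin, schedule$n_iter,
              by = schedule$thin)
  S <- length(keep)
  out <- list(
    mu = array(NA_real_, c(S, d)),
    mu_acc = array(NA_real_, c(S, Nacc, d)),
    Gamma = array(NA_real_, c(S, q, d)),
    gebv = array(NA_real_, c(S, Nacc, d)),
    Sigma_e = array(NA_real_, c(S, d, d)),
    Sigma_s = array(NA_real_, c(S, d, d)),
    Sigma_a = array(NA_real_, c(S, d, d))
  )
  nyr <- if (!is.null(state$B_meas)) nrow(state$B_meas)
         else if (!is.null(state$B_acc)) nrow(state$B_acc) else 0
  if (nyr > 0) out$B_year <- array(NA_real_, c(S, nyr, d))
  s <- 0L
  for (it in seq_len(schedule$n_iter)) {
    state <- impute_cells(model, state)
    state <- update_latent_scales(model, state)
    state <- update_acc_means(model, state)
    state <- update_covariances(model, state)
    state <- update_gamma(model, state)   # must follow the collapsed step
    state <- update_fixed_effects(model, state)
    if (s < S && it == keep[s + 1L]) {
      s <- s + 1L
      out$mu[s, ] <- state$mu
      out$mu_acc[s, , ] <- state$mu_acc
      if (q > 0) {
        out$Gamma[s, , ] <- state$Gamma
        out$gebv[s, , ] <- model$U %*% state$Gamma
      } else out$gebv[s, , ] <- 0
      out$Sigma_e[s, , ] <- state$Sigma_e
      out$Sigma_s[s, , ] <- state$Sigma_s
      out$Sigma_a[s, , ] <- state$Sigma_a
      if (nyr > 0)
        out$B_year[s, , ] <- if (!is.null(state$B_meas)) state$B_meas
                             else state$B_acc
    }
    if (verbose && it %% 1000 == 0)
      message("iteration ", it, "/", schedule$n_iter)
  }
  out$traits <- model$traits
  out$accessions <- model$accessions
  out$schedule <- schedule
  out$n_draws <- S
  class(out) <- "hb_samples"
  out
}

#' @export
print.hb_samples <- function(x, ...) {
  cat("hb_samples:", x$n_draws, "posterior draws,",
      length(x$accessions), "accessions,", length(x$traits), "trait(s)\n")
  invisible(x)
}
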