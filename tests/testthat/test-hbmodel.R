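# A tiny fitted panel reused across blocks (cheap: ~1 s).
small_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      tp <- toy_panel(n_acc = 40, n_snps = 150, h2 = 0.5, bg = 0.2,
                      n_rep = 4, seed = 19)
      basis <- eigenbasis(kernel_vanraden(tp$G))
      model <- hb_model(tp$phenotypes, basis,
                        hb_spec(error_df = Inf, marker_df = 3,
                                year_level = "none"))
      memo <<- list(tp = tp, basis = basis, model = model,
                    samples = run_mcmc(model, mcmc_schedule(1200, 400, 4,
                                                            seed = 8)))
    }
    memo
  }
})

test_that("model construction validates accessions, traits and year structure", {
  sf <- small_fit()
  ph <- sf$tp$phenotypes
  ph_bad <- ph
  ph_bad$accession[1] <- "ghost001"
  expect_error(hb_model(ph_bad, sf$basis), "ghost001")
  expect_error(hb_model(ph, sf$basis, hb_spec(block_zero_error = TRUE)),
               "at least 2 traits")
  # single year collapses the year level to none
  m <- hb_model(ph, sf$basis, hb_spec(year_level = "measurement"))
  expect_identical(m$year_level, "none")
  # two-year design at measurement level gets one contrast column
  ph2 <- ph
  ph2$year <- rep(c("2016", "2017"), length.out = nrow(ph2))
  m2 <- hb_model(ph2, sf$basis, hb_spec(year_level = "measurement"))
  expect_identical(colnames(m2$Xy_meas), "2017")
  expect_error(hb_model(ph2, sf$basis,
                        hb_spec(year_level = "measurement",
                                base_year = "1999")), "base_year")
})

test_that("year batch effects are recovered at measurement level", {
  spec <- sim_spec(n_accessions = 50, n_snps = 100, n_causal = 0,
                   target_marker_h2 = 0, target_background_var = 0.2,
                   error_var = 0.5, n_replicates = 6,
                   year_labels = list(years = c("2016", "2017"),
                                      offsets = matrix(c(0, 3), 2, 1)),
                   seed = 44)
  G <- simulate_genotypes(spec)
  sim <- simulate_phenotypes(G, spec)
  basis <- eigenbasis(kernel_vanraden(G))
  m <- hb_model(sim$phenotypes, basis,
                hb_spec(error_df = Inf, year_level = "measurement",
                        base_year = "2016"))
  s <- run_mcmc(m, mcmc_schedule(800, 300, 2, seed = 4))
  expect_equal(mean(s$B_year[, 1, 1]), 3, tolerance = 0.15)
})

test_that("latent scales hit their gamma conditionals and gaussian limits", {
  sf <- small_fit()
  model <- sf$model
  state <- markervar:::hb_init(model)
  # Gaussian limit: scales exactly one
  st <- update_latent_scales(model, state)
  expect_true(all(st$w == 1))
  # Student-t errors: zero-residual rows have scale mean (nu + d) / nu
  model_t <- model
  model_t$spec$error_df <- 3
  state0 <- state
  state0$Y <- state$mu_acc[model$acc, , drop = FALSE]  # zero residuals
  set.seed(1)
  draws <- replicate(4000, mean(update_latent_scales(model_t, state0)$w))
  expect_equal(mean(draws), (3 + 1) / 3, tolerance = 0.01)
  # large residuals are downweighted, monotonically in magnitude
  state_big <- state
  state_big$Y[1, 1] <- state_big$Y[1, 1] + 50
  set.seed(2)
  w_big <- replicate(300, update_latent_scales(model_t, state_big)$w[1])
  expect_lt(mean(w_big), 0.05)
})

test_that("error covariance update matches its scaled-inverse-chi-squared form", {
  # d = 1 conjugate closed form: with mu_acc pinned to zero and known
  # residuals, Sigma_e | . ~ InvGamma((df0 + n)/2, (S0 + ss)/2)
  set.seed(9)
  n_acc <- 30; n_rep <- 40
  ph <- data.frame(accession = rep(sprintf("a%02d", 1:n_acc), each = n_rep),
                   trait = "t1", value = rnorm(n_acc * n_rep, 0, 2),
                   stringsAsFactors = FALSE)
  model <- hb_model(ph, NULL, hb_spec(error_df = Inf, year_level = "none"))
  state <- markervar:::hb_init(model)
  state$mu_acc[] <- 0
  state$w[] <- 1
  ss <- sum(ph$value^2)
  n <- length(ph$value)
  df0 <- model$spec$wishart_df[["e"]]
  S0 <- model$S0_e[1, 1]
  set.seed(3)
  draws <- replicate(3000, update_covariances(model, state)$Sigma_e[1, 1])
  a <- (df0 + n) / 2; b <- (S0 + ss) / 2
  expect_equal(mean(draws), b / (a - 1), tolerance = 0.01)
  expect_equal(var(draws), b^2 / ((a - 1)^2 * (a - 2)), tolerance = 0.1)
})

test_that("error covariance update recovers a known covariance from bulk residuals", {
  # law of large numbers: many residual rows of known covariance
  set.seed(10)
  n_acc <- 100; n_rep <- 400
  n <- n_acc * n_rep
  C <- matrix(c(1, 0.3, 0.3, 0.5), 2, 2)
  E <- matrix(rnorm(2 * n), n, 2) %*% chol(C)
  meta <- data.frame(accession = rep(sprintf("a%03d", 1:n_acc), each = n_rep),
                     replicate = rep(seq_len(n_rep), n_acc),
                     stringsAsFactors = FALSE)
  ph <- rbind(cbind(meta, trait = "t1", value = E[, 1]),
              cbind(meta, trait = "t2", value = E[, 2]))
  model <- hb_model(ph, NULL, hb_spec(error_df = Inf, year_level = "none"))
  state <- markervar:::hb_init(model)
  state$mu_acc[] <- 0
  state$w[] <- 1
  st <- update_covariances(model, state)
  expect_equal(st$Sigma_e, C, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("block-zero error structure keeps the off-diagonal at exactly zero", {
  tp2 <- {
    spec <- sim_spec(n_accessions = 25, n_snps = 80, n_causal = 10,
                     causal_maf_range = c(0.1, 0.5), n_traits = 2,
                     target_marker_h2 = 0.4, target_background_var = 0.2,
                     genetic_correlation = matrix(c(1, 0.6, 0.6, 1), 2),
                     n_replicates = 3, seed = 12)
    G <- simulate_genotypes(spec)
    c(simulate_phenotypes(G, spec), list(G = G))
  }
  basis <- eigenbasis(kernel_vanraden(tp2$G))
  m <- hb_model(tp2$phenotypes, basis,
                hb_spec(error_df = Inf, block_zero_error = TRUE,
                        year_level = "none"))
  s <- run_mcmc(m, mcmc_schedule(300, 100, 2, seed = 5))
  expect_true(all(s$Sigma_e[, 1, 2] == 0))
  expect_true(all(s$Sigma_e[, 1, 1] > 0 & s$Sigma_e[, 2, 2] > 0))
  # unconstrained covariances stay PD
  dets <- apply(s$Sigma_s, 1, function(S) det(matrix(S, 2, 2)))
  expect_true(all(dets > 0))
})

test_that("chains are reproducible under the seed and consistent across seeds", {
  sf <- small_fit()
  s1 <- run_mcmc(sf$model, mcmc_schedule(600, 200, 2, seed = 30))
  s2 <- run_mcmc(sf$model, mcmc_schedule(600, 200, 2, seed = 30))
  expect_identical(s1$Sigma_s, s2$Sigma_s)
  expect_identical(s1$gebv, s2$gebv)
  # different seeds: same posterior within Monte-Carlo error
  s3 <- run_mcmc(sf$model, mcmc_schedule(1200, 400, 4, seed = 31))
  h2a <- mean(marker_h2(sf$samples, 1)$draws)
  h2b <- mean(marker_h2(s3, 1)$draws)
  expect_lt(abs(h2a - h2b), 0.05)
})

test_that("zero-variance data concentrate accession means at the common value", {
  ph <- data.frame(accession = rep(sprintf("a%02d", 1:10), each = 4),
                   trait = "t1", value = 5, stringsAsFactors = FALSE)
  model <- hb_model(ph, NULL, hb_spec(error_df = Inf, year_level = "none"))
  s <- run_mcmc(model, mcmc_schedule(400, 200, 2, seed = 6))
  expect_lt(max(abs(s$mu_acc - 5)), 0.2)
  expect_lt(stats::median(s$Sigma_e[, 1, 1]), 0.05)
})

test_that("missing trait cells are imputed by conditional draws", {
  spec <- sim_spec(n_accessions = 20, n_snps = 60, n_causal = 10,
                   causal_maf_range = c(0.1, 0.5), n_traits = 2,
                   target_marker_h2 = 0.4, target_background_var = 0.1,
                   n_replicates = 4, seed = 23)
  G <- simulate_genotypes(spec)
  sim <- simulate_phenotypes(G, spec)
  ph <- sim$phenotypes
  drop <- ph$trait == "trait2" & ph$replicate %in% c(1, 2) &
    ph$accession %in% sprintf("acc%03d", 1:5)
  ph <- ph[!drop, ]
  basis <- eigenbasis(kernel_vanraden(G))
  m <- hb_model(ph, basis, hb_spec(error_df = Inf, year_level = "none"))
  s <- run_mcmc(m, mcmc_schedule(300, 100, 2, seed = 7))
  expect_false(any(!is.finite(s$mu_acc)))
  expect_false(any(!is.finite(s$Sigma_e)))
})

test_that("student-t and near-gaussian marker priors agree in the low-heritability regime", {
  tp <- toy_panel(n_acc = 80, n_snps = 300, h2 = 0.15, bg = 0.3,
                  n_rep = 6, seed = 61, n_causal = 300,
                  causal_range = c(0, 0.5),
                  maf = list(dist = "uniform", min = 0.1, max = 0.5))
  basis <- eigenbasis(kernel_vanraden(tp$G))
  fit <- function(mdf) {
    m <- hb_model(tp$phenotypes, basis,
                  hb_spec(error_df = Inf, marker_df = mdf,
                          year_level = "none"))
    mean(marker_h2(run_mcmc(m, mcmc_schedule(1500, 500, 5, seed = 9)), 1)$draws)
  }
  expect_lt(abs(fit(3) - fit(1000)), 0.1)
})
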