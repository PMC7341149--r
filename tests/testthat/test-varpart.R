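# Hand-built posterior sample objects with known per-draw quantities.
fake_samples <- function(gebv, Ss, Se, traits = NULL) {
  S <- dim(gebv)[1]; d <- dim(gebv)[3]
  structure(list(gebv = gebv, Sigma_s = Ss, Sigma_e = Se,
                 mu_acc = gebv, n_draws = S,
                 traits = traits %||% sprintf("trait%d", seq_len(d)),
                 accessions = sprintf("acc%03d", seq_len(dim(gebv)[2]))),
            class = "hb_samples")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("marker heritability is the GEBV-variance fraction per draw", {
  n_acc <- 50
  g <- scale(rnorm(n_acc))[, 1]          # unit sample variance exactly
  gebv <- array(0, c(30, n_acc, 1))
  for (s in 1:30) gebv[s, , 1] <- g
  Ss <- array(1, c(30, 1, 1)); Se <- array(2, c(30, 1, 1))
  out <- marker_h2(fake_samples(gebv, Ss, Se), 1)
  # Vm = 1, Ss = 1, Se = 2 -> 0.25
  expect_equal(out$draws, rep(0.25, 30), tolerance = 1e-12)

  # zero marker effects -> 0; pure-marker limit -> 1
  out0 <- marker_h2(fake_samples(array(0, c(30, n_acc, 1)), Ss, Se), 1)
  expect_equal(out0$draws, rep(0, 30))
  out1 <- marker_h2(fake_samples(gebv, array(0, c(30, 1, 1)),
                                 array(0, c(30, 1, 1))), 1)
  expect_equal(out1$draws, rep(1, 30), tolerance = 1e-12)

  # fully degenerate draws are excluded with a warning
  expect_warning(
    outd <- marker_h2(fake_samples(array(0, c(30, n_acc, 1)),
                                   array(0, c(30, 1, 1)),
                                   array(c(0, rep(1, 29)), c(30, 1, 1))), 1),
    "excluded")
  expect_identical(outd$n_undefined, 1L)
  expect_length(outd$draws, 29)
})

test_that("broad-sense heritability and background fraction satisfy their identities", {
  n_acc <- 40
  gebv <- array(0, c(25, n_acc, 1))
  Ss <- array(3, c(25, 1, 1)); Se <- array(1, c(25, 1, 1))
  out <- broad_sense(fake_samples(gebv, Ss, Se), 1)
  expect_equal(out$draws, rep(0.75, 25))
  expect_equal(out$background$draws, rep(0.75, 25))

  # on a real fitted chain: h2m + background = H2 per draw, all in [0, 1]
  tp <- toy_panel(n_acc = 30, n_snps = 100, h2 = 0.4, bg = 0.2, n_rep = 3,
                  seed = 55)
  basis <- eigenbasis(kernel_vanraden(tp$G))
  s <- run_mcmc(hb_model(tp$phenotypes, basis,
                         hb_spec(error_df = Inf, year_level = "none")),
                mcmc_schedule(400, 100, 3, seed = 2))
  h2 <- marker_h2(s, 1); bs <- broad_sense(s, 1)
  expect_equal(h2$draws + bs$background$draws, bs$draws, tolerance = 1e-12)
  expect_true(all(bs$draws >= h2$draws))
  expect_true(all(h2$draws >= 0 & bs$draws <= 1))
})

test_that("genetic correlation combines GEBV and background covariance", {
  n_acc <- 30; S <- 25
  g <- scale(rnorm(n_acc))[, 1]
  gebv <- array(0, c(S, n_acc, 2))
  # identical trait columns with no background -> correlation exactly 1
  for (s in 1:S) { gebv[s, , 1] <- g; gebv[s, , 2] <- g }
  Ss0 <- array(0, c(S, 2, 2))
  Se <- array(0, c(S, 2, 2))
  out <- genetic_correlation(fake_samples(gebv, Ss0, Se), 1, 2)
  expect_equal(out$draws, rep(1, S), tolerance = 1e-12)
  # shared background covariance halves the correlation of the total
  Ss <- array(0, c(S, 2, 2))
  for (s in 1:S) Ss[s, , ] <- diag(c(1, 1))
  outh <- genetic_correlation(fake_samples(gebv, Ss, Se), 1, 2)
  expect_equal(outh$draws, rep(0.5, S), tolerance = 1e-12)
  # diagonal background and zero marker effects -> correlation 0
  out0 <- genetic_correlation(fake_samples(array(0, c(S, n_acc, 2)), Ss, Se),
                              1, 2)
  expect_equal(out0$draws, rep(0, S))
})

test_that("genetic correlation is recovered from correlated two-trait data", {
  C <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  spec <- sim_spec(n_accessions = 80, n_snps = 200, n_causal = 200,
                   causal_maf_range = c(0, 0.5), n_traits = 2,
                   maf = list(dist = "uniform", min = 0.1, max = 0.5),
                   target_marker_h2 = 0.4, target_background_var = 0.3,
                   genetic_correlation = C, n_replicates = 4, seed = 71)
  G <- simulate_genotypes(spec)
  sim <- simulate_phenotypes(G, spec)
  basis <- eigenbasis(kernel_vanraden(G))
  s <- run_mcmc(hb_model(sim$phenotypes, basis,
                         hb_spec(error_df = Inf, year_level = "none")),
                mcmc_schedule(1500, 500, 5, seed = 3))
  gc <- genetic_correlation(s, 1, 2)
  expect_gte(0.8, gc$summary$hpd95[1])
  expect_lte(0.8, gc$summary$hpd95[2])
  expect_lt(abs(gc$summary$mode - 0.8), 0.15)
})

test_that("posterior mode tracks the density peak, not the mean", {
  expect_equal(posterior_mode(rep(0.3, 50)), 0.3)
  set.seed(101)
  x <- rnorm(1e5, 2, 0.4)
  expect_lt(abs(posterior_mode(x) - 2), 0.02)
  b <- rbeta(1e5, 2, 20)
  m <- posterior_mode(b, bounded = TRUE)
  expect_lt(abs(m - 1 / 20), abs(m - 2 / 22))
  expect_error(posterior_mode(1:5), "at least 10")
  # boundary-heavy samples are not pushed inward by the reflection
  z <- abs(rnorm(1e4, 0, 0.05))
  expect_lt(posterior_mode(z, bounded = TRUE), 0.03)
})

test_that("HPD intervals are shortest, nested and correctly sized", {
  set.seed(55)
  u <- runif(5e4)
  h <- hpd_interval(u, 0.95)
  expect_lt(abs(diff(h) - 0.95), 0.02)
  expect_equal(hpd_interval(rep(0.4, 30), 0.5), c(0.4, 0.4))
  x <- rnorm(2000)
  h50 <- hpd_interval(x, 0.5); h95 <- hpd_interval(x, 0.95)
  expect_gte(h50[1], h95[1])
  expect_lte(h50[2], h95[2])
  expect_error(hpd_interval(x, 1.2), "mass")
  expect_error(hpd_interval(x[1:5], 0.5), "at least 20")
  # mode lies inside the 95% interval on a fitted summary
  s <- posterior_summary(rbeta(500, 3, 5), bounded = TRUE)
  expect_gte(s$mode, s$hpd95[1])
  expect_lte(s$mode, s$hpd95[2])
})

test_that("variance partition table covers every trait and component", {
  tp <- toy_panel(n_acc = 25, n_snps = 80, h2 = 0.4, bg = 0.1, n_rep = 3,
                  seed = 77)
  basis <- eigenbasis(kernel_vanraden(tp$G))
  s <- run_mcmc(hb_model(tp$phenotypes, basis,
                         hb_spec(error_df = Inf, year_level = "none")),
                mcmc_schedule(300, 100, 2, seed = 4))
  vp <- variance_partition(s)
  expect_equal(nrow(vp), 3L)
  expect_setequal(vp$component,
                  c("marker_h2", "background_fraction", "broad_sense_H2"))
  expect_true(all(vp$hpd95_lower <= vp$mode & vp$mode <= vp$hpd95_upper))
})
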