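test_that("sim_spec validates its inputs", {
  expect_error(sim_spec(causal_maf_range = c(0.4, 0.1)), "lower bound exceeds")
  expect_error(sim_spec(causal_maf_range = c(0, 0.7)), "within \\[0, 0.5\\]")
  expect_error(sim_spec(target_marker_h2 = 1.2), "\\[0, 1\\]")
  expect_error(sim_spec(n_causal = 50, n_snps = 10, causal_in_panel = TRUE),
               "exceeds n_snps")
  bad_cor <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(sim_spec(n_traits = 2, genetic_correlation = bad_cor),
               "symmetric")
  expect_error(sim_spec(error_df = 2), "error_df")
})

test_that("simulated genotypes are homozygous dosages with the requested spectrum", {
  spec <- sim_spec(n_accessions = 1000, n_snps = 200,
                   maf = list(dist = "point", value = 0.5), seed = 7)
  G <- simulate_genotypes(spec)
  expect_true(all(G$dosage %in% c(0, 2)))
  # binomial bound: sample MAF within +/-0.05 of 0.5 for >= 95% of SNPs
  # (se = sqrt(0.25/1000) ~ 0.016, so 0.05 is > 3 se)
  f <- allele_freq(G)
  expect_gte(mean(abs(f - 0.5) <= 0.05), 0.95)

  # degenerate point mass at 0 is rejected
  expect_error(simulate_genotypes(
    sim_spec(maf = list(dist = "point", value = 0))), "\\(0, 0.5\\]")

  # beta spectrum skews toward rare alleles
  spec2 <- sim_spec(n_accessions = 500, n_snps = 1000,
                    maf = list(dist = "beta", shape1 = 0.5, shape2 = 2,
                               min = 0.005, max = 0.5), seed = 8)
  f2 <- allele_freq(simulate_genotypes(spec2))
  f2 <- pmin(f2, 1 - f2)
  expect_gt(sum(f2 < 0.1), sum(f2 > 0.4))
})

test_that("genotype simulation is deterministic under the seed", {
  spec <- sim_spec(n_accessions = 3, n_snps = 2, n_causal = 0,
                   target_marker_h2 = 0, seed = 99)
  expect_identical(simulate_genotypes(spec)$dosage,
                   simulate_genotypes(spec)$dosage)
  ph1 <- simulate_phenotypes(simulate_genotypes(spec), spec)
  ph2 <- simulate_phenotypes(simulate_genotypes(spec), spec)
  expect_identical(ph1$phenotypes$value, ph2$phenotypes$value)
})

test_that("phenotypes hit their variance targets and degenerate limits", {
  # null trait: between-accession variance of replicate means ~ Ve / n_reps
  spec <- sim_spec(n_accessions = 400, n_snps = 50, n_causal = 0,
                   target_marker_h2 = 0, target_background_var = 0,
                   error_var = 1, n_replicates = 4, seed = 5)
  G <- simulate_genotypes(spec)
  sim <- simulate_phenotypes(G, spec)
  am <- tapply(sim$phenotypes$value, sim$phenotypes$accession, mean)
  # chi-square spread around 1/4 with 399 df: ~7% tolerance covers 3 se
  expect_lt(abs(var(am) - 1 / 4), 0.07 * 1 / 4 + 0.02)

  # realized accession-level variances equal the targets exactly
  tp <- toy_panel(h2 = 0.5, bg = 0.25, seed = 31)
  expect_equal(unname(tp$truth$marker_variance),
               0.5 * (0.25 + 1) / 0.5, tolerance = 1e-10)
  expect_equal(unname(tp$truth$background_variance), 0.25, tolerance = 1e-10)

  # zero-noise limit: replicates within accession identical
  spec0 <- sim_spec(n_accessions = 10, n_snps = 20, n_causal = 5,
                    target_marker_h2 = 0.5, target_background_var = 0.1,
                    error_var = 0, n_replicates = 2, seed = 6)
  sim0 <- simulate_phenotypes(simulate_genotypes(spec0), spec0)
  spread <- tapply(sim0$phenotypes$value, sim0$phenotypes$accession,
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))

  # unreachable marker target
  spec_bad <- sim_spec(n_causal = 0, target_marker_h2 = 0.5)
  expect_error(simulate_phenotypes(simulate_genotypes(spec_bad), spec_bad),
               "unreachable")
})

test_that("multi-trait generation respects the genetic correlation", {
  C <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  spec <- sim_spec(n_accessions = 300, n_snps = 400, n_causal = 100,
                   causal_maf_range = c(0.1, 0.5), n_traits = 2,
                   target_marker_h2 = 0.5, target_background_var = 0.3,
                   genetic_correlation = C, n_replicates = 2, seed = 13)
  sim <- simulate_phenotypes(simulate_genotypes(spec), spec)
  expect_equal(dim(sim$truth$genetic_values), c(300L, 2L))
  expect_lt(abs(sim$truth$genetic_correlation[1, 2] - 0.8), 0.1)
})

test_that("student-t noise produces heavier tails than gaussian at equal variance", {
  tp_t <- toy_panel(n_acc = 300, n_snps = 20, h2 = 0, n_causal = 0,
                    n_rep = 10, error_df = 3, seed = 77)
  tp_g <- toy_panel(n_acc = 300, n_snps = 20, h2 = 0, n_causal = 0,
                    n_rep = 10, error_df = Inf, seed = 77)
  kt <- function(x) mean((x - mean(x))^4) / var(x)^2
  expect_gt(kt(tp_t$phenotypes$value), kt(tp_g$phenotypes$value) + 1)
})

test_that("write_dataset round-trips through the readers", {
  tp <- toy_panel(n_acc = 12, n_snps = 15, seed = 3, n_causal = 4)
  tp$G$dosage[1, 2] <- NA  # exercise the missing-cell dialect
  dir <- withr::local_tempdir()
  files <- write_dataset(tp$G, tp$phenotypes, tp$truth, dir)
  G2 <- read_genotypes(files[["genotypes"]], "tsv")
  expect_identical(G2$dosage, tp$G$dosage)
  ph2 <- utils::read.table(files[["phenotypes"]], header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expect_equal(ph2$value, tp$phenotypes$value)
  tr <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_identical(tr$causal_ids, tp$truth$causal_ids)
  expect_equal(unlist(tr$effects[[1]]), unname(tp$truth$effects[, 1]),
               tolerance = 1e-12)
})
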