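#' Specify a synthetic replicated-panel dataset
#'
#' Describes a simulated study of fully homozygous (inbred) accessions
#' genotyped at biallelic SNPs and phenotyped in replicate, mirroring the
#' design of diversity-panel experiments on selfing crops: independent SNPs
#' with a controllable minor-allele-frequency spectrum, a set of causal
#' variants whose frequency and panel membership are controllable, correlated
#' traits, replicate measurements with optional year batch effects, and
#' optionally heavy-tailed (Student-t) measurement noise.
#'
#' Variance targets are interpreted at the accession level: the causal-variant
#' (marker) variance \eqn{V_m} is chosen so that
#' \eqn{V_m / (V_m + V_b + V_e)} equals `target_marker_h2`, where
#' \eqn{V_b} = `target_background_var` and \eqn{V_e} = `error_var` (the
#' variance of a single replicate measurement's noise). Causal effects and
#' background draws are rescaled so the realized accession-level sample
#' variances hit the targets exactly; the realized values are recorded in the
#' ground-truth object returned by [simulate_phenotypes()].
#'
#' @param n_accessions Number of inbred accessions (>= 2).
#' @param n_snps Number of genotyped SNPs in the panel.
#' @param maf Minor-allele-frequency spectrum, a list with element `dist` one
#'   of `"beta"` (shape1/shape2, truncated to \[min, max\]), `"uniform"`
#'   (on \[min, max\]) or `"point"` (all SNPs at `value`). Frequencies must
#'   lie in (0, 0.5]; a point mass at 0 is rejected.
#' @param n_causal Number of causal variants.
#' @param causal_maf_range Length-2 frequency interval from which causal
#'   variants are taken, within \[0, 0.5\].
#' @param causal_in_panel If `TRUE` causal variants are drawn from the
#'   genotyped SNPs; if `FALSE` they are simulated separately and never
#'   appear in the panel (the "untagged" regime — no LD proxy exists).
#' @param n_traits Number of traits measured on every replicate plant.
#' @param target_marker_h2 Per-trait fraction of phenotypic variance due to
#'   causal-variant additive effects, in \[0, 1\].
#' @param target_background_var Per-trait accession-level genetic variance not
#'   attributable to the causal variants (polygenic background).
#' @param error_var Per-trait variance of a single replicate's measurement
#'   noise.
#' @param genetic_correlation Trait-by-trait correlation matrix of total
#'   genetic values (symmetric, unit diagonal, positive semidefinite).
#' @param n_replicates Replicate measurements per accession.
#' @param year_labels Optional year batch structure: a list with `years`
#'   (labels cycled over replicates) and `offsets` (a `length(years)` x
#'   `n_traits` matrix of additive batch effects).
#' @param error_df Degrees of freedom of the Student-t measurement noise;
#'   `Inf` (default) gives Gaussian noise. Finite values must exceed 2 so the
#'   noise variance is defined.
#' @param effect_dist `"gaussian"` (default) or `"constant"` magnitude causal
#'   effects (random signs).
#' @param missing_rate Fraction of genotype calls set missing completely at
#'   random (default 0).
#' @param seed Integer seed; all simulation functions are deterministic
#'   given the spec.
#'
#' @return An object of class `sim_spec`.
#' @seealso [simulate_genotypes()], [simulate_phenotypes()], [write_dataset()]
#' @export
sim_spec <- function(n_accessions = 100,
                     n_snps = 1000,
                     maf = list(dist = "beta", shape1 = 0.5, shape2 = 2,
                                min = 0.005, max = 0.5),
                     n_causal = 20,
                     causal_maf_range = c(0.1, 0.5),
                     causal_in_panel = TRUE,
                     n_traits = 1,
                     target_marker_h2 = 0.4,
                     target_background_var = 0,
                     error_var = 1,
                     genetic_correlation = NULL,
                     n_replicates = 6,
                     year_labels = NULL,
                     error_df = Inf,
                     effect_dist = c("gaussian", "constant"),
                     missing_rate = 0,
                     seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  d <- as.integer(n_traits)
  if (is.null(genetic_correlation)) genetic_correlation <- diag(d)
  target_marker_h2 <- rep_len(target_marker_h2, d)
  target_background_var <- rep_len(target_background_var, d)
  error_var <- rep_len(error_var, d)

  spec <- structure(list(
    n_accessions = as.integer(n_accessions), n_snps = as.integer(n_snps),
    maf = maf, n_causal = as.integer(n_causal),
    causal_maf_range = as.numeric(causal_maf_range),
    causal_in_panel = isTRUE(causal_in_panel), n_traits = d,
    target_marker_h2 = target_marker_h2,
    target_background_var = target_background_var,
    error_var = error_var, genetic_correlation = genetic_correlation,
    n_replicates = as.integer(n_replicates), year_labels = year_labels,
    error_df = error_df, effect_dist = effect_dist,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  with(spec, {
    if (n_accessions < 2) stop("n_accessions must be >= 2", call. = FALSE)
    if (n_snps < 1) stop("n_snps must be >= 1", call. = FALSE)
    if (any(target_marker_h2 < 0 | target_marker_h2 > 1))
      stop("target_marker_h2 must lie in [0, 1]", call. = FALSE)
    if (any(target_marker_h2 >= 1))
      stop("target_marker_h2 = 1 requires zero background and error variance; use a value < 1",
           call. = FALSE)
    if (any(target_background_var < 0) || any(error_var < 0))
      stop("variances must be non-negative", call. = FALSE)
    if (causal_maf_range[1] > causal_maf_range[2])
      stop("causal_maf_range: lower bound exceeds upper bound", call. = FALSE)
    if (causal_maf_range[1] < 0 || causal_maf_range[2] > 0.5)
      stop("causal_maf_range must lie within [0, 0.5]", call. = FALSE)
    if (causal_in_panel && n_causal > n_snps)
      stop("n_causal exceeds n_snps with causal_in_panel = TRUE", call. = FALSE)
    C <- genetic_correlation
    if (nrow(C) != n_traits || max(abs(C - t(C))) > 1e-10 ||
        max(abs(diag(C) - 1)) > 1e-10 || min(eigen(C, symmetric = TRUE,
                                                   only.values = TRUE)$values) < -1e-8)
      stop("genetic_correlation must be symmetric, unit-diagonal and positive semidefinite",
           call. = FALSE)
    if (is.finite(error_df) && error_df <= 2)
      stop("error_df must exceed 2 (finite noise variance) or be Inf", call. = FALSE)
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must lie in [0, 1)", call. = FALSE)
    if (!is.null(year_labels)) {
      if (!is.list(year_labels) || is.null(year_labels$years))
        stop("year_labels must be a list with elements 'years' and 'offsets'",
             call. = FALSE)
    }
  })
  invisible(spec)
}

draw_maf <- function(maf, n) {
  lo <- maf$min %||% 0.005
  hi <- maf$max %||% 0.5
  if (lo > hi) stop("maf spectrum bounds: min exceeds max", call. = FALSE)
  p <- switch(maf$dist,
    point = {
      if (maf$value <= 0 || maf$value > 0.5)
        stop("point-mass allele frequency must lie in (0, 0.5]", call. = FALSE)
      rep(maf$value, n)
    },
    uniform = {
      if (lo <= 0) stop("maf min must be > 0", call. = FALSE)
      stats::runif(n, lo, hi)
    },
    beta = {
      # truncated beta via inverse-CDF so the draw count is seed-stable
      plo <- stats::pbeta(max(lo, 1e-12), maf$shape1, maf$shape2)
      phi <- stats::pbeta(hi, maf$shape1, maf$shape2)
      stats::qbeta(stats::runif(n, plo, phi), maf$shape1, maf$shape2)
    },
    stop("unknown maf distribution: ", maf$dist, call. = FALSE)
  )
  pmin(pmax(p, 1e-12), 0.5)
}

# Homozygous dosages: accession carries the minor allele (dosage 2) w.p. p.
draw_dosages <- function(n_acc, p) {
  n_snp <- length(p)
  X <- matrix(0, n_acc, n_snp)
  X[] <- 2 * (matrix(stats::runif(n_acc * n_snp), n_acc, n_snp) <
                matrix(p, n_acc, n_snp, byrow = TRUE))
  X
}

#' Simulate a homozygous-panel genotype matrix
#'
#' Draws per-SNP allele frequencies from the spec's MAF spectrum, then
#' independent homozygous dosages (0 or 2) per accession. SNPs are simulated
#' without linkage disequilibrium; the rare-untagged regime is produced by
#' frequency and panel-membership controls, not LD decay. Columns that come
#' out monomorphic by sampling are retained (real panels contain them; they
#' are removed by [filter_variants()]).
#'
#' @param spec A [sim_spec()].
#' @return A [genotype_matrix()] with accession ids `acc001, ...` and SNP ids
#'   `snp000001, ...`; variant records place SNPs on a single synthetic
#'   chromosome at 1-based kilobase spacing.
#' @export
simulate_genotypes <- function(spec) {
  validate_sim_spec(spec)
  set.seed(spec$seed)
  p <- draw_maf(spec$maf, spec$n_snps)
  X <- draw_dosages(spec$n_accessions, p)
  if (spec$missing_rate > 0) {
    X[stats::runif(length(X)) < spec$missing_rate] <- NA_real_
  }
  acc <- sprintf("acc%03d", seq_len(spec$n_accessions))
  ids <- sprintf("snp%06d", seq_len(spec$n_snps))
  dimnames(X) <- list(acc, ids)
  variants <- data.frame(
    id = ids, chrom = "chr1", pos = seq_len(spec$n_snps) * 1000L,
    ref = "A", alt = "T", stringsAsFactors = FALSE
  )
  genotype_matrix(X, variants)
}

scale_to_var <- function(M, v) {
  # rescale columns to exact sample variance v (keeps correlations)
  for (p in seq_len(ncol(M))) {
    s <- stats::sd(M[, p])
    M[, p] <- if (s > 0 && v[p] > 0) (M[, p] - mean(M[, p])) / s * sqrt(v[p]) else 0
  }
  M
}

#' Simulate replicated phenotypes with known genetic architecture
#'
#' Builds per-accession genetic values as causal-dosage-by-effect sums plus a
#' correlated polygenic background, then replicate measurements with optional
#' year batch offsets and Gaussian or Student-t noise (implemented as a Gamma
#' scale mixture, matching the latent-scale representation used by the
#' hierarchical model). Effects and background draws are rescaled so realized
#' accession-level sample variances equal the spec targets exactly.
#'
#' @param G A [genotype_matrix()] produced by [simulate_genotypes()] from the
#'   same spec (needed when `causal_in_panel = TRUE`).
#' @param spec A [sim_spec()].
#' @return A list with `phenotypes` (long-format data.frame with columns
#'   accession, trait, value, year, treatment, replicate) and `truth`
#'   (class `synthetic_truth`: causal ids, scaled effects, genetic values,
#'   realized variance components and genetic correlations, error scale).
#' @export
simulate_phenotypes <- function(G, spec) {
  validate_sim_spec(spec)
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$dosage) != spec$n_accessions)
    stop("genotype matrix inconsistent with spec: accession count differs",
         call. = FALSE)
  d <- spec$n_traits
  n_acc <- spec$n_accessions
  if (spec$n_causal == 0 && any(spec$target_marker_h2 > 0))
    stop("target_marker_h2 > 0 is unreachable with n_causal = 0", call. = FALSE)
  set.seed(spec$seed + 1000003L)

  Vb <- spec$target_background_var
  Ve <- spec$error_var
  h2 <- spec$target_marker_h2
  Vm <- ifelse(h2 > 0, h2 * (Vb + Ve) / (1 - h2), 0)

  # --- causal genotypes
  if (spec$n_causal > 0) {
    if (spec$causal_in_panel) {
      f <- allele_freq(G)
      f <- pmin(f, 1 - f)  # minor-allele frequency
      eligible <- which(f >= spec$causal_maf_range[1] &
                          f <= spec$causal_maf_range[2])
      if (length(eligible) < spec$n_causal)
        stop("only ", length(eligible), " panel SNPs fall in causal_maf_range; ",
             spec$n_causal, " required", call. = FALSE)
      causal_idx <- sort(sample(eligible, spec$n_causal))
      causal_ids <- colnames(G$dosage)[causal_idx]
      Xc <- G$dosage[, causal_idx, drop = FALSE]
      Xc[is.na(Xc)] <- 0  # rare under default missing_rate = 0
    } else {
      pc <- stats::runif(spec$n_causal,
                         max(spec$causal_maf_range[1], 1e-4),
                         spec$causal_maf_range[2])
      Xc <- draw_dosages(n_acc, pc)
      causal_ids <- sprintf("causal%04d", seq_len(spec$n_causal))
      colnames(Xc) <- causal_ids
    }
  } else {
    Xc <- matrix(0, n_acc, 0)
    causal_ids <- character(0)
  }

  C <- spec$genetic_correlation
  # --- causal effects, correlated across traits
  if (spec$n_causal > 0) {
    B <- rmvn(spec$n_causal, C)
    if (spec$effect_dist == "constant") B <- sign(B)
    M <- Xc %*% B
    M <- scale_to_var(M, Vm)
    # back out the effectively applied effects (centering absorbs intercept)
    sd0 <- apply(Xc %*% B, 2, stats::sd)
    scl <- ifelse(sd0 > 0 & Vm > 0, sqrt(Vm) / sd0, 0)
    B <- sweep(B, 2, scl, "*")
  } else {
    B <- matrix(0, 0, d)
    M <- matrix(0, n_acc, d)
  }

  bg <- scale_to_var(rmvn(n_acc, C), Vb)
  g <- M + bg
  rownames(g) <- rownames(G$dosage)

  # --- replicates
  n_rep <- spec$n_replicates
  trait_names <- sprintf("trait%d", seq_len(d))
  yl <- spec$year_labels
  years <- if (is.null(yl)) "year1" else yl$years
  offsets <- if (is.null(yl)) matrix(0, 1, d) else {
    o <- yl$offsets %||% matrix(0, length(years), d)
    matrix(as.numeric(o), length(years), d)
  }
  year_of_rep <- rep_len(seq_along(years), n_rep)

  nu <- spec$error_df
  # marginal noise variance = Ve regardless of df
  Se <- diag(if (is.finite(nu)) Ve * (nu - 2) / nu else Ve, d)
  n_rows <- n_acc * n_rep
  w <- if (is.finite(nu)) stats::rgamma(n_rows, nu / 2, nu / 2) else rep(1, n_rows)
  E <- rmvn(n_rows, Se) / sqrt(w)

  acc_of_row <- rep(seq_len(n_acc), each = n_rep)
  rep_of_row <- rep(seq_len(n_rep), times = n_acc)
  Y <- g[acc_of_row, , drop = FALSE] +
    offsets[year_of_rep[rep_of_row], , drop = FALSE] + E

  phenotypes <- data.frame(
    accession = rep(rownames(G$dosage)[acc_of_row], times = d),
    trait = rep(trait_names, each = n_rows),
    value = as.vector(Y),
    year = rep(years[year_of_rep[rep_of_row]], times = d),
    treatment = "none",
    replicate = rep(rep_of_row, times = d),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    causal_ids = causal_ids,
    causal_in_panel = spec$causal_in_panel,
    effects = B,
    genetic_values = g,
    marker_variance = apply(M, 2, stats::var),
    background_variance = apply(bg, 2, stats::var),
    error_variance = Ve,
    error_df = nu,
    genetic_correlation = if (d > 1) stats::cor(g) else matrix(1, 1, 1),
    trait_names = trait_names,
    seed = spec$seed,
    spec = spec
  ), class = "synthetic_truth")

  list(phenotypes = phenotypes, truth = truth)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genotypes.tsv` (rows = accessions, first column `accession`, one
#' column per SNP, cells in \{0, 1, 2, NA\}), `phenotypes.tsv` (long format)
#' and `truth.json`. The genotype file round-trips losslessly through
#' [read_genotypes()].
#'
#' @param G A [genotype_matrix()].
#' @param phenotypes Long-format phenotype data.frame.
#' @param truth A `synthetic_truth` object (or `NULL` to skip).
#' @param dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(G, phenotypes, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gf <- file.path(dir, "genotypes.tsv")
  pf <- file.path(dir, "phenotypes.tsv")
  gm <- data.frame(accession = rownames(G$dosage), G$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gm, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(phenotypes, pf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(genotypes = gf, phenotypes = pf)
  if (!is.null(truth)) {
    tf <- file.path(dir, "truth.json")
    tr <- truth
    tr$spec <- unclass(tr$spec)
    tr$effects <- as.data.frame(tr$effects)
    tr$genetic_values <- as.data.frame(tr$genetic_values)
    jsonlite::write_json(unclass(tr), tf, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    files <- c(files, truth = tf)
  }
  invisible(files)
}
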