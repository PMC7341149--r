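#' Construct a genotype matrix object
#'
#' Container for an accessions-by-SNP minor-allele dosage matrix from a fully
#' or partially inbred panel. Dosages are 0, 1 or 2 copies of the counted
#' (minor, by convention) allele; `NA` marks missing calls.
#'
#' @param dosage Numeric matrix, rows = accessions (rownames required),
#'   columns = SNPs (colnames required), entries in \{0, 1, 2, NA\}.
#' @param variants Optional data.frame of variant records with columns `id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`; defaults to placeholders.
#' @return An object of class `genotype_matrix` with elements `dosage`,
#'   `variants` and an allele-frequency cache.
#' @export
genotype_matrix <- function(dosage, variants = NULL) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("acc%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp%06d", seq_len(ncol(dosage)))
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosage[bad]), collapse = ", "), call. = FALSE)
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(dosage), chrom = NA_character_,
                           pos = NA_integer_, ref = NA_character_,
                           alt = NA_character_, stringsAsFactors = FALSE)
  }
  structure(list(dosage = dosage, variants = variants,
                 freq = NULL), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "accessions x", ncol(x$dosage),
      "SNPs;", sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Counted-allele frequencies
#'
#' Per-SNP frequency of the counted allele over non-missing diploid calls.
#'
#' @param G A [genotype_matrix()].
#' @return Numeric vector of length `ncol(G$dosage)`.
#' @export
allele_freq <- function(G) {
  colMeans(G$dosage, na.rm = TRUE) / 2
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect matches [write_dataset()]: a header row of SNP ids, first
#' column `accession`, cells in \{0, 1, 2, NA\}. The VCF path reads diploid GT
#' fields via the vcfR package and counts ALT alleles (`1/1` is dosage 2,
#' `./.` missing); multiallelic records are rejected.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2 || names(tab)[1] != "accession")
    stop("genotype TSV must have an 'accession' first column and >= 1 SNP column",
         call. = FALSE)
  acc <- tab[[1]]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  ok <- cells %in% c("0", "1", "2", "NA", "") | is.na(cells)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable genotype token '%s' at row %d (accession %s), SNP %s",
                 cells[bad[1], bad[2]], bad[1], acc[bad[1]],
                 colnames(cells)[bad[2]]), call. = FALSE)
  }
  X <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells),
                               dimnames = list(acc, colnames(cells))))
  genotype_matrix(X)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multiallelic VCF records are not supported; split them first",
         call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  obs <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dose[obs] <- as.numeric(a1[obs]) + as.numeric(a2[obs])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  X <- t(dose)
  colnames(X) <- ids
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                         alt = fix[, "ALT"], stringsAsFactors = FALSE)
  genotype_matrix(X, variants)
}

#' Variant filter thresholds
#'
#' Defaults retain SNPs whose minor-allele count (over diploid genotypes:
#' a homozygous-minor accession contributes 2, a heterozygote 1, a missing
#' call 0) is strictly greater than 2 — eliminating singletons in a highly
#' inbred panel — and whose fraction of missing calls is strictly below 0.30.
#'
#' @param min_minor_allele_count Retain SNPs with minor-allele count strictly
#'   greater than this (default 2).
#' @param max_missing_fraction Retain SNPs with missing fraction strictly
#'   below this (default 0.30).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_minor_allele_count = 2,
                        max_missing_fraction = 0.30) {
  stopifnot(min_minor_allele_count >= 0,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  structure(list(min_minor_allele_count = min_minor_allele_count,
                 max_missing_fraction = max_missing_fraction),
            class = "filter_spec")
}

#' Filter variants on minor-allele count and missingness
#'
#' The minor allele at each SNP is whichever allele is rarer among observed
#' calls; its count is tallied over diploid genotypes. SNP order is
#' preserved; an empty result is allowed (a message reports the removal
#' counts). The operation is idempotent.
#'
#' @param G A [genotype_matrix()].
#' @param f A [filter_spec()].
#' @return A filtered [genotype_matrix()].
#' @export
filter_variants <- function(G, f = filter_spec()) {
  X <- G$dosage
  n_obs <- colSums(!is.na(X))
  counted <- colSums(X, na.rm = TRUE)            # counted-allele copies
  mac <- pmin(counted, 2 * n_obs - counted)      # minor = rarer of the two
  miss_frac <- 1 - n_obs / nrow(X)
  keep <- mac > f$min_minor_allele_count & miss_frac < f$max_missing_fraction
  keep[n_obs == 0] <- FALSE
  if (!all(keep))
    message(sum(!keep), " of ", ncol(X), " SNPs removed by MAC/missingness filter")
  genotype_matrix(X[, keep, drop = FALSE],
                  G$variants[keep, , drop = FALSE])
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing cell with the per-SNP mean dosage over observed
#' calls; observed cells (and hence per-SNP means) are unchanged. Needed
#' before kernel algebra.
#'
#' @param G A [genotype_matrix()].
#' @return A complete [genotype_matrix()] (imputed values may be fractional;
#'   the dosage-domain check is relaxed for them).
#' @export
impute_missing <- function(G) {
  X <- G$dosage
  nas <- is.na(X)
  if (!any(nas)) return(G)
  if (any(colSums(!nas) == 0))
    stop("some SNPs have no observed calls; run filter_variants() first",
         call. = FALSE)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(nas, arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  out <- G
  out$dosage <- X
  out$freq <- NULL
  out
}

#' Minor-allele-frequency spectrum
#'
#' Histogram of per-SNP minor-allele frequencies (the rarer allele among
#' observed calls, so values lie in \[0, 0.5\]). Useful for checking whether a
#' panel's spectrum is skewed toward rare alleles.
#'
#' @param G A [genotype_matrix()].
#' @param bins Number of equal-width bins on \[0, 0.5\], or a vector of
#'   breakpoints.
#' @return A data.frame with `lower`, `upper`, `count`; counts sum to the
#'   number of SNPs with at least one observed call.
#' @export
maf_spectrum <- function(G, bins = 25) {
  f <- allele_freq(G)
  f <- pmin(f, 1 - f)
  f <- f[!is.nan(f)]
  breaks <- if (length(bins) == 1) seq(0, 0.5, length.out = bins + 1) else bins
  h <- hist(f, breaks = breaks, plot = FALSE, include.lowest = TRUE,
            right = TRUE)
  data.frame(lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1],
             count = h$counts)
}
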