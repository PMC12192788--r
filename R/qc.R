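#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact test for Hardy-Weinberg equilibrium from genotype
#' counts at a biallelic marker. Conditional on the observed allele
#' counts, the p-value is the sum of probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed count. Probabilities are evaluated from the closed-form
#' conditional distribution
#' \deqn{P(n_{AB}) = \frac{n!\,2^{n_{AB}}\,n_A!\,n_B!}{n_{AA}!\,n_{AB}!\,n_{BB}!\,(2n)!}}
#' via log-factorials. A marker with one allele absent admits a single
#' configuration and returns p = 1.
#'
#' @param n_AA,n_AB,n_BB Non-negative integer genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_AA, n_AB, n_BB) {
  n_AA <- as.integer(n_AA); n_AB <- as.integer(n_AB); n_BB <- as.integer(n_BB)
  if (anyNA(c(n_AA, n_AB, n_BB)) || any(c(n_AA, n_AB, n_BB) < 0)) {
    stop("genotype counts must be non-negative integers")
  }
  n <- n_AA + n_AB + n_BB
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2L * n_AA + n_AB
  n_b <- 2L * n_BB + n_AB
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  # feasible heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2L, rare, by = 2L)
  lp <- lfactorial(n) + het * log(2) + lfactorial(n_a) + lfactorial(n_b) -
    lfactorial((n_a - het) / 2) - lfactorial(het) -
    lfactorial((n_b - het) / 2) - lfactorial(2L * n)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_AB, het)]
  if (is.na(p_obs)) stop("n_AB inconsistent with allele count parity")
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

qc_entry <- function(step, scope, n_before, n_removed) {
  tibble::tibble(step = step, scope = scope,
                 n_before = as.integer(n_before),
                 n_removed = as.integer(n_removed),
                 n_remaining = as.integer(n_before - n_removed))
}

#' Filter samples by call rate
#'
#' Retains individuals whose genotype call rate strictly exceeds
#' `min_rate` (a sample at exactly the threshold is removed).
#'
#' @param ds A `genotype_dataset`.
#' @param min_rate Minimum call rate in (0, 1]; default 0.95.
#' @return List with `ds` (filtered dataset) and `entry` (one-row QC
#'   report tibble).
#' @export
filter_sample_call_rate <- function(ds, min_rate = 0.95) {
  stopifnot(inherits(ds, "genotype_dataset"),
            min_rate > 0, min_rate <= 1)
  cr <- rowMeans(!is.na(ds$geno))
  keep <- cr > min_rate
  if (!any(keep)) {
    stop("sample call-rate filter removed every sample; ",
         "review min_rate = ", min_rate)
  }
  list(ds = subset_gds(ds, samples = keep),
       entry = qc_entry("sample_call_rate", "samples",
                        length(keep), sum(!keep)))
}

#' Restrict to autosomal markers
#'
#' Drops markers on non-autosomal or unmapped chromosomes (e.g. X, Y,
#' MT, `0`).
#'
#' @param ds A `genotype_dataset`.
#' @param autosomes Character vector of autosome labels.
#' @return List with `ds` and `entry` as in [filter_sample_call_rate()].
#' @export
filter_autosomes <- function(ds, autosomes = default_autosomes()) {
  stopifnot(inherits(ds, "genotype_dataset"))
  keep <- ds$map$chrom %in% autosomes
  list(ds = subset_gds(ds, snps = keep),
       entry = qc_entry("non_autosomal", "snps", length(keep), sum(!keep)))
}

#' Filter SNPs by missingness
#'
#' Removes markers whose missing-call fraction strictly exceeds
#' `max_missing` (a marker at exactly the threshold is retained).
#'
#' @param ds A `genotype_dataset`.
#' @param max_missing Maximum tolerated missing fraction in `[0, 1)`;
#'   default 0.20.
#' @return List with `ds` and `entry`.
#' @export
filter_snp_missingness <- function(ds, max_missing = 0.20) {
  stopifnot(inherits(ds, "genotype_dataset"),
            max_missing >= 0, max_missing < 1)
  fr <- colMeans(is.na(ds$geno))
  keep <- fr <= max_missing
  if (!any(keep)) warning("missingness filter removed every SNP")
  list(ds = subset_gds(ds, snps = keep),
       entry = qc_entry("snp_missingness", "snps", length(keep), sum(!keep)))
}

#' Filter SNPs by minor allele frequency
#'
#' Removes markers with pooled-population MAF strictly below `min_maf`;
#' monomorphic markers (MAF 0) and markers with no calls are always
#' removed when `min_maf > 0`.
#'
#' @param ds A `genotype_dataset`.
#' @param min_maf Minimum MAF; default 0.05.
#' @return List with `ds` and `entry`.
#' @export
filter_maf <- function(ds, min_maf = 0.05) {
  stopifnot(inherits(ds, "genotype_dataset"), min_maf >= 0, min_maf <= 0.5)
  maf <- snp_maf(ds)$maf
  keep <- !is.na(maf) & maf >= min_maf
  list(ds = subset_gds(ds, snps = keep),
       entry = qc_entry("maf", "snps", length(keep), sum(!keep)))
}

# Per-population HWE p-values for every SNP. Memoised over unique
# genotype-count triples since array data repeats them heavily.
hwe_pvalues_by_population <- function(ds) {
  pops <- unique(ds$samples$population)
  out <- lapply(pops, function(pop) {
    rows <- ds$samples$population == pop
    if (sum(rows) < 2) return(rep(NA_real_, nrow(ds$map)))
    g <- ds$geno[rows, , drop = FALSE]
    nAA <- colSums(g == 0L, na.rm = TRUE)
    nAB <- colSums(g == 1L, na.rm = TRUE)
    nBB <- colSums(g == 2L, na.rm = TRUE)
    key <- paste(nAA, nAB, nBB)
    uk <- !duplicated(key)
    pv <- vapply(which(uk), function(i) {
      if (nAA[i] + nAB[i] + nBB[i] == 0) return(NA_real_)
      hwe_exact_pvalue(nAA[i], nAB[i], nBB[i])
    }, 0)
    names(pv) <- key[uk]
    unname(pv[key])
  })
  names(out) <- pops
  out
}

#' Filter SNPs by Hardy-Weinberg equilibrium
#'
#' Applies the exact test [hwe_exact_pvalue()] within each population
#' separately and removes a marker globally if its p-value falls below
#' `alpha` in at least one population. Populations with fewer than two
#' genotyped individuals are skipped with a warning.
#'
#' @param ds A `genotype_dataset`.
#' @param alpha Significance threshold; default `1e-5`.
#' @return List with `ds`, `entry`, and `pvalues` (tibble of per-SNP,
#'   per-population p-values for the removed markers).
#' @export
filter_hwe <- function(ds, alpha = 1e-5) {
  stopifnot(inherits(ds, "genotype_dataset"), alpha >= 0, alpha <= 1)
  pv <- hwe_pvalues_by_population(ds)
  skipped <- names(pv)[vapply(pv, function(x) all(is.na(x)), TRUE)]
  if (length(skipped)) {
    warning("populations skipped in HWE filter (<2 individuals): ",
            paste(skipped, collapse = ", "))
  }
  pmat <- do.call(cbind, pv)
  deviates <- rowSums(pmat < alpha, na.rm = TRUE) > 0
  removed_tbl <- tibble::as_tibble(pmat[deviates, , drop = FALSE])
  removed_tbl <- dplyr::bind_cols(
    tibble::tibble(snp_id = ds$map$snp_id[deviates]), removed_tbl)
  list(ds = subset_gds(ds, snps = !deviates),
       entry = qc_entry("hwe", "snps", length(deviates), sum(deviates)),
       pvalues = removed_tbl)
}

#' Run the full quality-control cascade
#'
#' Applies, in order: sample call-rate filter, autosome restriction,
#' SNP missingness, minor allele frequency (pooled), and per-population
#' exact Hardy-Weinberg filtering. The per-step accounting reconciles
#' exactly: each step's remaining count is the next step's before count
#' within its scope.
#'
#' @param ds A `genotype_dataset`.
#' @param min_call_rate Sample call-rate threshold (strict >).
#' @param autosomes Autosome labels to keep.
#' @param max_missing SNP missingness threshold (strict >, removal).
#' @param min_maf MAF threshold (strict <, removal).
#' @param hwe_alpha HWE significance threshold (strict <, removal).
#' @return List of class `qc_result`: `ds` (filtered dataset), `report`
#'   (tibble of per-step counts), `hwe_pvalues` (removed-SNP p-values).
#' @export
qc_apply <- function(ds, min_call_rate = 0.95,
                     autosomes = default_autosomes(),
                     max_missing = 0.20, min_maf = 0.05,
                     hwe_alpha = 1e-5) {
  s1 <- filter_sample_call_rate(ds, min_call_rate)
  s2 <- filter_autosomes(s1$ds, autosomes)
  s3 <- filter_snp_missingness(s2$ds, max_missing)
  s4 <- filter_maf(s3$ds, min_maf)
  s5 <- filter_hwe(s4$ds, hwe_alpha)
  report <- dplyr::bind_rows(s1$entry, s2$entry, s3$entry, s4$entry, s5$entry)
  structure(list(ds = s5$ds, report = report, hwe_pvalues = s5$pvalues),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("QC cascade:\n")
  print(as.data.frame(x$report), row.names = FALSE)
  cat("final: ", nrow(x$ds$samples), " samples x ", nrow(x$ds$map),
      " SNPs\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname qc_apply
#' @param x A `qc_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qc_result <- function(x, ...) x$report

#' @rdname qc_apply
#' @exportS3Method generics::glance
glance.qc_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$ds$samples),
    n_snps = nrow(x$ds$map),
    n_samples_removed = sum(x$report$n_removed[x$report$scope == "samples"]),
    n_snps_removed = sum(x$report$n_removed[x$report$scope == "snps"])
  )
}
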