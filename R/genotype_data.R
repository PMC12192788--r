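#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Genotype codes used throughout: 0 = HOM_A (homozygous for allele_a),
# 1 = HET, 2 = HOM_B, NA = missing call.
GENO_HOM_A <- 0L
GENO_HET <- 1L
GENO_HOM_B <- 2L

#' Default autosome labels
#'
#' Chromosome labels treated as autosomes by run detection, summaries and
#' the QC cascade. The default is the sheep autosome set `"1"`--`"26"`;
#' pass a different character vector for other species.
#'
#' @param n Number of autosomes.
#' @return Character vector of chromosome labels.
#' @export
default_autosomes <- function(n = 26) as.character(seq_len(n))

#' Construct a genotype dataset
#'
#' Bundles a marker map, a sample table and an individuals-by-markers
#' genotype matrix into a validated `genotype_dataset` object, the input
#' container for QC, run detection and all downstream steps.
#'
#' @param map Data frame with columns `chrom` (character), `pos`
#'   (integer base pairs, 1-based), `snp_id`, `allele_a`, `allele_b`.
#'   Markers are sorted by (chromosome, position); within a chromosome
#'   positions must be unique.
#' @param samples Data frame with columns `sample_id` and `population`.
#' @param geno Integer matrix, `nrow(samples)` x `nrow(map)`, coded
#'   0 = homozygous for `allele_a`, 1 = heterozygous, 2 = homozygous for
#'   `allele_b`, `NA` = missing.
#' @return A `genotype_dataset`: a list with elements `map` (tibble,
#'   sorted), `samples` (tibble) and `geno` (matrix, columns permuted to
#'   map order, dimnames set to sample and SNP ids).
#' @export
genotype_dataset <- function(map, samples, geno) {
  map <- tibble::as_tibble(map)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("chrom", "pos", "snp_id") %in% names(map)),
    all(c("sample_id", "population") %in% names(samples))
  )
  if (!"allele_a" %in% names(map)) map$allele_a <- NA_character_
  if (!"allele_b" %in% names(map)) map$allele_b <- NA_character_
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (anyDuplicated(map$snp_id)) {
    stop("duplicate snp_id in map: ", map$snp_id[duplicated(map$snp_id)][1])
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  }
  if (any(!nzchar(samples$population)) || anyNA(samples$population)) {
    stop("population labels must be non-empty")
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(map)) {
    stop("geno must be ", nrow(samples), " x ", nrow(map),
         ", got ", nrow(geno), " x ", ncol(geno))
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  ord <- order(chrom_sort_key(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  dup <- duplicated(map[, c("chrom", "pos")])
  if (any(dup)) {
    stop("duplicate (chrom, pos) in map at ", map$chrom[dup][1], ":",
         map$pos[dup][1])
  }
  dimnames(geno) <- list(samples$sample_id, map$snp_id)
  structure(list(map = map, samples = samples, geno = geno),
            class = "genotype_dataset")
}

# Numeric-aware chromosome ordering: "2" before "10", non-numeric labels
# (X, MT, ...) after all numeric ones, alphabetically.
chrom_sort_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), Inf, num)
  order_within <- rank(chrom, ties.method = "min")
  key * 1e6 + ifelse(is.infinite(key), order_within, 0)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset: ", nrow(x$samples), " individuals x ",
      nrow(x$map), " SNPs\n", sep = "")
  cat("chromosomes: ", paste(unique(x$map$chrom), collapse = " "), "\n",
      sep = "")
  pops <- table(x$samples$population)
  cat("populations: ",
      paste(names(pops), " (", as.integer(pops), ")",
            sep = "", collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(nrow(x$samples), nrow(x$map))

#' Subset a genotype dataset
#'
#' @param ds A `genotype_dataset`.
#' @param samples Logical or integer index over individuals (default all).
#' @param snps Logical or integer index over markers (default all).
#' @return A `genotype_dataset` restricted to the selected rows/columns.
#' @export
subset_gds <- function(ds, samples = NULL, snps = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(ds$samples)) else samples
  mi <- if (is.null(snps)) seq_len(nrow(ds$map)) else snps
  genotype_dataset(ds$map[mi, , drop = FALSE],
                   ds$samples[si, , drop = FALSE],
                   ds$geno[si, mi, drop = FALSE])
}

#' Per-sample call rate
#'
#' Fraction of non-missing genotype calls per individual.
#'
#' @param ds A `genotype_dataset`.
#' @return Tibble with `sample_id`, `population`, `call_rate`.
#' @export
sample_call_rate <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  tibble::tibble(
    sample_id = ds$samples$sample_id,
    population = ds$samples$population,
    call_rate = rowMeans(!is.na(ds$geno))
  )
}

#' Per-SNP minor allele frequency
#'
#' MAF computed from non-missing genotypes with all populations pooled.
#' Monomorphic markers have MAF 0; markers with no calls get `NA`.
#'
#' @param ds A `genotype_dataset`.
#' @return Tibble with `snp_id`, `chrom`, `pos`, `maf`, `n_called`.
#' @export
snp_maf <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- ds$geno
  n_called <- colSums(!is.na(g))
  # allele_b count = het + 2 * hom_b
  b_count <- colSums(g == 1L, na.rm = TRUE) + 2 * colSums(g == 2L, na.rm = TRUE)
  p_b <- ifelse(n_called > 0, b_count / (2 * n_called), NA_real_)
  tibble::tibble(
    snp_id = ds$map$snp_id,
    chrom = ds$map$chrom,
    pos = ds$map$pos,
    maf = pmin(p_b, 1 - p_b),
    n_called = as.integer(n_called)
  )
}
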