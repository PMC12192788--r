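# Small in-memory fixtures built in code.

make_map <- function(pos_by_chrom) {
  map <- dplyr::bind_rows(lapply(names(pos_by_chrom), function(ch) {
    tibble::tibble(chrom = ch, pos = as.integer(pos_by_chrom[[ch]]))
  }))
  map$snp_id <- sprintf("s_%s_%d", map$chrom, map$pos)
  map$allele_a <- "A"
  map$allele_b <- "G"
  map
}

# geno: matrix or vector (one individual); populations recycled
make_gds <- function(geno, pos_by_chrom, populations = "P1") {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  n <- nrow(geno)
  samples <- tibble::tibble(
    sample_id = sprintf("id%02d", seq_len(n)),
    population = rep_len(populations, n))
  genotype_dataset(make_map(pos_by_chrom), samples, geno)
}

# evenly spaced positions: n markers, step bp apart, from start
even_pos <- function(n, step = 2e4, start = 1e6) {
  seq(start, by = step, length.out = n)
}

# a run tibble row
run_row <- function(sample_id, chrom, start_bp, end_bp, population = "P1") {
  tibble::tibble(sample_id = sample_id, population = population,
                 chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 n_snps = 30L, n_opposite = 0L, n_missing = 0L,
                 length_bp = as.numeric(end_bp - start_bp))
}
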