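#' Simulation configuration
#'
#' Parameters of the synthetic genotype generator. The default genome is
#' a desk-scale stand-in for a medium-density livestock array: 5
#' chromosomes of 50 Mb carrying 1,000 SNPs each, allele frequencies
#' uniform on \[0.05, 0.5\], and a 1 cM/Mb genetic map. The full
#' 26-autosome, ~48k-SNP scale is reachable by raising `n_chromosomes`
#' and `n_snps_per_chrom`.
#'
#' @param n_chromosomes Number of autosomes simulated.
#' @param chrom_length_bp Chromosome length in bp (shared).
#' @param n_snps_per_chrom Markers per chromosome, uniformly placed.
#' @param maf_range Range of the allele-b frequency spectrum (drawn
#'   uniformly, then used directly as the B-allele frequency).
#' @param missing_rate Per-call missingness probability, applied last.
#' @param error_rate Per-call genotyping error probability; an erred
#'   call is replaced by one of the two other states uniformly.
#' @param cm_per_mb Genetic map density (centimorgan per megabase) used
#'   by the pedigree gene-drop recombination model.
#' @param seed Optional integer seed applied before any draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 5, chrom_length_bp = 5e7,
                       n_snps_per_chrom = 1000,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0, error_rate = 0,
                       cm_per_mb = 1, seed = NULL) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp > 0, n_snps_per_chrom >= 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1, cm_per_mb > 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 maf_range = as.numeric(maf_range),
                 missing_rate = missing_rate, error_rate = error_rate,
                 cm_per_mb = cm_per_mb,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Simulate a marker map
#'
#' Draws uniformly placed, strictly increasing SNP positions per
#' chromosome and a B-allele frequency for each marker from the
#' configured spectrum.
#'
#' @param config A [sim_config()].
#' @return Map tibble with `chrom`, `pos`, `snp_id`, `allele_a`,
#'   `allele_b` and the simulation column `freq_b`.
#' @export
simulate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, config$n_snps_per_chrom))
    tibble::tibble(chrom = as.character(ch), pos = as.integer(pos))
  })
  map <- dplyr::bind_rows(maps)
  map$snp_id <- sprintf("snp_%s_%07d", map$chrom, map$pos)
  map$allele_a <- "A"
  map$allele_b <- "G"
  map$freq_b <- stats::runif(nrow(map), config$maf_range[1],
                             config$maf_range[2])
  map
}

# Apply symmetric genotyping error then missingness to a genotype matrix.
apply_noise <- function(geno, error_rate, missing_rate) {
  if (error_rate > 0) {
    err <- which(stats::runif(length(geno)) < error_rate & !is.na(geno))
    if (length(err)) {
      # replace by one of the two other states, uniformly
      shift <- sample.int(2, length(err), replace = TRUE)
      geno[err] <- (geno[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0) {
    mis <- stats::runif(length(geno)) < missing_rate
    geno[mis] <- NA_integer_
  }
  geno
}

#' Simulate genotypes with planted runs
#'
#' Generates a cohort whose background genotypes are drawn per SNP from
#' Hardy-Weinberg proportions at the marker's allele frequency, with
#' specified tracts overridden: inside an `autozygous` tract the
#' individual is homozygous (allele drawn by frequency, emulating
#' identity by descent); inside a `heterozygous` tract every call is
#' forced heterozygous. Genotyping error and missingness are applied
#' afterwards, so the truth tracts remain exact.
#'
#' @param config A [sim_config()].
#' @param tracts Tibble with `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `state` (`"autozygous"` or `"heterozygous"`). Tracts of one
#'   individual must not overlap. May be empty.
#' @param n_individuals Cohort size; sample ids are `S001`, `S002`, ...
#' @param population Population label for all individuals.
#' @param map Optional pre-built map from [simulate_map()] (so several
#'   cohorts can share one marker scaffold); generated from `config`
#'   when `NULL`.
#' @param guard_flanks Force the `n_guard` markers immediately outside
#'   each tract to the opposite state (heterozygous around autozygous
#'   tracts, homozygous around heterozygous ones). With more guards
#'   than the scanner's opposite-state allowance, a detected run cannot
#'   extend past the tract's own markers, so noise-free recovery is
#'   exact at the tract's first and last SNP. Default `TRUE`.
#' @param n_guard Guard markers per side; default 4 (exceeds both
#'   default allowances).
#' @return List with `ds` (a `genotype_dataset`) and `truth` (the tract
#'   tibble, echoed exactly).
#' @export
simulate_planted <- function(config, tracts = NULL, n_individuals = 10,
                             population = "SIM", map = NULL,
                             guard_flanks = TRUE, n_guard = 4) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(map)) {
    map <- simulate_map(config)
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  if (is.null(tracts)) {
    tracts <- tibble::tibble(sample_id = character(), chrom = character(),
                             start_bp = numeric(), end_bp = numeric(),
                             state = character())
  }
  stopifnot(all(tracts$state %in% c("autozygous", "heterozygous")))
  sample_ids <- sprintf("S%03d", seq_len(n_individuals))
  if (nrow(tracts) > 0) {
    if (!all(tracts$sample_id %in% sample_ids)) {
      stop("tract sample_id outside cohort ids S001..S",
           sprintf("%03d", n_individuals))
    }
    ov <- tracts |>
      dplyr::group_by(.data$sample_id, .data$chrom) |>
      dplyr::arrange(.data$start_bp, .by_group = TRUE) |>
      dplyr::summarise(bad = dplyr::n() > 1 &&
                         any(.data$start_bp[-1] <= .data$end_bp[-dplyr::n()]),
                       .groups = "drop")
    if (any(ov$bad)) stop("overlapping planted tracts for one individual")
  }
  n_snp <- nrow(map)
  p <- map$freq_b
  geno <- matrix(NA_integer_, n_individuals, n_snp)
  for (i in seq_len(n_individuals)) {
    a1 <- stats::rbinom(n_snp, 1, p)
    a2 <- stats::rbinom(n_snp, 1, p)
    g <- a1 + a2
    tr <- tracts[tracts$sample_id == sample_ids[i], ]
    if (nrow(tr) > 0) {
      in_any <- rep(FALSE, n_snp)
      for (k in seq_len(nrow(tr))) {
        in_tr <- map$chrom == tr$chrom[k] & map$pos >= tr$start_bp[k] &
          map$pos <= tr$end_bp[k]
        in_any <- in_any | in_tr
        if (tr$state[k] == "autozygous") {
          g[in_tr] <- 2L * stats::rbinom(sum(in_tr), 1, p[in_tr])
        } else {
          g[in_tr] <- 1L
        }
      }
      if (guard_flanks) {
        for (k in seq_len(nrow(tr))) {
          on_chr <- which(map$chrom == tr$chrom[k])
          inside <- which(map$chrom == tr$chrom[k] &
                            map$pos >= tr$start_bp[k] &
                            map$pos <= tr$end_bp[k])
          if (!length(inside)) next
          lo <- match(inside[1], on_chr)
          hi <- match(inside[length(inside)], on_chr)
          left <- seq.int(max(1, lo - n_guard), lo)[-(lo - max(1, lo - n_guard) + 1)]
          right <- seq.int(hi, min(length(on_chr), hi + n_guard))[-1]
          guards <- on_chr[c(left, right)]
          guards <- guards[!in_any[guards]]
          if (tr$state[k] == "autozygous") {
            g[guards] <- 1L
          } else {
            g[guards] <- 2L * stats::rbinom(length(guards), 1, p[guards])
          }
        }
      }
    }
    geno[i, ] <- g
  }
  geno <- apply_noise(geno, config$error_rate, config$missing_rate)
  samples <- tibble::tibble(sample_id = sample_ids,
                            population = population)
  list(ds = genotype_dataset(map, samples, geno), truth = tracts)
}
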