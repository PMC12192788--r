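# A haplotype along one chromosome is piecewise founder-origin:
# list(breaks, origin) where breaks[1] == 1 and origin[k] is the founder
# haplotype id on [breaks[k], breaks[k+1]).

founder_hap <- function(id) list(breaks = 1, origin = id)

origin_at <- function(hap, pos) hap$origin[findInterval(pos, hap$breaks)]

# One meiosis under the Haldane (no-interference) model: crossover count
# Poisson with mean equal to the chromosome's genetic length in Morgans,
# crossover positions uniform, starting phase random.
meiosis <- function(h1, h2, chrom_length_bp, morgans) {
  k <- stats::rpois(1, morgans)
  xo <- if (k > 0) sort(stats::runif(k, 1, chrom_length_bp)) else numeric()
  breaks <- sort(unique(c(1, xo, h1$breaks, h2$breaks)))
  phase <- (findInterval(breaks, c(1, xo)) +
              sample.int(2, 1)) %% 2L   # 0/1 alternating at crossovers
  origin <- ifelse(phase == 0L, origin_at(h1, breaks), origin_at(h2, breaks))
  keep <- c(TRUE, diff(origin) != 0)
  list(breaks = breaks[keep], origin = origin[keep])
}

# Maximal intervals where the two haplotypes share founder origin
# (identity by descent), as 1-based inclusive bp intervals.
ibd_intervals <- function(h1, h2, chrom_length_bp) {
  breaks <- sort(unique(c(h1$breaks, h2$breaks)))
  eq <- origin_at(h1, breaks) == origin_at(h2, breaks)
  ends <- c(breaks[-1] - 1, chrom_length_bp)
  r <- rle(eq)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  sel <- which(r$values)
  tibble::tibble(start_bp = floor(breaks[lo[sel]]),
                 end_bp = floor(ends[hi[sel]]))
}

#' Pedigree presets with known expected inbreeding
#'
#' Small pedigrees whose offspring have a classical expected inbreeding
#' coefficient: full-sib mating (F = 0.25), half-sib (F = 0.125),
#' first-cousin (F = 0.0625), and outbred (F = 0).
#'
#' @param type Preset name.
#' @param n_offspring Number of genotyped offspring produced by the
#'   final mating.
#' @return Pedigree tibble with `id`, `sire`, `dam` (`NA` for
#'   founders); offspring ids are `O001`, `O002`, ...
#' @export
pedigree_preset <- function(type = c("fullsib", "halfsib", "first_cousin",
                                     "outbred"),
                            n_offspring = 50) {
  type <- match.arg(type)
  off <- sprintf("O%03d", seq_len(n_offspring))
  base <- switch(type,
    outbred = tibble::tibble(
      id = c("F1", "F2"), sire = NA_character_, dam = NA_character_),
    fullsib = tibble::tibble(
      id = c("F1", "F2", "C1", "C2"),
      sire = c(NA, NA, "F1", "F1"),
      dam = c(NA, NA, "F2", "F2")),
    halfsib = tibble::tibble(
      id = c("F1", "F2", "F3", "C1", "C2"),
      sire = c(NA, NA, NA, "F1", "F1"),
      dam = c(NA, NA, NA, "F2", "F3")),
    first_cousin = tibble::tibble(
      id = c("F1", "F2", "F3", "F4", "C1", "C2", "P1", "P2"),
      sire = c(NA, NA, NA, NA, "F1", "F1", "C1", "C2"),
      dam = c(NA, NA, NA, NA, "F2", "F2", "F3", "F4"))
  )
  parents <- switch(type, outbred = c("F1", "F2"),
                    fullsib = c("C1", "C2"), halfsib = c("C1", "C2"),
                    first_cousin = c("P1", "P2"))
  dplyr::bind_rows(base, tibble::tibble(id = off, sire = parents[1],
                                        dam = parents[2]))
}

#' Simulate genotypes by pedigree gene drop
#'
#' Draws two founder haplotypes per founder (alleles per SNP by the
#' mapped frequency), transmits them through the pedigree with
#' recombination under the Haldane model (crossovers Poisson, mean
#' `cm_per_mb / 100` Morgans per Mb), and genotypes the terminal
#' individuals. The truth set records, per genotyped individual, the
#' maximal autozygous intervals — regions where both haplotypes descend
#' from the same founder haplotype copy — and the resulting autozygous
#' genome fraction.
#'
#' @param config A [sim_config()].
#' @param pedigree Pedigree tibble (`id`, `sire`, `dam`; `NA` parents
#'   mark founders), e.g. from [pedigree_preset()]. Parents must be
#'   listed before their offspring.
#' @param population Population label for the genotyped individuals.
#' @param genotyped Ids to genotype; default every individual that is
#'   not a parent in the pedigree.
#' @param map Optional shared map from [simulate_map()].
#' @return List with `ds` (a `genotype_dataset`), `truth` (tibble
#'   `sample_id`, `chrom`, `start_bp`, `end_bp` of autozygous
#'   intervals) and `truth_fraction` (tibble `sample_id`, `fraction`).
#' @export
simulate_pedigree <- function(config, pedigree, population = "SIM",
                              genotyped = NULL, map = NULL) {
  stopifnot(inherits(config, "sim_config"),
            all(c("id", "sire", "dam") %in% names(pedigree)))
  if (is.null(map)) {
    map <- simulate_map(config)
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  is_founder <- is.na(pedigree$sire) & is.na(pedigree$dam)
  if (any(is.na(pedigree$sire) != is.na(pedigree$dam))) {
    stop("individuals must have both parents or neither")
  }
  known <- pedigree$id[is_founder]
  for (i in which(!is_founder)) {
    for (p in c(pedigree$sire[i], pedigree$dam[i])) {
      if (!p %in% known) {
        stop("pedigree references unknown (or later-listed) individual: ", p)
      }
    }
    known <- c(known, pedigree$id[i])
  }
  if (is.null(genotyped)) {
    genotyped <- setdiff(pedigree$id, c(pedigree$sire, pedigree$dam))
  }
  chroms <- unique(map$chrom)
  L <- config$chrom_length_bp
  morgans <- L / 1e6 * config$cm_per_mb / 100

  founders <- pedigree$id[is_founder]
  n_hap <- 2L * length(founders)
  freq <- map$freq_b
  founder_alleles <- matrix(stats::rbinom(n_hap * nrow(map), 1,
                                          rep(freq, each = n_hap)),
                            nrow = n_hap)

  # gene drop, chromosome by chromosome
  haps <- lapply(chroms, function(ch) {
    h <- list()
    for (i in seq_along(founders)) {
      h[[founders[i]]] <- list(founder_hap(2L * i - 1L),
                               founder_hap(2L * i))
    }
    for (i in which(!is_founder)) {
      s <- h[[pedigree$sire[i]]]
      d <- h[[pedigree$dam[i]]]
      h[[pedigree$id[i]]] <- list(meiosis(s[[1]], s[[2]], L, morgans),
                                  meiosis(d[[1]], d[[2]], L, morgans))
    }
    h
  })
  names(haps) <- chroms

  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  names(chrom_idx) <- chroms
  geno <- matrix(NA_integer_, length(genotyped), nrow(map))
  truth <- list()
  fractions <- numeric(length(genotyped))
  for (j in seq_along(genotyped)) {
    id <- genotyped[j]
    auto_len <- 0
    for (ch in chroms) {
      hp <- haps[[ch]][[id]]
      ci <- chrom_idx[[ch]]
      pos <- map$pos[ci]
      o1 <- origin_at(hp[[1]], pos)
      o2 <- origin_at(hp[[2]], pos)
      geno[j, ci] <- founder_alleles[cbind(o1, ci)] +
        founder_alleles[cbind(o2, ci)]
      iv <- ibd_intervals(hp[[1]], hp[[2]], L)
      if (nrow(iv) > 0) {
        iv$sample_id <- id
        iv$chrom <- ch
        truth[[length(truth) + 1L]] <- iv
        auto_len <- auto_len + sum(iv$end_bp - iv$start_bp + 1)
      }
    }
    fractions[j] <- auto_len / (length(chroms) * L)
  }
  truth_tbl <- if (length(truth)) {
    dplyr::bind_rows(truth)[, c("sample_id", "chrom", "start_bp", "end_bp")]
  } else {
    tibble::tibble(sample_id = character(), chrom = character(),
                   start_bp = numeric(), end_bp = numeric())
  }
  geno <- apply_noise(geno, config$error_rate, config$missing_rate)
  samples <- tibble::tibble(sample_id = genotyped, population = population)
  list(ds = genotype_dataset(map, samples, geno),
       truth = truth_tbl,
       truth_fraction = tibble::tibble(sample_id = genotyped,
                                       fraction = fractions))
}

#' Simulate a multi-population cohort
#'
#' Builds one shared marker map and, per population, gene-drops a
#' pedigree preset to produce cohorts with distinct known inbreeding
#' regimes, concatenated into a single dataset for end-to-end pipeline
#' runs.
#'
#' @param config A [sim_config()]; its seed governs the whole cohort.
#' @param breeds Tibble with `population`, `n` (cohort size) and
#'   `preset` (a [pedigree_preset()] type). Population labels must be
#'   unique.
#' @return List with `ds` (combined `genotype_dataset`), `truth` and
#'   `truth_fraction` (as in [simulate_pedigree()], with a
#'   `population` column added to `truth_fraction`).
#' @export
generate_breed_cohort <- function(config, breeds) {
  stopifnot(all(c("population", "n", "preset") %in% names(breeds)),
            nrow(breeds) >= 1)
  if (anyDuplicated(breeds$population)) stop("duplicate breed label")
  if (!is.null(config$seed)) set.seed(config$seed)
  map <- simulate_map(sim_config_no_seed(config))
  sims <- lapply(seq_len(nrow(breeds)), function(i) {
    ped <- pedigree_preset(breeds$preset[i], n_offspring = breeds$n[i])
    sim <- simulate_pedigree(sim_config_no_seed(config), ped,
                             population = breeds$population[i], map = map)
    # prefix ids so cohorts do not collide
    pre <- function(x) paste0(breeds$population[i], "_", x)
    sim$ds$samples$sample_id <- pre(sim$ds$samples$sample_id)
    rownames(sim$ds$geno) <- sim$ds$samples$sample_id
    sim$truth$sample_id <- if (nrow(sim$truth)) pre(sim$truth$sample_id)
      else character()
    sim$truth_fraction$sample_id <- pre(sim$truth_fraction$sample_id)
    sim$truth_fraction$population <- breeds$population[i]
    sim
  })
  ds <- genotype_dataset(
    map,
    dplyr::bind_rows(lapply(sims, function(s) s$ds$samples)),
    do.call(rbind, lapply(sims, function(s) s$ds$geno)))
  list(ds = ds,
       truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
       truth_fraction = dplyr::bind_rows(lapply(sims, `[[`,
                                                "truth_fraction")))
}

# copy of a sim_config with the seed cleared (callers manage RNG state)
sim_config_no_seed <- function(config) {
  config$seed <- NULL
  config
}
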