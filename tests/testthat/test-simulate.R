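test_that("planted autozygous tracts are recovered exactly without noise", {
  cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 600, seed = 5)
  tracts <- tibble::tibble(sample_id = "S001", chrom = "1",
                           start_bp = 1e7, end_bp = 1.5e7,
                           state = "autozygous")
  sim <- simulate_planted(cfg, tracts, n_individuals = 4)
  expect_identical(sim$truth, tracts)
  runs <- detect_runs(sim$ds)
  m <- sim$ds$map
  inside <- m$chrom == "1" & m$pos >= 1e7 & m$pos <= 1.5e7
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$sample_id, "S001")
  expect_equal(runs$start_bp, min(m$pos[inside]))
  expect_equal(runs$end_bp, max(m$pos[inside]))
})

test_that("dense 50% MAF background yields no spurious ROH", {
  # at MAF 0.5 a 30-SNP all-homozygous window has probability 2^-30 x
  # allowance inflation; a union bound over windows stays << 1 per seed
  for (seed in 1:10) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e7,
                      n_snps_per_chrom = 500, maf_range = c(0.499, 0.5),
                      seed = seed)
    sim <- simulate_planted(cfg, n_individuals = 5)
    expect_equal(nrow(detect_runs(sim$ds)), 0L)
  }
})

test_that("planted heterozygous tracts are recovered by the ROHet scan", {
  cfg <- sim_config(n_chromosomes = 1, n_snps_per_chrom = 800, seed = 9)
  tracts <- tibble::tibble(sample_id = "S001", chrom = "1",
                           start_bp = 2e7, end_bp = 2.2e7,
                           state = "heterozygous")
  sim <- simulate_planted(cfg, tracts, n_individuals = 2)
  het <- detect_runs(sim$ds, default_rohet_config())
  m <- sim$ds$map
  inside <- m$pos >= 2e7 & m$pos <= 2.2e7
  expect_gte(sum(inside), 15)
  r <- het[het$sample_id == "S001", ]
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_bp, min(m$pos[inside]))
  expect_equal(r$end_bp, max(m$pos[inside]))
})

test_that("overlapping tracts and foreign ids are rejected", {
  cfg <- sim_config(n_chromosomes = 1, seed = 2)
  bad <- tibble::tibble(sample_id = "S001", chrom = "1",
                        start_bp = c(1e6, 4e6), end_bp = c(5e6, 8e6),
                        state = "autozygous")
  expect_error(simulate_planted(cfg, bad, 2), "overlapping")
  foreign <- tibble::tibble(sample_id = "S099", chrom = "1",
                            start_bp = 1e6, end_bp = 2e6,
                            state = "autozygous")
  expect_error(simulate_planted(cfg, foreign, 2), "cohort")
})

test_that("simulation output is reproducible given the seed", {
  cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 300, seed = 42,
                    error_rate = 0.01, missing_rate = 0.02)
  a <- simulate_planted(cfg, n_individuals = 5)
  b <- simulate_planted(cfg, n_individuals = 5)
  expect_identical(a$ds$geno, b$ds$geno)
  expect_identical(a$ds$map, b$ds$map)
  p1 <- simulate_pedigree(cfg, pedigree_preset("halfsib", 8))
  p2 <- simulate_pedigree(cfg, pedigree_preset("halfsib", 8))
  expect_identical(p1$ds$geno, p2$ds$geno)
  expect_identical(p1$truth, p2$truth)
})

test_that("gene drop reproduces classical expected inbreeding", {
  cfg <- sim_config(n_chromosomes = 10, chrom_length_bp = 1e8,
                    n_snps_per_chrom = 400, seed = 77)
  # full-sib offspring: E[F] = 0.25, averaged over replicates
  fracs <- unlist(lapply(1:6, function(i) {
    sim <- simulate_pedigree(sim_config(n_chromosomes = 10,
                                        chrom_length_bp = 1e8,
                                        n_snps_per_chrom = 400,
                                        seed = 77 + i),
                             pedigree_preset("fullsib", 25))
    sim$truth_fraction$fraction
  }))
  expect_lt(abs(mean(fracs) - 0.25), 0.05)
  # outbred offspring carry no autozygosity at all
  simo <- simulate_pedigree(cfg, pedigree_preset("outbred", 20))
  expect_equal(nrow(simo$truth), 0L)
  expect_true(all(simo$truth_fraction$fraction == 0))
  expect_error(
    simulate_pedigree(cfg, tibble::tibble(id = "x", sire = "ghost",
                                          dam = "ghost2")),
    "unknown")
})

test_that("detected F_ROH tracks the truth autozygous fraction", {
  cfg <- sim_config(n_chromosomes = 15, chrom_length_bp = 1e8,
                    n_snps_per_chrom = 800, seed = 31)
  sim <- simulate_pedigree(cfg, pedigree_preset("fullsib", 30))
  fr <- f_roh(detect_runs(sim$ds), sim$ds$map, sim$ds$samples)
  fr1 <- fr[fr$class == ">1 Mb", ]
  j <- dplyr::inner_join(fr1, sim$truth_fraction, by = "sample_id")
  expect_gt(stats::cor(j$froh, j$fraction), 0.9)
  expect_lt(abs(mean(j$froh) - mean(j$fraction)), 0.05)
})

test_that("multi-breed cohorts order F_ROH by their inbreeding regime", {
  cfg <- sim_config(n_chromosomes = 5, n_snps_per_chrom = 500, seed = 55)
  breeds <- tibble::tibble(
    population = c("SWlike", "CUZ", "PZlike"),
    n = c(12, 12, 12),
    preset = c("fullsib", "first_cousin", "outbred"))
  cohort <- generate_breed_cohort(cfg, breeds)
  expect_equal(nrow(cohort$ds$samples), 36L)
  fr <- f_roh(detect_runs(cohort$ds), cohort$ds$map, cohort$ds$samples)
  m <- fr[fr$class == ">1 Mb", ] |>
    dplyr::group_by(population) |>
    dplyr::summarise(froh = mean(froh))
  v <- stats::setNames(m$froh, m$population)
  expect_gt(v["SWlike"], v["CUZ"])
  expect_gt(v["CUZ"], v["PZlike"])
  expect_lt(v["PZlike"], 0.01)
  expect_error(generate_breed_cohort(
    cfg, tibble::tibble(population = c("A", "A"), n = 5,
                        preset = "outbred")), "duplicate")
})
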