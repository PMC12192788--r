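test_that("default rule sets carry the published criteria", {
  roh <- default_roh_config()
  expect_equal(roh$target_state, "homozygous")
  expect_equal(roh$min_snps, 30L)
  expect_equal(roh$min_length_bp, 5e5)
  expect_equal(roh$max_gap_bp, 1e6)
  expect_equal(roh$max_opposite, 1L)
  expect_equal(roh$max_missing, 1L)
  het <- default_rohet_config()
  expect_equal(het$target_state, "heterozygous")
  expect_equal(het$min_snps, 15L)
  expect_equal(het$min_length_bp, 1e6)
  expect_equal(het$max_opposite, 3L)
  expect_equal(het$max_missing, 2L)
})

test_that("a clean homozygous stretch is one run; no seed means no run", {
  pos <- even_pos(35, step = 17000)          # 34 * 17 kb ~ 0.58 Mb
  runs <- detect_runs_one(rep(0L, 35), pos, default_roh_config())
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start_bp, pos[1])
  expect_equal(runs$end_bp, pos[35])
  expect_equal(runs$n_snps, 35L)
  expect_equal(detect_runs_one(rep(1L, 60), even_pos(60),
                               default_roh_config()) |> nrow(), 0L)
})

test_that("interior opposite calls beyond the allowance split runs", {
  g <- rep(0L, 40)
  g[c(15, 25)] <- 1L
  pos <- even_pos(40, step = 30000)
  found <- detect_runs_one(g, pos, default_roh_config())
  expect_same_runs(found, oracle_detect_runs(g, pos, default_roh_config()))
  # counted allowances are recorded
  expect_true(all(found$n_opposite <= 1))
})

test_that("a gap beyond max_gap_bp terminates the run on both sides", {
  pos <- c(even_pos(20, step = 30000),
           even_pos(20, step = 30000, start = even_pos(20, 30000)[20] + 1.2e6))
  g <- rep(0L, 40)
  cfg <- run_config("homozygous", 10, 4e5, 1e6, 1, 1)
  found <- detect_runs_one(g, pos, cfg)
  expect_equal(nrow(found), 2L)
  expect_equal(found$start_bp, c(pos[1], pos[21]))
  expect_equal(found$end_bp, c(pos[20], pos[40]))
  expect_same_runs(found, oracle_detect_runs(g, pos, cfg))
})

test_that("scanner equals the naive consecutive-method oracle on random data", {
  set.seed(99)
  cfgs <- list(
    default_roh_config(), default_rohet_config(),
    run_config("homozygous", 5, 1e5, 8e5, 2, 2),
    run_config("heterozygous", 4, 0, 5e5, 0, 0))
  for (case in 1:300) {
    x <- random_geno_case(n_max = 150)
    cfg <- cfgs[[sample(length(cfgs), 1)]]
    found <- detect_runs_one(x$geno, x$pos, cfg)
    expect_same_runs(found, oracle_detect_runs(x$geno, x$pos, cfg))
  }
})

test_that("runs are disjoint, trimmed to target flanks, deterministic", {
  set.seed(21)
  cfg <- run_config("homozygous", 5, 1e5, 1e6, 1, 1)
  for (case in 1:50) {
    x <- random_geno_case(n_max = 120)
    runs <- detect_runs_one(x$geno, x$pos, cfg)
    if (nrow(runs) > 1) {
      expect_true(all(runs$start_bp[-1] > runs$end_bp[-nrow(runs)]))
    }
    # first/last markers called in target state
    for (k in seq_len(nrow(runs))) {
      expect_true(x$geno[match(runs$start_bp[k], x$pos)] %in% c(0L, 2L))
      expect_true(x$geno[match(runs$end_bp[k], x$pos)] %in% c(0L, 2L))
    }
    expect_identical(runs, detect_runs_one(x$geno, x$pos, cfg))
  }
})

test_that("heterozygous detection is the homozygous scan of relabelled data", {
  set.seed(33)
  for (case in 1:30) {
    x <- random_geno_case(n_max = 100)
    hcfg <- run_config("heterozygous", 5, 1e5, 1e6, 2, 1)
    ocfg <- run_config("homozygous", 5, 1e5, 1e6, 2, 1)
    relabelled <- ifelse(is.na(x$geno), NA_integer_,
                         ifelse(x$geno == 1L, 0L, 1L))
    expect_same_runs(detect_runs_one(x$geno, x$pos, hcfg),
                     detect_runs_one(relabelled, x$pos, ocfg))
  }
})

test_that("invalid inputs are rejected", {
  cfg <- default_roh_config()
  expect_error(detect_runs_one(c(0L, 0L), c(100L, 100L), cfg),
               "strictly increasing")
  expect_error(detect_runs_one(c(0L, 0L), c(100L, 50L), cfg),
               "strictly increasing")
  expect_error(detect_runs_one(rep(0L, 3), c(1L, 2L), cfg), "length")
})

test_that("whole-dataset detection recovers planted tracts exactly", {
  cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 800, seed = 101)
  tracts <- tibble::tibble(
    sample_id = c("S001", "S001", "S002"),
    chrom = c("1", "2", "1"),
    start_bp = c(5e6, 2e7, 3e7),
    end_bp = c(11e6, 28e6, 38e6),
    state = "autozygous")
  sim <- simulate_planted(cfg, tracts, n_individuals = 2)
  runs <- detect_runs(sim$ds)
  expect_equal(nrow(runs), 3L)
  m <- sim$ds$map
  for (k in seq_len(nrow(tracts))) {
    inside <- m$chrom == tracts$chrom[k] & m$pos >= tracts$start_bp[k] &
      m$pos <= tracts$end_bp[k]
    r <- runs[runs$sample_id == tracts$sample_id[k] &
                runs$chrom == tracts$chrom[k], ]
    expect_equal(r$start_bp, min(m$pos[inside]))
    expect_equal(r$end_bp, max(m$pos[inside]))
  }
  # deterministic ordering: by sample, chromosome, start
  expect_equal(runs$sample_id, c("S001", "S001", "S002"))
  expect_warning(
    detect_runs(subset_gds(sim$ds, samples = integer(0)),
                default_roh_config()),
    "empty")
})
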