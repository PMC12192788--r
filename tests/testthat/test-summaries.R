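test_that("covered autosome length is the per-chromosome SNP span sum", {
  map <- make_map(list("1" = c(1e6, 3e6, 5e6), "2" = c(2e6, 12e6)))
  expect_equal(covered_autosome_length(map), 4e6 + 1e7)
  # non-autosomes excluded; error when nothing remains
  mapx <- make_map(list("X" = c(1e6, 2e6)))
  expect_error(covered_autosome_length(mapx), "no autosomal")
  set.seed(8)
  rmap <- make_map(list("1" = sort(sample.int(5e7, 100)),
                        "2" = sort(sample.int(5e7, 100)),
                        "3" = sort(sample.int(5e7, 100))))
  brute <- sum(vapply(c("1", "2", "3"), function(ch) {
    p <- rmap$pos[rmap$chrom == ch]
    max(p) - min(p)
  }, 0))
  expect_equal(covered_autosome_length(rmap), brute)
})

test_that("length classes are cumulative greater-than sets", {
  runs <- dplyr::bind_rows(
    run_row("a", "1", 1e6, 2.5e6),    # 1.5 Mb
    run_row("a", "1", 5e6, 25e6),     # 20 Mb
    run_row("a", "2", 1e6, 3e6))      # exactly 2.0 Mb
  cl <- classify_runs(runs, roh_length_classes())
  of_len <- function(l) sort(unique(cl$class[cl$length_bp == l]))
  expect_equal(of_len(1.5e6), ">1 Mb")
  expect_equal(of_len(2e7), sort(paste0(">", c(1, 2, 4, 8, 16), " Mb")))
  expect_equal(of_len(2e6), ">1 Mb")  # strict: 2.0 Mb not in >2 Mb
})

test_that("per-animal summary counts, sums, and zero-run animals", {
  runs <- dplyr::bind_rows(
    run_row("a", "1", 1e6, 2.5e6),
    run_row("a", "1", 5e6, 8e6),
    run_row("a", "2", 1e6, 21e6))
  samples <- tibble::tibble(sample_id = c("a", "b"), population = "P1")
  s <- per_animal_summary(runs, samples)
  get <- function(id, cls, col) s[[col]][s$sample_id == id & s$class == cls]
  expect_equal(get("a", ">1 Mb", "n_runs"), 3L)
  expect_equal(get("a", ">2 Mb", "n_runs"), 2L)
  expect_equal(get("a", ">16 Mb", "n_runs"), 1L)
  expect_equal(get("a", ">1 Mb", "sum_bp"), 24.5e6)
  expect_equal(get("b", ">1 Mb", "n_runs"), 0L)
  # zero-run animal pulls the population mean down
  ps <- population_summary(s)
  expect_equal(ps$mean_n_runs[ps$class == ">1 Mb"], 1.5)
  expect_equal(ps$n_animals[1], 2L)
})

test_that("summaries match an independent aggregation oracle on random runs", {
  set.seed(15)
  ids <- sprintf("i%02d", 1:12)
  runs <- dplyr::bind_rows(lapply(ids, function(id) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    start <- sort(sample.int(4e7, k))
    len <- sample.int(2e7, k)
    tibble::tibble(sample_id = id, population = sample(c("A", "B"), 1),
                   chrom = "1", start_bp = start, end_bp = start + len,
                   n_snps = 30L, n_opposite = 0L, n_missing = 0L,
                   length_bp = as.numeric(len))
  }))
  samples <- dplyr::distinct(runs[, c("sample_id", "population")])
  s <- per_animal_summary(runs, samples)
  for (row in sample(nrow(s), 20)) {
    id <- s$sample_id[row]; thr <- s$threshold_bp[row]
    sub <- runs[runs$sample_id == id & runs$length_bp > thr, ]
    expect_equal(s$n_runs[row], nrow(sub))
    expect_equal(s$sum_bp[row], sum(sub$length_bp))
  }
  # counts and sums non-increasing along the ladder
  by_id <- split(s[order(s$threshold_bp), ], s$sample_id[order(s$threshold_bp)])
  for (b in by_id) {
    expect_true(all(diff(b$n_runs) <= 0))
    expect_true(all(diff(b$sum_bp) <= 0))
  }
})

test_that("F_ROH is 0 with no runs and 1 for a fully homozygous genome", {
  map <- make_map(list("1" = even_pos(60, 40000), "2" = even_pos(60, 40000)))
  samples <- tibble::tibble(sample_id = c("hom", "none"), population = "P")
  geno <- rbind(rep(0L, 120), rep(1L, 120))
  ds <- genotype_dataset(map, samples, geno)
  runs <- detect_runs(ds)
  fr <- f_roh(runs, ds$map, samples)
  # every chromosome span (2.36 Mb) exceeds 1 Mb, so the whole covered
  # genome is in ROH at the >1 Mb threshold; longer thresholds drop it
  expect_equal(fr$froh[fr$sample_id == "hom" & fr$class == ">1 Mb"], 1)
  expect_equal(fr$froh[fr$sample_id == "hom" & fr$class == ">2 Mb"], 1)
  expect_equal(fr$froh[fr$sample_id == "hom" & fr$class == ">4 Mb"], 0)
  expect_true(all(fr$froh[fr$sample_id == "none"] == 0))
  expect_true(all(fr$froh >= 0 & fr$froh <= 1))
  # monotone non-increasing in threshold for each sample
  for (id in samples$sample_id) {
    v <- fr[fr$sample_id == id, ]
    expect_true(all(diff(v$froh[order(v$threshold_bp)]) <= 0))
  }
})

test_that("D_ROHet covers planted heterozygous tracts within spacing error", {
  cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 1000, seed = 61)
  tracts <- tibble::tibble(
    sample_id = "S001", chrom = c("1", "2"),
    start_bp = c(1e7, 5e6), end_bp = c(1.4e7, 7e6), state = "heterozygous")
  sim <- simulate_planted(cfg, tracts, n_individuals = 2)
  het <- detect_runs(sim$ds, default_rohet_config(5e5))
  dr <- d_rohet(het, sim$ds$map, sim$ds$samples)
  v <- dr[dr$sample_id == "S001" & dr$class == ">0.5 Mb", ]
  truth_frac <- sum(tracts$end_bp - tracts$start_bp) /
    covered_autosome_length(sim$ds$map)
  # detected span is the tract's SNP span: within mean-spacing slack
  expect_lt(abs(v$drohet - truth_frac), 2 * 50000 * 2 /
              covered_autosome_length(sim$ds$map) + 0.003)
  # all-homozygous individual has zero coverage
  hom_ds <- genotype_dataset(
    make_map(list("1" = even_pos(40, 40000))),
    tibble::tibble(sample_id = "h", population = "P"),
    matrix(0L, 1, 40))
  het2 <- detect_runs(hom_ds, default_rohet_config(5e5))
  dr2 <- d_rohet(het2, hom_ds$map, hom_ds$samples)
  expect_true(all(dr2$drohet == 0))
  expect_true(all(diff(dr2$drohet[order(dr2$threshold_bp)]) <= 0))
})
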