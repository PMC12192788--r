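test_that("per-SNP incidence matches the interval-stabbing oracle", {
  map <- make_map(list("1" = even_pos(30, 1e5), "2" = even_pos(20, 1e5)))
  runs <- dplyr::bind_rows(
    run_row("a", "1", 1.2e6, 2.4e6), run_row("b", "1", 2.0e6, 3.4e6),
    run_row("a", "2", 1e6, 1.5e6),
    run_row("b", "1", 2.2e6, 2.8e6))   # overlapping runs, same animal
  inc <- snp_incidence(runs, map, "P1")
  expect_equal(inc$incidence,
               oracle_incidence(runs, map, c("a", "b")))
  expect_true(all(inc$incidence >= 0 & inc$incidence <= 1))
  # a SNP inside a run of every individual has incidence 1
  expect_equal(inc$incidence[inc$chrom == "1" & inc$pos == 2.3e6], 1)
  # uncovered chromosome-2 tail is 0
  expect_equal(inc$incidence[inc$chrom == "2" & inc$pos > 1.6e6],
               rep(0, sum(map$chrom == "2" & map$pos > 1.6e6)))
  expect_error(snp_incidence(runs, map, "nope"), "absent")
  set.seed(44)
  for (case in 1:20) {
    ids <- c("a", "b", "c")
    rr <- dplyr::bind_rows(lapply(ids, function(id) {
      k <- sample(0:4, 1)
      if (!k) return(NULL)
      st <- sample.int(4e6, k) + 5e5
      tibble::tibble(sample_id = id, population = "P1",
                     chrom = sample(c("1", "2"), k, TRUE),
                     start_bp = st, end_bp = st + sample.int(2e6, k),
                     n_snps = 10L, n_opposite = 0L, n_missing = 0L,
                     length_bp = 1)
    }))
    inc <- snp_incidence(rr, map, "P1", n_individuals = 3)
    expect_equal(inc$incidence, oracle_incidence(rr, map, ids))
  }
})

test_that("top-percentile threshold is the k-th highest with ties included", {
  set.seed(12)
  x <- stats::runif(1000)
  thr <- top_percentile_threshold(x, 1)
  expect_equal(thr, sort(x, decreasing = TRUE)[10])
  expect_equal(sum(x >= thr), 10L)
  # all-equal incidences select everything
  expect_equal(sum(rep(0.4, 55) >= top_percentile_threshold(rep(0.4, 55), 1)),
               55L)
  # tied values at the threshold are all selected
  y <- c(rep(1, 3), rep(0.5, 8), stats::runif(89, max = 0.4))
  thr_y <- top_percentile_threshold(y, 5)   # ceiling(5) = 5th highest = 0.5
  expect_equal(thr_y, 0.5)
  expect_equal(sum(y >= thr_y), 11L)
  for (case in 1:30) {
    v <- stats::runif(sample(50:500, 1))
    pct <- sample(c(1, 2, 5, 10), 1)
    k <- ceiling(length(v) * pct / 100)
    expect_equal(top_percentile_threshold(v, pct),
                 sort(v, decreasing = TRUE)[k])
  }
})

test_that("island aggregation equals the run-length oracle, no bridging", {
  map <- make_map(list("1" = even_pos(5, 1e5)))
  isl <- aggregate_islands(c(FALSE, TRUE, TRUE, TRUE, FALSE), map, 2)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$n_snps, 3L)
  expect_equal(isl$start_bp, map$pos[2])
  expect_equal(isl$end_bp, map$pos[4])
  # an unselected SNP between two selected ones splits them
  isl2 <- aggregate_islands(c(TRUE, FALSE, TRUE, FALSE, FALSE), map, 1)
  expect_equal(nrow(isl2), 2L)
  expect_equal(aggregate_islands(c(TRUE, FALSE, TRUE, FALSE, FALSE),
                                 map, 2) |> nrow(), 0L)
  set.seed(77)
  bigmap <- make_map(list("1" = even_pos(60, 1e5), "2" = even_pos(40, 1e5)))
  for (case in 1:40) {
    flags <- stats::runif(100) < 0.3
    found <- aggregate_islands(flags, bigmap, 2)
    want <- oracle_islands(flags, bigmap, 2)
    expect_equal(as.data.frame(found[, c("chrom", "start_bp", "end_bp",
                                         "n_snps")]),
                 want, ignore_attr = TRUE)
  }
})

test_that("island members all exceed the breed threshold and are disjoint", {
  cfg <- sim_config(n_chromosomes = 3, n_snps_per_chrom = 400, seed = 90)
  sim <- simulate_pedigree(cfg, pedigree_preset("fullsib", 25),
                           population = "HB")
  runs <- detect_runs(sim$ds)
  isl <- detect_islands(runs, sim$ds$map,
                        cohort_sizes = c(HB = 25), min_island_snps = 2)
  expect_gt(nrow(isl), 0)
  inc <- snp_incidence(runs, sim$ds$map, "HB", n_individuals = 25)
  for (k in seq_len(nrow(isl))) {
    members <- inc[match(isl$snp_ids[[k]], inc$snp_id), ]
    expect_true(all(members$incidence >= isl$threshold[k]))
    expect_equal(isl$peak_incidence[k], max(members$incidence))
    # members are map-consecutive: no unselected SNP inside
    between <- inc$chrom == isl$chrom[k] & inc$pos >= isl$start_bp[k] &
      inc$pos <= isl$end_bp[k]
    expect_equal(sum(between), isl$n_snps[k])
  }
  # islands of one breed never overlap each other
  by_chr <- split(isl, isl$chrom)
  for (b in by_chr) {
    b <- b[order(b$start_bp), ]
    if (nrow(b) > 1) expect_true(all(b$start_bp[-1] > b$end_bp[-nrow(b)]))
  }
})

test_that("annotation overlap equals all-pairs brute force", {
  isl <- tibble::tibble(population = "P", chrom = "1",
                        start_bp = 1e7, end_bp = 2e7)
  ann <- tibble::tibble(chrom = c("1", "1", "2"),
                        start_bp = c(1.5e7, 2.5e7, 1.5e7),
                        end_bp = c(2.5e7, 3e7, 2.5e7),
                        name = c("q1", "q2", "q3"), category = "t")
  ov <- overlap_annotations(isl, ann)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlap_bp, 5e6 + 1)   # inclusive convention
  expect_equal(ov$name, "q1")
  set.seed(13)
  for (case in 1:50) {
    a <- tibble::tibble(
      population = "P", chrom = sample(c("1", "2"), 8, TRUE),
      start_bp = sample.int(1e7, 8))
    a$end_bp <- a$start_bp + sample.int(3e6, 8)
    b <- tibble::tibble(
      chrom = sample(c("1", "2", "3"), 10, TRUE),
      start_bp = sample.int(1e7, 10))
    b$end_bp <- b$start_bp + sample.int(3e6, 10)
    b$name <- sprintf("q%d", 1:10)
    b$category <- "t"
    ov <- overlap_annotations(a, b)
    want <- oracle_overlaps(a, b)
    expect_equal(nrow(ov), nrow(want))
    expect_equal(sort(ov$overlap_bp), sort(want$overlap_bp))
    expect_true(all(ov$overlap_bp > 0))
    expect_true(all(ov$overlap_bp <=
                      pmin(ov$island_end - ov$island_start + 1,
                           ov$annot_end - ov$annot_start + 1)))
  }
})
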