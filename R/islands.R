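#' Per-SNP run incidence within a population
#'
#' For each marker, the count and fraction of a population's
#' individuals that have at least one run covering the marker's
#' position (run start <= position <= run end). Overlapping runs of the
#' same individual are unioned first, so an individual contributes at
#' most once per marker.
#'
#' @param runs Run tibble from [detect_runs()].
#' @param map Marker map of the dataset.
#' @param population Population label; must be present in `runs`'
#'   `population` column (individuals of the population with zero runs
#'   still count in the denominator through `n_individuals`).
#' @param n_individuals Number of individuals in the population
#'   (denominator). Defaults to the number of distinct `sample_id`s of
#'   the population present in `runs`; pass the cohort size explicitly
#'   when some animals have no runs.
#' @return Tibble with `snp_id`, `chrom`, `pos`, `n_covered`,
#'   `incidence`.
#' @export
snp_incidence <- function(runs, map, population, n_individuals = NULL) {
  r <- runs[runs$population == population, ]
  if (is.null(n_individuals)) {
    n_individuals <- length(unique(r$sample_id))
    if (n_individuals == 0) {
      stop("population '", population, "' absent from runs; ",
           "pass n_individuals explicitly for an all-zero cohort")
    }
  }
  counts <- integer(nrow(map))
  if (nrow(r) > 0) {
    for (ch in unique(r$chrom)) {
      mi <- which(map$chrom == ch)
      if (!length(mi)) next
      pos <- map$pos[mi]
      rc <- r[r$chrom == ch, ]
      # union runs per individual, then mark covered marker index ranges
      delta <- integer(length(pos) + 1L)
      for (sid in unique(rc$sample_id)) {
        iv <- rc[rc$sample_id == sid, c("start_bp", "end_bp")]
        iv <- iv[order(iv$start_bp), ]
        merged_s <- iv$start_bp[1]; merged_e <- iv$end_bp[1]
        add <- function(s, e) {
          lo <- findInterval(s - 1L, pos) + 1L   # first pos >= s
          hi <- findInterval(e, pos)             # last pos <= e
          if (lo <= hi) {
            delta[lo] <<- delta[lo] + 1L
            delta[hi + 1L] <<- delta[hi + 1L] - 1L
          }
        }
        if (nrow(iv) > 1) {
          for (k in 2:nrow(iv)) {
            if (iv$start_bp[k] <= merged_e) {
              merged_e <- max(merged_e, iv$end_bp[k])
            } else {
              add(merged_s, merged_e)
              merged_s <- iv$start_bp[k]; merged_e <- iv$end_bp[k]
            }
          }
        }
        add(merged_s, merged_e)
      }
      counts[mi] <- cumsum(delta[-length(delta)])
    }
  }
  tibble::tibble(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                 n_covered = counts,
                 incidence = counts / n_individuals)
}

#' Top-percentile incidence threshold
#'
#' The incidence value of the `ceiling(n * pct / 100)`-th highest
#' marker; markers are selected when their incidence is greater than or
#' equal to this threshold, so ties at the threshold are all included.
#'
#' @param incidence Numeric vector of per-SNP incidences.
#' @param pct Percentile in (0, 100); default 1 (top 1 percent).
#' @return The threshold value.
#' @export
top_percentile_threshold <- function(incidence, pct = 1) {
  stopifnot(pct > 0, pct < 100, length(incidence) > 0)
  k <- ceiling(length(incidence) * pct / 100)
  sort(incidence, decreasing = TRUE)[k]
}

#' Aggregate selected SNPs into islands
#'
#' Groups map-consecutive selected markers on the same chromosome into
#' maximal blocks; a single unselected marker between two selected ones
#' splits them (no bridging). Blocks with fewer than `min_island_snps`
#' markers are discarded.
#'
#' @param selected Logical vector aligned to `map` row order.
#' @param map Marker map.
#' @param min_island_snps Minimum markers per island; default 2.
#' @return Tibble with `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_bp` and list-column `snp_ids`.
#' @export
aggregate_islands <- function(selected, map, min_island_snps = 2) {
  stopifnot(length(selected) == nrow(map), min_island_snps >= 1)
  out <- list()
  for (ch in unique(map$chrom)) {
    mi <- which(map$chrom == ch)
    r <- rle(selected[mi])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= min_island_snps
    for (b in which(ok)) {
      bi <- mi[starts[b]:ends[b]]
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch,
        start_bp = map$pos[bi[1]],
        end_bp = map$pos[bi[length(bi)]],
        n_snps = length(bi),
        length_bp = as.numeric(map$pos[bi[length(bi)]] - map$pos[bi[1]]),
        snp_ids = list(map$snp_id[bi])
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), start_bp = integer(),
                          end_bp = integer(), n_snps = integer(),
                          length_bp = numeric(), snp_ids = list()))
  }
  dplyr::bind_rows(out)
}

#' Call ROH islands (hotspots) per population
#'
#' For each population: compute per-SNP ROH incidence, take the top
#' `pct` percent of markers by incidence (ties included), and aggregate
#' map-consecutive selected markers into island regions. Thresholds are
#' computed within each population by default; set `per_population =
#' FALSE` to pool incidences across the whole dataset before selecting.
#'
#' @param runs ROH tibble from [detect_runs()].
#' @param map Marker map.
#' @param cohort_sizes Optional named vector giving the number of
#'   individuals per population (denominator for incidences); defaults
#'   to animals present in `runs`.
#' @param pct Top percentile; default 1.
#' @param min_island_snps Minimum markers per island; default 2.
#' @param per_population Compute the selection threshold within each
#'   population (default) or once across the pooled dataset.
#' @return Tibble of islands with `population`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`, `peak_incidence`, `threshold`,
#'   `snp_ids` (list-column).
#' @export
detect_islands <- function(runs, map, cohort_sizes = NULL, pct = 1,
                           min_island_snps = 2, per_population = TRUE) {
  pops <- sort(unique(runs$population))
  inc_all <- lapply(pops, function(p) {
    n <- if (!is.null(cohort_sizes)) unname(cohort_sizes[p]) else NULL
    snp_incidence(runs, map, p, n_individuals = n)
  })
  names(inc_all) <- pops
  pooled_thr <- if (!per_population) {
    top_percentile_threshold(unlist(lapply(inc_all, `[[`, "incidence")))
  } else NULL

  out <- lapply(pops, function(p) {
    inc <- inc_all[[p]]
    thr <- if (per_population) {
      top_percentile_threshold(inc$incidence, pct)
    } else pooled_thr
    isl <- aggregate_islands(inc$incidence >= thr, map, min_island_snps)
    if (nrow(isl) == 0) return(NULL)
    isl$population <- p
    isl$threshold <- thr
    isl$peak_incidence <- vapply(isl$snp_ids, function(ids) {
      max(inc$incidence[match(ids, inc$snp_id)])
    }, 0)
    isl
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(population = character(), chrom = character(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), length_bp = numeric(),
                          peak_incidence = numeric(), threshold = numeric(),
                          snp_ids = list()))
  }
  out[order(out$population, chrom_sort_key(out$chrom), out$start_bp),
      c("population", "chrom", "start_bp", "end_bp", "n_snps", "length_bp",
        "peak_incidence", "threshold", "snp_ids")]
}

#' Overlap islands with annotation intervals
#'
#' Reports every (island, annotation) pair with at least 1 bp of
#' positional intersection, with the overlap length under the 1-based
#' inclusive convention. Matching is by chromosome using IRanges
#' interval-tree overlap.
#'
#' @param islands Island tibble from [detect_islands()] (or any tibble
#'   with `chrom`, `start_bp`, `end_bp`).
#' @param annotations Annotation tibble from [read_annotation_bed()].
#' @return Tibble with island coordinates, annotation `name` and
#'   `category`, annotation coordinates and `overlap_bp`.
#' @export
overlap_annotations <- function(islands, annotations) {
  empty <- tibble::tibble(
    population = character(), chrom = character(),
    island_start = integer(), island_end = integer(),
    name = character(), category = character(),
    annot_start = integer(), annot_end = integer(), overlap_bp = numeric())
  if (nrow(islands) == 0 || nrow(annotations) == 0) return(empty)
  iq <- IRanges::IRanges(start = islands$start_bp, end = islands$end_bp)
  is_split <- split(seq_len(nrow(islands)), islands$chrom)
  an_split <- split(seq_len(nrow(annotations)), annotations$chrom)
  res <- list()
  for (ch in intersect(names(is_split), names(an_split))) {
    ii <- is_split[[ch]]; ai <- an_split[[ch]]
    hits <- IRanges::findOverlaps(
      iq[ii],
      IRanges::IRanges(start = annotations$start_bp[ai],
                       end = annotations$end_bp[ai]))
    if (!length(hits)) next
    i <- ii[S4Vectors::queryHits(hits)]
    a <- ai[S4Vectors::subjectHits(hits)]
    res[[ch]] <- tibble::tibble(
      population = if ("population" %in% names(islands))
        islands$population[i] else NA_character_,
      chrom = ch,
      island_start = islands$start_bp[i],
      island_end = islands$end_bp[i],
      name = annotations$name[a],
      category = annotations$category[a],
      annot_start = annotations$start_bp[a],
      annot_end = annotations$end_bp[a],
      overlap_bp = pmin(islands$end_bp[i], annotations$end_bp[a]) -
        pmax(islands$start_bp[i], annotations$start_bp[a]) + 1
    )
  }
  if (!length(res)) return(empty)
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, .data$population, chrom_sort_key(.data$chrom),
                 .data$island_start, .data$annot_start)
}
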