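#' Run-detection rule set
#'
#' Bundles the parameters of the consecutive-SNP run detection method:
#' the target genotype state, the minimum number of markers spanned, the
#' minimum physical length, the maximum tolerated gap between adjacent
#' markers, and the per-run allowances for markers of the opposite
#' called state and for missing calls.
#'
#' @param target_state `"homozygous"` or `"heterozygous"`.
#' @param min_snps Minimum markers spanned by a run (tolerated markers
#'   included).
#' @param min_length_bp Minimum run length in bp (`end - start`).
#' @param max_gap_bp Maximum adjacent-marker spacing within a run; a
#'   larger gap terminates the run unconditionally.
#' @param max_opposite Maximum opposite-state called markers tolerated
#'   inside one run.
#' @param max_missing Maximum missing calls tolerated inside one run.
#' @return A `run_config` object.
#' @export
run_config <- function(target_state, min_snps, min_length_bp,
                       max_gap_bp, max_opposite, max_missing) {
  target_state <- match.arg(target_state, c("homozygous", "heterozygous"))
  stopifnot(min_snps >= 1, min_length_bp >= 0, max_gap_bp > 0,
            max_opposite >= 0, max_missing >= 0)
  structure(list(target_state = target_state,
                 min_snps = as.integer(min_snps),
                 min_length_bp = as.numeric(min_length_bp),
                 max_gap_bp = as.numeric(max_gap_bp),
                 max_opposite = as.integer(max_opposite),
                 max_missing = as.integer(max_missing)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("run_config: target %s, >=%d SNPs, >=%g bp, ",
                     "gap <= %g bp, allow %d opposite / %d missing\n"),
              x$target_state, x$min_snps, x$min_length_bp, x$max_gap_bp,
              x$max_opposite, x$max_missing))
  invisible(x)
}

#' Default ROH rule set
#'
#' The medium-density-array ROH criteria: at least 30 consecutive
#' homozygous SNPs, minimum length 0.5 Mb, maximum SNP spacing 1 Mb,
#' with up to 1 heterozygous and 1 missing call tolerated per run.
#'
#' @return A `run_config`.
#' @export
default_roh_config <- function() {
  run_config("homozygous", min_snps = 30, min_length_bp = 5e5,
             max_gap_bp = 1e6, max_opposite = 1, max_missing = 1)
}

#' Default ROHet rule set
#'
#' Heterozygosity-rich-region criteria: at least 15 consecutive
#' heterozygous SNPs, minimum length 1 Mb, maximum SNP spacing 1 Mb,
#' with up to 3 homozygous and 2 missing calls tolerated per run.
#' Summaries of ROHet are reported down to a 0.5 Mb class, so pipelines
#' that populate that class lower `min_length_bp` to `5e5`
#' (`default_rohet_config(min_length_bp = 5e5)`).
#'
#' @param min_length_bp Minimum ROHet length in bp; default 1 Mb.
#' @return A `run_config`.
#' @export
default_rohet_config <- function(min_length_bp = 1e6) {
  run_config("heterozygous", min_snps = 15, min_length_bp = min_length_bp,
             max_gap_bp = 1e6, max_opposite = 3, max_missing = 2)
}

# Classify a genotype vector into run states given the target.
# Returns list(target, opposite, missing) logical vectors.
run_states <- function(geno, target_state) {
  missing <- is.na(geno)
  het <- !missing & geno == 1L
  hom <- !missing & !het
  if (target_state == "homozygous") {
    list(target = hom, opposite = het, missing = missing)
  } else {
    list(target = het, opposite = hom, missing = missing)
  }
}

#' Detect runs on one chromosome of one individual
#'
#' Scans a genotype vector aligned to strictly increasing positions
#' left to right, in the manner of the consecutive run-detection
#' method: the current run grows while every adjacent-marker gap stays
#' within `max_gap_bp` and the counts of opposite-state and missing
#' markers stay within their allowances; when the next marker would
#' violate a constraint the run is closed, trimmed so that its first
#' and last markers are called in the target state, reported if it
#' spans at least `min_snps` markers and `min_length_bp` base pairs,
#' and the scan resumes at the violating marker with fresh allowances.
#' Reported runs are therefore pairwise disjoint and, within one scan,
#' each is as long as its budgets permit.
#'
#' @param geno Integer genotype vector (0/1/2/NA) for one individual on
#'   one chromosome, in map order.
#' @param pos Strictly increasing integer bp positions aligned to `geno`.
#' @param config A [run_config()].
#' @return Tibble with columns `start_bp`, `end_bp`, `n_snps`,
#'   `n_opposite`, `n_missing`, `length_bp`, sorted by `start_bp`.
#' @export
detect_runs_one <- function(geno, pos, config) {
  stopifnot(inherits(config, "run_config"))
  if (length(geno) != length(pos)) {
    stop("genotype vector and positions differ in length (",
         length(geno), " vs ", length(pos), ")")
  }
  n <- length(geno)
  empty <- tibble::tibble(start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), n_opposite = integer(),
                          n_missing = integer(), length_bp = numeric())
  if (n == 0) return(empty)
  if (n > 1 && any(diff(pos) <= 0)) {
    stop("positions must be strictly increasing")
  }
  st <- run_states(geno, config$target_state)

  # gap > max_gap_bp is a hard break: process each gap-delimited block
  breaks <- if (n > 1) which(diff(pos) > config$max_gap_bp) else integer()
  block_start <- c(1L, breaks + 1L)
  block_end <- c(breaks, n)

  segs <- vector("list", length(block_start))
  for (b in seq_along(block_start)) {
    segs[[b]] <- scan_block(block_start[b], block_end[b], st, pos, config)
  }
  out <- do.call(rbind, segs)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- tibble::as_tibble(out)
  out$length_bp <- as.numeric(out$end_bp - out$start_bp)
  out[order(out$start_bp), ]
}

# Greedy left-to-right scan of one gap-free block [lo, hi]: grow a
# window from the current start while the opposite/missing budgets
# hold, emit it trimmed to its target-state flanks, and resume at the
# first violating marker (which may seed the next run with a fresh
# budget). Emitted runs are pairwise disjoint. The budget-limited
# window ends r(i) are precomputed for all starts by a vectorised
# order-statistic lookup, so the walk costs one iteration per run.
scan_block <- function(lo, hi, st, pos, config) {
  idx <- lo:hi
  m <- length(idx)
  opp <- st$opposite[idx]
  mis <- st$missing[idx]
  tgt <- st$target[idx]
  if (!any(tgt)) return(NULL)

  # r(i): furthest right end of a window starting at i whose opposite
  # and missing counts stay within budget (gaps already satisfied).
  r_limit <- function(flag, budget) {
    which_f <- which(flag)
    cum <- cumsum(flag)
    before <- cum - flag            # count strictly before each i
    viol_rank <- before + budget + 1L
    viol_idx <- ifelse(viol_rank <= length(which_f),
                       which_f[pmin(viol_rank, length(which_f))], m + 1L)
    viol_idx - 1L
  }
  r <- pmin(r_limit(opp, config$max_opposite),
            r_limit(mis, config$max_missing), m)

  wt <- which(tgt)
  next_tgt <- wt[findInterval(seq_len(m) - 1L, wt) + 1L]  # first target >= i
  prev_rank <- findInterval(seq_len(m), wt)               # targets <= i
  prev_tgt <- ifelse(prev_rank >= 1L, wt[pmax(prev_rank, 1L)], NA_integer_)

  s_trim <- integer(); e_trim <- integer()
  i <- 1L
  while (i <= m) {
    j <- r[i]
    if (j >= i) {
      s <- next_tgt[i]
      e <- prev_tgt[j]
      if (!is.na(s) && !is.na(e) && s <= e && s <= j) {
        s_trim <- c(s_trim, s)
        e_trim <- c(e_trim, e)
      }
    }
    i <- max(j + 1L, i + 1L)
  }
  if (!length(s_trim)) return(NULL)

  cum_opp <- c(0L, cumsum(opp))
  cum_mis <- c(0L, cumsum(mis))
  n_snps <- e_trim - s_trim + 1L
  length_bp <- pos[idx[e_trim]] - pos[idx[s_trim]]
  pass <- n_snps >= config$min_snps & length_bp >= config$min_length_bp
  if (!any(pass)) return(NULL)
  s_trim <- s_trim[pass]; e_trim <- e_trim[pass]

  data.frame(
    start_bp = pos[idx[s_trim]],
    end_bp = pos[idx[e_trim]],
    n_snps = e_trim - s_trim + 1L,
    n_opposite = cum_opp[e_trim + 1L] - cum_opp[s_trim],
    n_missing = cum_mis[e_trim + 1L] - cum_mis[s_trim],
    length_bp = as.numeric(pos[idx[e_trim]] - pos[idx[s_trim]])
  )
}

#' Detect runs across a whole dataset
#'
#' Applies [detect_runs_one()] to every (individual, autosome) pair and
#' concatenates the results in deterministic order (sample file order,
#' then chromosome, then start position).
#'
#' @param ds A QC-filtered `genotype_dataset`.
#' @param config A [run_config()]; see [default_roh_config()] and
#'   [default_rohet_config()].
#' @param autosomes Chromosome labels scanned; default sheep `1`--`26`.
#' @return Tibble of runs with columns `sample_id`, `population`,
#'   `chrom`, `start_bp`, `end_bp`, `n_snps`, `n_opposite`, `n_missing`,
#'   `length_bp`. The rule set is attached as attribute `config`.
#' @export
detect_runs <- function(ds, config = default_roh_config(),
                        autosomes = default_autosomes()) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(config, "run_config"))
  if (nrow(ds$samples) == 0 || nrow(ds$map) == 0) {
    warning("empty dataset: no runs to detect")
  }
  chroms <- unique(ds$map$chrom)
  chroms <- chroms[chroms %in% autosomes]
  chrom_idx <- lapply(chroms, function(ch) which(ds$map$chrom == ch))
  names(chrom_idx) <- chroms

  res <- vector("list", nrow(ds$samples) * length(chroms))
  k <- 0L
  for (i in seq_len(nrow(ds$samples))) {
    for (ch in chroms) {
      ci <- chrom_idx[[ch]]
      runs <- detect_runs_one(ds$geno[i, ci], ds$map$pos[ci], config)
      if (nrow(runs) > 0) {
        k <- k + 1L
        runs$sample_id <- ds$samples$sample_id[i]
        runs$population <- ds$samples$population[i]
        runs$chrom <- ch
        res[[k]] <- runs
      }
    }
  }
  cols <- c("sample_id", "population", "chrom", "start_bp", "end_bp",
            "n_snps", "n_opposite", "n_missing", "length_bp")
  if (k == 0) {
    out <- tibble::as_tibble(stats::setNames(
      list(character(), character(), character(), integer(), integer(),
           integer(), integer(), integer(), numeric()), cols))
  } else {
    out <- dplyr::bind_rows(res[seq_len(k)])[, cols]
    out <- out[order(match(out$sample_id, ds$samples$sample_id),
                     chrom_sort_key(out$chrom), out$start_bp), ]
  }
  attr(out, "config") <- config
  out
}
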