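# Independent reference implementations used to check the package's
# vectorised code paths. All are deliberately naive: per-element loops,
# full enumeration, all-pairs scans.

# Naive consecutive-method scan: grow the window one marker at a time,
# re-checking gap and allowance constraints explicitly; close, trim to
# target-state flanks, apply minima; resume at the violating marker.
oracle_detect_runs <- function(geno, pos, config) {
  n <- length(geno)
  miss <- is.na(geno)
  het <- !miss & geno == 1L
  hom <- !miss & !het
  tgt <- if (config$target_state == "homozygous") hom else het
  opp <- if (config$target_state == "homozygous") het else hom
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i - 1L
    n_opp <- 0L
    n_mis <- 0L
    repeat {
      k <- j + 1L
      if (k > n) break
      if (k > i && pos[k] - pos[k - 1L] > config$max_gap_bp) break
      no <- n_opp + opp[k]
      nm <- n_mis + miss[k]
      if (no > config$max_opposite || nm > config$max_missing) break
      j <- k
      n_opp <- no
      n_mis <- nm
    }
    if (j >= i) {
      ts <- which(tgt[i:j])
      if (length(ts)) {
        s <- i + ts[1] - 1L
        e <- i + ts[length(ts)] - 1L
        if (e - s + 1L >= config$min_snps &&
            pos[e] - pos[s] >= config$min_length_bp) {
          out[[length(out) + 1L]] <- c(pos[s], pos[e])
        }
      }
    }
    i <- max(j + 1L, i + 1L)
  }
  if (!length(out)) {
    return(data.frame(start_bp = integer(), end_bp = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(start_bp = m[, 1], end_bp = m[, 2])
}

# random genotype vector + positions for oracle cross-checks
random_geno_case <- function(n_max = 200, max_pos_step = 1.6e6) {
  n <- sample(10:n_max, 1)
  # mix regimes so long runs, short runs and no runs all occur
  p_het <- sample(c(0.02, 0.1, 0.3, 0.5), 1)
  p_mis <- sample(c(0, 0.02, 0.1), 1)
  g <- sample(c(0L, 1L, 2L), n, replace = TRUE,
              prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2))
  g[stats::runif(n) < p_mis] <- NA_integer_
  pos <- cumsum(sample(c(rep(2e4, 8), 5e5, max_pos_step), n, replace = TRUE))
  list(geno = g, pos = as.integer(pos))
}

# Exact HWE p-value by direct enumeration with choose(), normalised in
# probability space (the package uses log-factorials + a recurrence-free
# closed form; this stays independent).
oracle_hwe <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  na <- 2 * n_AA + n_AB
  nb <- 2 * n_BB + n_AB
  if (na == 0 || nb == 0) return(1)
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    naa <- (na - h) / 2
    nbb <- (nb - h) / 2
    choose(n, h) * choose(n - h, naa) * 2^h / choose(2 * n, na)
  }, 0)
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_AB, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every labelling of
# the pooled sample (no ties), matching the doubled-tail convention.
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_null <- apply(combos, 2, function(ix) {
    sum(r[ix]) - nx * (nx + 1) / 2
  })
  lo <- mean(u_null <= u_obs)
  hi <- mean(u_null >= u_obs)
  p <- if (u_obs > nx * (length(pooled) - nx) / 2) 2 * hi else 2 * lo
  min(1, p)
}

# All-pairs interval intersection (1-based inclusive).
oracle_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      o <- min(a$end_bp[i], b$end_bp[j]) - max(a$start_bp[i], b$start_bp[j]) + 1
      if (o >= 1) {
        out[[length(out) + 1L]] <- data.frame(
          ai = i, bi = j, overlap_bp = o)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ai = integer(), bi = integer(),
                      overlap_bp = numeric()))
  }
  do.call(rbind, out)
}

# Point-in-interval count per SNP per individual (incidence oracle).
oracle_incidence <- function(runs, map, ids) {
  vapply(seq_len(nrow(map)), function(s) {
    covered <- vapply(ids, function(id) {
      r <- runs[runs$sample_id == id & runs$chrom == map$chrom[s], ]
      any(r$start_bp <= map$pos[s] & map$pos[s] <= r$end_bp)
    }, TRUE)
    sum(covered)
  }, 0L) / length(ids)
}

# Run-length grouping of selected flags per chromosome (island oracle).
oracle_islands <- function(selected, map, min_snps) {
  out <- list()
  idx <- which(selected)
  if (!length(idx)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer()))
  }
  grp <- cumsum(c(1, diff(idx) != 1 |
                    map$chrom[idx[-1]] != map$chrom[idx[-length(idx)]]))
  for (g in split(idx, grp)) {
    if (length(g) >= min_snps) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = map$chrom[g[1]], start_bp = map$pos[g[1]],
        end_bp = map$pos[g[length(g)]], n_snps = length(g))
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer()))
  }
  do.call(rbind, out)
}

expect_same_runs <- function(found, expected) {
  f <- found[order(found$start_bp), c("start_bp", "end_bp")]
  e <- expected[order(expected$start_bp), c("start_bp", "end_bp")]
  expect_equal(as.data.frame(f), as.data.frame(e),
               ignore_attr = TRUE)
}
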