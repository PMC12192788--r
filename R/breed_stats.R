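#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] returning a tidy row;
#' used to justify the nonparametric between-population comparisons
#' (per-animal run counts and length sums are typically heavily
#' non-normal).
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return Tibble with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got n = ", length(x))
  }
  if (length(unique(x)) == 1) stop("sample is constant")
  sw <- stats::shapiro.test(x)
  tibble::tibble(statistic = unname(sw$statistic),
                 p_value = sw$p.value)
}

#' Wilcoxon rank-sum test between two samples
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test with midranks for
#' ties. In `"auto"` mode the exact p-value is computed by enumeration
#' when both samples have at most 10 observations and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections is used. The reported statistic is the Mann-Whitney U of
#' the first sample.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return Tibble with `statistic`, `p_value`, `n_x`, `n_y`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  exact = TRUE,
                  approx = FALSE,
                  auto = length(x) <= 10 && length(y) <= 10 && !ties)
  if (exact && ties) {
    stop("exact mode is unavailable with ties; use mode = \"approx\"")
  }
  if (length(unique(c(x, y))) == 1) {
    # fully tied pooled sample: statistic at its null expectation
    return(tibble::tibble(statistic = length(x) * length(y) / 2,
                          p_value = 1, n_x = length(x), n_y = length(y),
                          method = "normal_approx"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic),
                 p_value = min(1, wt$p.value),
                 n_x = length(x), n_y = length(y),
                 method = if (exact) "exact" else "normal_approx")
}

#' Pairwise between-population run comparisons
#'
#' For every cumulative length class and every unordered population
#' pair, Wilcoxon rank-sum tests on the per-animal run count and on the
#' per-animal summed run length. Raw two-sided p-values are primary;
#' Bonferroni-adjusted columns (across pairs within one statistic and
#' class) are provided alongside.
#'
#' @param animal_summary Output of [per_animal_summary()].
#' @param min_n Populations with fewer animals than this are excluded
#'   with a warning; default 2.
#' @return A `breed_comparison` object; use [tidy()] for the long table
#'   with columns `class`, `statistic` (`n_runs` or `sum_bp`),
#'   `pop_a`, `pop_b`, `w_statistic`, `p_value`, `p_bonferroni`,
#'   `n_a`, `n_b`.
#' @export
pairwise_breed_tests <- function(animal_summary, min_n = 2) {
  counts <- table(dplyr::distinct(
    animal_summary[, c("sample_id", "population")])$population)
  small <- names(counts)[counts < min_n]
  if (length(small)) {
    warning("populations excluded (<", min_n, " animals): ",
            paste(small, collapse = ", "))
  }
  pops <- sort(names(counts)[counts >= min_n])
  if (length(pops) < 2) {
    res <- tibble::tibble(class = character(), statistic = character(),
                          pop_a = character(), pop_b = character(),
                          w_statistic = numeric(), p_value = numeric(),
                          p_bonferroni = numeric(), n_a = integer(),
                          n_b = integer())
    return(structure(list(results = res, populations = pops),
                     class = "breed_comparison"))
  }
  pairs <- utils::combn(pops, 2)
  classes <- unique(animal_summary$class)
  grid <- tidyr::crossing(
    class = classes, statistic = c("n_runs", "sum_bp"),
    pair = seq_len(ncol(pairs)))
  rows <- purrr::pmap(grid, function(class, statistic, pair) {
    a <- pairs[1, pair]; b <- pairs[2, pair]
    sub <- animal_summary[animal_summary$class == class, ]
    xa <- sub[[statistic]][sub$population == a]
    xb <- sub[[statistic]][sub$population == b]
    wt <- wilcoxon_rank_sum(xa, xb, mode = "auto")
    tibble::tibble(class = class, statistic = statistic,
                   pop_a = a, pop_b = b,
                   w_statistic = wt$statistic, p_value = wt$p_value,
                   n_a = length(xa), n_b = length(xb))
  })
  res <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$class, .data$statistic) |>
    dplyr::mutate(p_bonferroni = stats::p.adjust(.data$p_value,
                                                 method = "bonferroni")) |>
    dplyr::ungroup() |>
    dplyr::select("class", "statistic", "pop_a", "pop_b", "w_statistic",
                  "p_value", "p_bonferroni", "n_a", "n_b")
  structure(list(results = res, populations = pops),
            class = "breed_comparison")
}

#' @export
print.breed_comparison <- function(x, ...) {
  cat("breed_comparison: ", length(x$populations), " populations, ",
      nrow(x$results), " tests\n", sep = "")
  print(x$results, n = 10)
  invisible(x)
}

#' @rdname pairwise_breed_tests
#' @param x A `breed_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.breed_comparison <- function(x, ...) x$results

#' @rdname pairwise_breed_tests
#' @exportS3Method generics::glance
glance.breed_comparison <- function(x, ...) {
  tibble::tibble(
    n_populations = length(x$populations),
    n_tests = nrow(x$results),
    n_signif_raw = sum(x$results$p_value < 0.05),
    n_signif_bonferroni = sum(x$results$p_bonferroni < 0.05)
  )
}
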