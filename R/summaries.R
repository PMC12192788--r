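#' Length-class threshold ladders
#'
#' Cumulative "greater-than" length classes used for run summaries and
#' genome-coverage coefficients. Classes are not disjoint bins: a run
#' belongs to every class whose threshold its length strictly exceeds,
#' so counts, sums and coefficients are non-increasing along the ladder.
#'
#' @return Named numeric vector of thresholds in bp (names in Mb).
#' @export
roh_length_classes <- function() {
  c("1" = 1e6, "2" = 2e6, "4" = 4e6, "8" = 8e6, "16" = 16e6)
}

#' @rdname roh_length_classes
#' @export
rohet_length_classes <- function() {
  c("0.5" = 5e5, "1" = 1e6, "1.5" = 1.5e6)
}

check_classes <- function(classes) {
  stopifnot(is.numeric(classes), length(classes) >= 1,
            all(diff(classes) > 0))
  if (is.null(names(classes))) {
    names(classes) <- format(classes / 1e6, trim = TRUE)
  }
  classes
}

#' Autosomal genome length covered by SNPs
#'
#' Sum over autosomes of (last SNP position - first SNP position), the
#' denominator of the genomic coefficients F_ROH and D_ROHet.
#'
#' @param map Marker map tibble with `chrom` and `pos`.
#' @param autosomes Chromosome labels counted as autosomes.
#' @return Covered length in bp.
#' @export
covered_autosome_length <- function(map, autosomes = default_autosomes()) {
  m <- map[map$chrom %in% autosomes, ]
  if (nrow(m) == 0) stop("no autosomal SNPs in map")
  spans <- tapply(m$pos, m$chrom, function(p) max(p) - min(p))
  sum(as.numeric(spans))
}

#' Assign runs to cumulative length classes
#'
#' @param runs Run tibble from [detect_runs()].
#' @param classes Threshold ladder, e.g. [roh_length_classes()].
#' @return Tibble of runs replicated per class membership, with added
#'   columns `class` (label) and `threshold_bp`; a run of length L
#'   appears under every threshold t with L > t.
#' @export
classify_runs <- function(runs, classes = roh_length_classes()) {
  classes <- check_classes(classes)
  cls <- tibble::tibble(class = paste0(">", names(classes), " Mb"),
                        threshold_bp = unname(classes))
  out <- tidyr::crossing(runs, cls)
  out[out$length_bp > out$threshold_bp, ]
}

#' Per-animal run summary by length class
#'
#' For every individual and every cumulative length class: the number
#' of runs and the summed run length. Individuals with no qualifying
#' run in a class contribute zeros (and stay in population means).
#'
#' @param runs Run tibble from [detect_runs()].
#' @param samples Sample tibble (`sample_id`, `population`) defining the
#'   cohort, so zero-run animals are represented; defaults to the
#'   samples present in `runs`.
#' @param classes Threshold ladder in bp.
#' @return Tibble with `sample_id`, `population`, `class`,
#'   `threshold_bp`, `n_runs`, `sum_bp`.
#' @export
per_animal_summary <- function(runs, samples = NULL,
                               classes = roh_length_classes()) {
  classes <- check_classes(classes)
  if (is.null(samples)) {
    samples <- dplyr::distinct(runs[, c("sample_id", "population")])
  }
  cls <- tibble::tibble(class = paste0(">", names(classes), " Mb"),
                        threshold_bp = unname(classes))
  grid <- tidyr::crossing(samples[, c("sample_id", "population")], cls)
  hits <- classify_runs(runs, classes) |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     sum_bp = sum(.data$length_bp), .groups = "drop")
  out <- dplyr::left_join(grid, hits, by = c("sample_id", "class")) |>
    dplyr::mutate(n_runs = ifelse(is.na(.data$n_runs), 0L, .data$n_runs),
                  sum_bp = ifelse(is.na(.data$sum_bp), 0, .data$sum_bp))
  dplyr::arrange(out, .data$sample_id, .data$threshold_bp)
}

#' Per-population mean and SD of run statistics
#'
#' Population-level mean and sample standard deviation (n - 1
#' denominator) of per-animal run counts and summed lengths in each
#' cumulative length class.
#'
#' @param animal_summary Output of [per_animal_summary()].
#' @return Tibble with `population`, `class`, `threshold_bp`, `n_animals`,
#'   `mean_n_runs`, `sd_n_runs`, `mean_sum_mb`, `sd_sum_mb`.
#' @export
population_summary <- function(animal_summary) {
  animal_summary |>
    dplyr::group_by(.data$population, .data$class, .data$threshold_bp) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      mean_n_runs = mean(.data$n_runs),
      sd_n_runs = stats::sd(.data$n_runs),
      mean_sum_mb = mean(.data$sum_bp) / 1e6,
      sd_sum_mb = stats::sd(.data$sum_bp) / 1e6,
      .groups = "drop") |>
    dplyr::arrange(.data$population, .data$threshold_bp)
}

genomic_coefficient <- function(runs, map, samples, classes, autosomes,
                                value_name) {
  classes <- check_classes(classes)
  denom <- covered_autosome_length(map, autosomes)
  runs <- runs[runs$chrom %in% autosomes, ]
  summ <- per_animal_summary(runs, samples = samples, classes = classes)
  summ[[value_name]] <- summ$sum_bp / denom
  summ$denominator_bp <- denom
  summ[, c("sample_id", "population", "class", "threshold_bp",
           value_name, "denominator_bp")]
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Per individual and per length threshold, the summed length of ROH
#' exceeding the threshold divided by the SNP-covered autosomal genome
#' length ([covered_autosome_length()]).
#'
#' @param runs ROH tibble from [detect_runs()] with a homozygous-target
#'   rule set.
#' @param map Marker map of the dataset the runs came from.
#' @param samples Cohort sample tibble (zero-run animals get F_ROH 0);
#'   defaults to samples present in `runs`.
#' @param classes Threshold ladder; default [roh_length_classes()].
#' @param autosomes Autosome labels.
#' @return Tibble with `sample_id`, `population`, `class`,
#'   `threshold_bp`, `froh`, `denominator_bp`.
#' @export
f_roh <- function(runs, map, samples = NULL,
                  classes = roh_length_classes(),
                  autosomes = default_autosomes()) {
  genomic_coefficient(runs, map, samples, classes, autosomes, "froh")
}

#' Genome coverage of heterozygosity-rich regions D_ROHet
#'
#' As [f_roh()], for ROHet runs: the fraction of the SNP-covered
#' autosomal genome lying in heterozygosity-rich regions longer than
#' each threshold.
#'
#' @inheritParams f_roh
#' @param runs ROHet tibble from [detect_runs()] with a
#'   heterozygous-target rule set.
#' @return Tibble with `sample_id`, `population`, `class`,
#'   `threshold_bp`, `drohet`, `denominator_bp`.
#' @export
d_rohet <- function(runs, map, samples = NULL,
                    classes = rohet_length_classes(),
                    autosomes = default_autosomes()) {
  genomic_coefficient(runs, map, samples, classes, autosomes, "drohet")
}
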