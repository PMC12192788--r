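#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis — input paths, QC
#' thresholds, the two run-detection presets, length-class ladders,
#' island parameters, annotation paths and the output directory — into
#' a validated list. Defaults reproduce the package's standard
#' medium-density-array settings.
#'
#' @param ped,map Paths to PLINK PED/MAP input (alternatively pass a
#'   dataset directly to [run_pipeline()]).
#' @param out_dir Output directory (created if absent).
#' @param autosomes Autosome labels.
#' @param min_call_rate,max_missing,min_maf,hwe_alpha QC thresholds,
#'   see [qc_apply()].
#' @param roh_config,rohet_config Run rule sets. The ROHet preset uses
#'   a 0.5 Mb minimum length so the `>0.5 Mb` summary class is
#'   populated.
#' @param roh_classes,rohet_classes Length-class ladders (bp).
#' @param island_pct,min_island_snps Island-calling parameters.
#' @param annotation Optional path to a BED-like annotation file (QTL
#'   or genes) for island overlap.
#' @param seed Integer seed recorded in the manifest and applied before
#'   any stochastic stage (the standard pipeline is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ped = NULL, map = NULL, out_dir = "rohscan_out",
                            autosomes = default_autosomes(),
                            min_call_rate = 0.95, max_missing = 0.20,
                            min_maf = 0.05, hwe_alpha = 1e-5,
                            roh_config = default_roh_config(),
                            rohet_config = default_rohet_config(5e5),
                            roh_classes = roh_length_classes(),
                            rohet_classes = rohet_length_classes(),
                            island_pct = 1, min_island_snps = 2,
                            annotation = NULL, seed = 1L) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            max_missing >= 0, max_missing < 1,
            min_maf >= 0, min_maf <= 0.5,
            hwe_alpha >= 0, hwe_alpha <= 1,
            island_pct > 0, island_pct < 100, min_island_snps >= 1)
  for (p in c(ped, map, annotation)) {
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  }
  structure(list(ped = ped, map = map, out_dir = out_dir,
                 autosomes = autosomes, min_call_rate = min_call_rate,
                 max_missing = max_missing, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, roh_config = roh_config,
                 rohet_config = rohet_config, roh_classes = roh_classes,
                 rohet_classes = rohet_classes, island_pct = island_pct,
                 min_island_snps = min_island_snps,
                 annotation = annotation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [pipeline_config()]; the `roh` and `rohet` blocks (fields
#' `min_snps`, `min_length_bp`, `max_gap_bp`, `max_opposite`,
#' `max_missing`) populate the two rule-set presets.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(block, default) {
    if (is.null(block)) return(default)
    args <- utils::modifyList(unclass(default), block)
    run_config(args$target_state, args$min_snps, args$min_length_bp,
               args$max_gap_bp, args$max_opposite, args$max_missing)
  }
  cls <- function(block, default) {
    if (is.null(block)) default else unlist(block)
  }
  pipeline_config(
    ped = y$ped, map = y$map,
    out_dir = y$out_dir %||% "rohscan_out",
    autosomes = as.character(y$autosomes %||% default_autosomes()),
    min_call_rate = y$min_call_rate %||% 0.95,
    max_missing = y$max_missing %||% 0.20,
    min_maf = y$min_maf %||% 0.05,
    hwe_alpha = y$hwe_alpha %||% 1e-5,
    roh_config = mk(y$roh, default_roh_config()),
    rohet_config = mk(y$rohet, default_rohet_config(5e5)),
    roh_classes = cls(y$roh_classes, roh_length_classes()),
    rohet_classes = cls(y$rohet_classes, rohet_length_classes()),
    island_pct = y$island_pct %||% 1,
    min_island_snps = y$min_island_snps %||% 2,
    annotation = y$annotation,
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_csv_det <- function(x, path) {
  # drop list-columns (e.g. snp_ids) for flat CSV export
  x <- x[, !vapply(x, is.list, TRUE), drop = FALSE]
  readr::write_csv(x, path)
}

#' Run the full analysis pipeline
#'
#' Executes QC, ROH and ROHet detection, per-animal and per-population
#' summaries, genomic coefficients, island calling (with annotation
#' overlap when an annotation file is configured) and pairwise
#' between-population tests, writing a deterministic set of CSV/BED
#' outputs plus a YAML run manifest to `config$out_dir`. Re-running
#' with the same inputs and configuration reproduces every output file
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param ds Optional `genotype_dataset`; when `NULL` the configured
#'   PED/MAP paths are read.
#' @param quiet Suppress per-stage messages.
#' @param make_plots Also write per-population Manhattan-style ROH
#'   incidence plots (PNG, threshold as dashed line); default `FALSE`
#'   since graphics devices may be unavailable on headless systems.
#' @return Invisibly, a list with the main result tables and the
#'   manifest.
#' @export
run_pipeline <- function(config, ds = NULL, quiet = FALSE,
                         make_plots = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[rohscan] ", ...)
  stages <- character()
  note <- function(stage) stages <<- c(stages, stage)
  set.seed(config$seed)

  say("stage input")
  if (is.null(ds)) {
    if (is.null(config$ped) || is.null(config$map)) {
      stop("stage input: no dataset given and no ped/map configured")
    }
    ds <- read_plink(config$ped, config$map)
  }
  note("input")

  say("stage qc")
  qc <- qc_apply(ds, min_call_rate = config$min_call_rate,
                 autosomes = config$autosomes,
                 max_missing = config$max_missing,
                 min_maf = config$min_maf, hwe_alpha = config$hwe_alpha)
  write_csv_det(qc$report, file.path(config$out_dir, "qc_report.csv"))
  note("qc")

  say("stage detect")
  roh <- detect_runs(qc$ds, config$roh_config, config$autosomes)
  rohet <- detect_runs(qc$ds, config$rohet_config, config$autosomes)
  write_csv_det(roh, file.path(config$out_dir, "runs_roh.csv"))
  write_csv_det(rohet, file.path(config$out_dir, "runs_rohet.csv"))
  write_segments_bed(roh, file.path(config$out_dir, "runs_roh.bed"))
  write_segments_bed(rohet, file.path(config$out_dir, "runs_rohet.bed"))
  note("detect")

  say("stage summarize")
  samples <- qc$ds$samples
  asum <- per_animal_summary(roh, samples, config$roh_classes)
  asum_het <- per_animal_summary(rohet, samples, config$rohet_classes)
  froh <- f_roh(roh, qc$ds$map, samples, config$roh_classes,
                config$autosomes)
  droh <- d_rohet(rohet, qc$ds$map, samples, config$rohet_classes,
                  config$autosomes)
  write_csv_det(asum, file.path(config$out_dir, "animal_summary_roh.csv"))
  write_csv_det(asum_het,
                file.path(config$out_dir, "animal_summary_rohet.csv"))
  write_csv_det(population_summary(asum),
                file.path(config$out_dir, "breed_summary_roh.csv"))
  write_csv_det(population_summary(asum_het),
                file.path(config$out_dir, "breed_summary_rohet.csv"))
  write_csv_det(froh, file.path(config$out_dir, "froh.csv"))
  write_csv_det(droh, file.path(config$out_dir, "drohet.csv"))
  note("summarize")

  say("stage islands")
  cohort_sizes <- table(samples$population)
  islands <- detect_islands(roh, qc$ds$map,
                            cohort_sizes = stats::setNames(
                              as.integer(cohort_sizes),
                              names(cohort_sizes)),
                            pct = config$island_pct,
                            min_island_snps = config$min_island_snps)
  write_csv_det(islands, file.path(config$out_dir, "islands.csv"))
  write_segments_bed(islands, file.path(config$out_dir, "islands.bed"))
  if (make_plots) {
    for (pop in sort(unique(samples$population))) {
      inc <- snp_incidence(roh, qc$ds$map, pop,
                           n_individuals = sum(samples$population == pop))
      thr <- top_percentile_threshold(inc$incidence, config$island_pct)
      p <- plot_snp_incidence(inc, threshold = thr, title = pop)
      tryCatch(
        ggplot2::ggsave(file.path(config$out_dir,
                                  paste0("incidence_", pop, ".png")),
                        p, width = 8, height = 3, dpi = 120),
        error = function(e) say("plot skipped for ", pop, ": ",
                                conditionMessage(e)))
    }
  }
  overlaps <- NULL
  if (!is.null(config$annotation)) {
    ann <- read_annotation_bed(config$annotation)
    overlaps <- overlap_annotations(islands, ann)
    write_csv_det(overlaps, file.path(config$out_dir, "overlaps.csv"))
  } else {
    say("no annotation file configured; overlap step skipped")
  }
  note("islands")

  say("stage compare")
  cmp <- pairwise_breed_tests(asum)
  write_csv_det(tidy(cmp), file.path(config$out_dir, "pairwise_tests.csv"))
  note("compare")

  manifest <- list(
    package = "rohscan",
    version = as.character(utils::packageVersion("rohscan")),
    seed = config$seed,
    stages = lapply(stages, function(s) list(stage = s, status = "ok")),
    thresholds = list(min_call_rate = config$min_call_rate,
                      max_missing = config$max_missing,
                      min_maf = config$min_maf,
                      hwe_alpha = config$hwe_alpha,
                      island_pct = config$island_pct),
    counts = list(n_samples = nrow(samples), n_snps = nrow(qc$ds$map),
                  n_roh = nrow(roh), n_rohet = nrow(rohet),
                  n_islands = nrow(islands),
                  n_overlaps = if (is.null(overlaps)) 0L
                    else nrow(overlaps),
                  n_tests = nrow(tidy(cmp))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  say("done: ", length(stages), " stages ok")
  invisible(list(qc = qc, roh = roh, rohet = rohet,
                 animal_summary = asum, animal_summary_rohet = asum_het,
                 froh = froh, drohet = droh, islands = islands,
                 overlaps = overlaps, comparisons = cmp,
                 manifest = manifest))
}
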