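#' Read PLINK PED/MAP text files
#'
#' Parses whitespace-delimited PLINK text genotypes into a
#' [genotype_dataset()]. The PED family-ID column is used as the
#' population label (the conventional carrier for breed or cohort in
#' multi-population array studies). Allele pairs are recoded against the
#' two alleles observed at each marker: `allele_a` is the first allele
#' seen scanning samples in file order, `0 0` is a missing call. Markers
#' are sorted by (chromosome, position) with genotype columns permuted
#' to match.
#'
#' @param ped_path Path to the `.ped` file (6 metadata columns followed
#'   by two allele columns per marker).
#' @param map_path Path to the `.map` file (4 columns: chromosome,
#'   snp id, genetic distance, bp position).
#' @return A `genotype_dataset`.
#' @seealso [write_plink()]
#' @export
read_plink <- function(ped_path, map_path) {
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4L)) {
    stop("MAP line ", which(nf != 4L)[1], " has ", nf[nf != 4L][1],
         " fields, expected 4")
  }
  mp <- do.call(rbind, map_fields)
  map <- tibble::tibble(
    chrom = mp[, 1],
    snp_id = mp[, 2],
    pos = as.integer(mp[, 4])
  )
  n_snp <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * n_snp
  nf <- lengths(ped_fields)
  if (any(nf != want)) {
    i <- which(nf != want)[1]
    stop("PED line ", i, " has ", nf[i], " fields, expected ", want,
         " (6 + 2 alleles x ", n_snp, " markers)")
  }
  pd <- do.call(rbind, ped_fields)
  samples <- tibble::tibble(
    sample_id = pd[, 2],
    population = pd[, 1]
  )
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in PED: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  }
  al <- pd[, -(1:6), drop = FALSE]
  legal <- c("A", "C", "G", "T", "0", "1", "2", "B")
  bad <- !(al %in% legal)
  if (any(bad)) {
    stop("illegal allele code '", al[bad][1],
         "' (expected A/C/G/T, 1/2 or 0 for missing)")
  }
  a1 <- al[, seq(1, 2 * n_snp, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * n_snp, by = 2), drop = FALSE]
  if (any((a1 == "0") != (a2 == "0"))) {
    stop("half-missing genotype (one allele '0'): not supported")
  }
  geno <- matrix(NA_integer_, nrow(pd), n_snp)
  allele_a <- rep(NA_character_, n_snp)
  allele_b <- rep(NA_character_, n_snp)
  for (s in seq_len(n_snp)) {
    x1 <- a1[, s]
    x2 <- a2[, s]
    called <- x1 != "0"
    obs <- unique(c(x1[called], x2[called]))
    if (length(obs) > 2) {
      stop("marker ", map$snp_id[s], " has >2 alleles: ",
           paste(obs, collapse = "/"))
    }
    if (length(obs) == 0) next
    allele_a[s] <- obs[1]
    if (length(obs) == 2) allele_b[s] <- obs[2]
    code <- (x1 != obs[1]) + (x2 != obs[1])
    code[!called] <- NA_integer_
    geno[, s] <- as.integer(code)
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b
  genotype_dataset(map, samples, geno)
}

#' Write a genotype dataset as PLINK PED/MAP text
#'
#' Inverse of [read_plink()]: `read_plink(write_plink(ds))` reproduces
#' the map, genotype codes and population labels exactly. Missing calls
#' are written as `0 0`; markers whose alleles were never observed are
#' written with placeholder alleles `A`/`B`.
#'
#' @param ds A `genotype_dataset`.
#' @param basename Output path without extension; writes
#'   `<basename>.ped` and `<basename>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(ds, basename) {
  stopifnot(inherits(ds, "genotype_dataset"))
  map_path <- paste0(basename, ".map")
  ped_path <- paste0(basename, ".ped")
  writeLines(paste(ds$map$chrom, ds$map$snp_id, 0, ds$map$pos), map_path)

  aa <- ifelse(is.na(ds$map$allele_a), "A", ds$map$allele_a)
  ab <- ifelse(is.na(ds$map$allele_b), "B", ds$map$allele_b)
  n <- nrow(ds$samples)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- ds$geno[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, ab, aa))
    x2 <- ifelse(is.na(g), "0", ifelse(g == 0L, aa, ab))
    lines[i] <- paste(ds$samples$population[i], ds$samples$sample_id[i],
                      "0", "0", "0", "-9",
                      paste(rbind(x1, x2), collapse = " "))
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Write run segments as BED
#'
#' Converts segments from the package's 1-based inclusive coordinates to
#' BED 0-based half-open, one line per segment, sorted by (chromosome,
#' start, sample). The name column carries `sample_id`.
#'
#' @param segments Tibble of runs with at least `chrom`, `start_bp`,
#'   `end_bp` and optionally `sample_id`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_segments_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname (0-based half-open)", con)
  if (nrow(segments) == 0) return(invisible(path))
  name <- if ("sample_id" %in% names(segments)) segments$sample_id else "."
  df <- tibble::tibble(
    chrom = as.character(segments$chrom),
    start = segments$start_bp - 1L,
    end = segments$end_bp,
    name = name
  )
  df <- df[order(chrom_sort_key(df$chrom), df$start, df$name), ]
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s",
                     df$chrom, df$start, df$end, df$name), con)
  invisible(path)
}

#' Read annotation intervals from a BED-like file
#'
#' Reads >=3 tab-separated columns (chromosome, start, end, optional
#' name, optional category such as a QTL trait), converting BED 0-based
#' half-open coordinates to the package's 1-based inclusive convention.
#' Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path Path to the BED file.
#' @return Tibble with `chrom`, `start_bp`, `end_bp`, `name`,
#'   `category` (1-based inclusive).
#' @export
read_annotation_bed <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  empty <- tibble::tibble(chrom = character(), start_bp = integer(),
                          end_bp = integer(), name = character(),
                          category = character())
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("annotation line ", which(nf < 3L)[1], " has fewer than 3 columns")
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[`, "", 1),
    start_bp = as.integer(vapply(fields, `[`, "", 2)) + 1L,
    end_bp = as.integer(vapply(fields, `[`, "", 3)),
    name = vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", ""),
    category = vapply(fields, function(f) if (length(f) >= 5) f[5] else ".", "")
  )
  bad <- out$start_bp > out$end_bp
  if (any(bad)) {
    stop("annotation line ", which(bad)[1],
         ": start > end after coordinate conversion")
  }
  out
}
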