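#' Read and write dosage matrices as TSV
#'
#' The dosage TSV has one row per sample: a `sample_id` column followed by one
#' column per SNP (dosage of the reference allele, 0/1/2, `NA` for missing).
#'
#' @param geno Samples x SNPs dosage matrix with dimnames.
#' @param path File path.
#' @return `write_dosage_tsv()` returns `path` invisibly; `read_dosage_tsv()`
#'   returns the dosage matrix.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(is.matrix(geno))
  df <- tibble::as_tibble(as.data.frame(geno), .name_repair = "minimal")
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(sample_id = rownames(geno)), df),
                   path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  g <- as.matrix(df[, -1])
  rownames(g) <- df$sample_id
  g
}

#' Read and write PLINK-style MAP files
#'
#' Four whitespace-separated columns: chromosome, marker id, genetic position
#' (cM), physical position (bp); no header.
#'
#' @param map Marker map tibble (`chrom`, `id`, `bp`, `cM`).
#' @param path File path.
#' @return `write_map()` returns `path` invisibly; `read_map()` returns the
#'   map tibble.
#' @export
write_map <- function(map, path) {
  check_columns(map, c("chrom", "id", "bp", "cM"), "map")
  readr::write_tsv(map[, c("chrom", "id", "cM", "bp")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "id", "cM", "bp"),
                        col_types = "ccdd", progress = FALSE)
  ok <- tapply(df$cM, df$chrom, function(x) all(diff(x) > 0))
  if (!all(ok)) {
    abort(sprintf("Map positions are not strictly increasing on chromosome(s): %s.",
                  paste(names(ok)[!ok], collapse = ", ")))
  }
  tibble::tibble(chrom = df$chrom, id = df$id, bp = as.integer(df$bp), cM = df$cM)
}

#' Read IBD/HBD segments in Refined-IBD-style tabular format
#'
#' Accepts tab-separated files with either the 8-column Refined-IBD dialect
#' (`sample_a`, `hap_a`, `sample_b`, `hap_b`, `chrom`, `start_bp`, `end_bp`,
#' `score`; haplotype indices and score are ignored) or a minimal 5-column
#' format (`sample_a`, `sample_b`, `chrom`, `start_bp`, `end_bp`). No header.
#' Base-pair coordinates are converted to cM by linear interpolation on the
#' map; positions outside the map are clamped to the map ends with a warning.
#' Records are merged per pair per chromosome on load (0-1 IBD status).
#'
#' @param path File path.
#' @param map Marker map used for the bp -> cM conversion.
#' @return Segment tibble (`sample_a`, `sample_b`, `chrom`, `start_cm`,
#'   `end_cm`), normalized by [merge_segments()].
#' @export
read_ibd_segments <- function(path, map) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(sample_a = character(0), sample_b = character(0),
                          chrom = character(0), start_cm = numeric(0),
                          end_cm = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(5L, 8L)) || length(unique(nf)) != 1L) {
    bad <- which(!nf %in% c(5L, 8L) | nf != nf[1])[1]
    abort(sprintf("Malformed segment line %d: expected %s tab-separated fields, found %d.",
                  bad, if (nf[1] %in% c(5L, 8L)) nf[1] else "5 or 8", nf[bad]))
  }
  pick <- if (nf[1] == 8L) c(1L, 3L, 5L, 6L, 7L) else 1:5
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)[, pick, drop = FALSE]
  start_bp <- suppressWarnings(as.numeric(m[, 4]))
  end_bp <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(!is.finite(start_bp) | !is.finite(end_bp) | start_bp >= end_bp)
  if (length(bad)) {
    abort(sprintf("Malformed segment line %d: non-numeric or inverted coordinates.",
                  bad[1]))
  }
  segs <- tibble::tibble(sample_a = m[, 1], sample_b = m[, 2], chrom = m[, 3],
                         start_bp = start_bp, end_bp = end_bp)
  segs <- segments_bp_to_cm(segs, map)
  merge_segments(segs)
}

segments_bp_to_cm <- function(segs, map) {
  bad <- !segs$chrom %in% map$chrom
  if (any(bad)) {
    abort(sprintf("Segment line %d is on chromosome '%s' not present in the map.",
                  which(bad)[1], segs$chrom[which(bad)[1]]))
  }
  out <- vector("list", length(unique(segs$chrom)))
  clamped <- FALSE
  for (i in seq_along(out)) {
    c_i <- unique(segs$chrom)[i]
    mc <- map[map$chrom == c_i, ]
    sc <- segs[segs$chrom == c_i, ]
    if (any(sc$start_bp < min(mc$bp) | sc$end_bp > max(mc$bp))) clamped <- TRUE
    out[[i]] <- tibble::tibble(sample_a = sc$sample_a, sample_b = sc$sample_b,
                               chrom = c_i,
                               start_cm = interp_bp_to_cm(sc$start_bp, mc),
                               end_cm = interp_bp_to_cm(sc$end_bp, mc))
  }
  if (clamped) {
    warn("Some segment coordinates lie outside the map and were clamped to the map ends.")
  }
  res <- dplyr::bind_rows(out)
  res[res$end_cm > res$start_cm, , drop = FALSE]
}

#' Write IBD/HBD segments in the Refined-IBD-style dialect
#'
#' Writes the 8-column tab-separated format read by [read_ibd_segments()]
#' (haplotype indices written as 0 and score as the segment cM length). cM
#' coordinates are converted to bp by linear interpolation on the map.
#'
#' @param segs Segment tibble with cM coordinates.
#' @param map Marker map for the cM -> bp conversion.
#' @param path File path.
#' @export
write_ibd_segments <- function(segs, map, path) {
  check_columns(segs, c("sample_a", "sample_b", "chrom", "start_cm", "end_cm"), "segs")
  start_bp <- end_bp <- numeric(nrow(segs))
  for (c_i in unique(segs$chrom)) {
    mc <- map[map$chrom == c_i, ]
    sel <- segs$chrom == c_i
    start_bp[sel] <- round(stats::approx(mc$cM, mc$bp, segs$start_cm[sel], rule = 2)$y)
    end_bp[sel] <- round(stats::approx(mc$cM, mc$bp, segs$end_cm[sel], rule = 2)$y)
  }
  df <- data.frame(segs$sample_a, 0L, segs$sample_b, 0L, segs$chrom,
                   start_bp, end_bp, segs$end_cm - segs$start_cm)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read and write trait tables
#'
#' Tab-separated with a header: `sample_id`, `value`, then any covariate
#' columns.
#'
#' @param trait Data frame with at least `sample_id` and `value`.
#' @param path File path.
#' @export
write_trait_tsv <- function(trait, path) {
  check_columns(trait, c("sample_id", "value"), "trait")
  readr::write_tsv(trait, path)
  invisible(path)
}

#' @rdname write_trait_tsv
#' @export
read_trait_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), value = readr::col_double()),
    progress = FALSE)
}

#' Write genotypes as an uncompressed VCF
#'
#' Writes a minimal VCFv4.2 with GT-only FORMAT; dosage 0/1/2 of the reference
#' allele `A` maps to genotypes `0/0`, `0/1`, `1/1` of the alternate allele
#' `B` (so the VCF ALT dosage is `2 - x`), and missing dosage to `./.`.
#' Reading back with [read_vcf()] restores the dosage matrix and a map
#' skeleton (bp positions; cM must come from a MAP file).
#'
#' @param geno Samples x SNPs dosage matrix (or `population_sim`).
#' @param map Marker map (`chrom`, `id`, `bp`).
#' @param path Output path (plain text).
#' @export
write_vcf <- function(geno, map = NULL, path) {
  if (inherits(geno, "population_sim")) {
    map <- map %||% geno$map
    geno <- geno$genotypes
  }
  stopifnot(is.matrix(geno), !is.null(map))
  check_columns(map, c("chrom", "id", "bp"), "map")
  stopifnot(nrow(map) == ncol(geno))
  gt <- c("1/1", "0/1", "0/0") # index by dosage + 1 (ALT carries 2 - x)
  body <- matrix(gt[geno + 1], nrow = nrow(geno))
  body[is.na(geno)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=ibdherit",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"),
    paste(map$chrom, map$bp, map$id, "A", "B", ".", ".", ".", "GT",
          apply(body, 2, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields into reference-allele dosages (the VCF REF allele is the
#' reference allele of the dosage matrix). Requires the `vcfR` package.
#'
#' @param path VCF path (plain or gzipped).
#' @return List with `genotypes` (samples x SNPs dosage matrix) and `map`
#'   (tibble `chrom`, `id`, `bp`; `cM` set to `NA`).
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF requires the `vcfR` package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles, then convert to REF dosage
  alt <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  alt <- alt + (substr(gt, 1, 1) == "1") + (substr(gt, 3, 3) == "1")
  alt[substr(gt, 1, 1) == "."] <- NA_integer_
  fix <- vcfR::getFIX(v)
  list(genotypes = t(2L - alt),
       map = tibble::tibble(chrom = fix[, "CHROM"], id = fix[, "ID"],
                            bp = as.integer(fix[, "POS"]), cM = NA_real_))
}

#' Write a study summary and its run manifest
#'
#' Writes `summary.tsv` and `estimates.tsv` plus `manifest.json` recording the
#' seed, configuration, exclusion counts and rate threshold, for
#' reproducibility.
#'
#' @param study A `study_summary` from [run_simulation_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$summary, file.path(dir, "summary.tsv"))
  readr::write_tsv(study$estimates, file.path(dir, "estimates.tsv"))
  cfg <- study$config
  manifest <- list(
    seed = study$seed, true_h2 = study$true_h2,
    n_samples_analyzed = length(study$samples),
    excluded_relatives = study$excluded_relatives,
    pc_outliers = study$pc_outliers,
    rate_threshold = study$rate_threshold,
    n_failed = study$n_failed,
    config = cfg[setdiff(names(cfg), character(0))])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
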