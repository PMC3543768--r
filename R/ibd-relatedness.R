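#' Merge overlapping segment records
#'
#' Normalizes a segment set so that records are non-overlapping per pair per
#' chromosome (IBD has 0-1 status per pair: overlapping or abutting records
#' collapse into one). Self-pairs (HBD records) are merged per individual.
#'
#' @param segs Segment tibble (`sample_a`, `sample_b`, `chrom`, `start_cm`,
#'   `end_cm`) with `start_cm < end_cm`.
#' @return A tibble of the same shape with merged records, ordered by pair,
#'   chromosome and start.
#' @export
merge_segments <- function(segs) {
  check_columns(segs, c("sample_a", "sample_b", "chrom", "start_cm", "end_cm"), "segs")
  if (any(segs$start_cm >= segs$end_cm)) {
    abort(sprintf("Segment record %d has start_cm >= end_cm.",
                  which(segs$start_cm >= segs$end_cm)[1]))
  }
  if (!nrow(segs)) return(tibble::as_tibble(segs))
  sample_a <- sample_b <- chrom <- start_cm <- end_cm <- run_end <- block <- NULL
  dt <- data.table::as.data.table(segs[, c("sample_a", "sample_b", "chrom",
                                           "start_cm", "end_cm")])
  # order pair ids so (a, b) and (b, a) records merge
  swap <- dt$sample_a > dt$sample_b
  if (any(swap)) {
    tmp <- dt$sample_a[swap]
    dt$sample_a[swap] <- dt$sample_b[swap]
    dt$sample_b[swap] <- tmp
  }
  data.table::setorder(dt, sample_a, sample_b, chrom, start_cm, end_cm)
  dt[, run_end := cummax(end_cm), by = list(sample_a, sample_b, chrom)]
  prev_end <- data.table::shift(dt$run_end, 1L, fill = -Inf)
  first <- !duplicated(dt[, list(sample_a, sample_b, chrom)])
  dt[, block := cumsum(first | start_cm > prev_end)]
  out <- dt[, list(sample_a = sample_a[1L], sample_b = sample_b[1L],
                   chrom = chrom[1L], start_cm = min(start_cm),
                   end_cm = max(end_cm)), by = block]
  tibble::as_tibble(out[, list(sample_a, sample_b, chrom, start_cm, end_cm)])
}

#' IBD-segment relatedness weighted by local detection rate
#'
#' Estimates pairwise relatedness from detected IBD segments, weighting each
#' inter-marker interval by the inverse of its IBD detection rate so that every
#' part of the genome contributes equally:
#' \deqn{R(j,k) = \frac{\sum_i 1\{IR_i > T\}\, IBD(j,k,i)\, L_i / IR_i}
#'                     {\sum_i 2 \cdot 1\{IR_i > T\}\, L_i / IR_i}}
#' where the sums run over inter-marker intervals `i` (the interval after the
#' last marker of each chromosome does not exist), `IBD(j,k,i)` is 1 when the
#' pair has a detected segment spanning interval `i` entirely, `L_i` is the
#' interval's genetic length and `IR_i` its IBD rate. Intervals with
#' `IR <= T` are excluded from numerator and denominator. The factor 2 makes
#' the value twice the realized kinship (a pair sharing the whole included
#' genome gets 0.5, ignoring inbreeding).
#'
#' @param segs Detected segment tibble, non-overlapping per pair (see
#'   [merge_segments()]).
#' @param track IBD-rate track from [compute_ibd_rate()] on the same map.
#' @param threshold Rate threshold `T` (see [rate_threshold()]); intervals with
#'   `ir <= threshold` are excluded. Default 0 keeps all intervals with
#'   positive rate.
#' @param samples Character vector of all sample ids (rows/columns of the
#'   result). Defaults to the ids present in `segs`; pass the full sample list
#'   explicitly so samples without segments are represented.
#' @param hbd Optional HBD segment tibble (`sample_a == sample_b`) used to set
#'   the diagonal to `1 + f` via [hbd_inbreeding()]; without it the diagonal
#'   is 1.
#' @param map Marker map (required when `hbd` is given, to compute `f`).
#' @return A [relatedness_matrix()] with method `"ibd_weighted"`.
#' @export
weighted_relatedness <- function(segs, track, threshold = 0, samples = NULL,
                                 hbd = NULL, map = NULL) {
  check_columns(track, c("chrom", "interval", "start_cm", "end_cm",
                         "length_cm", "ir"), "track")
  check_scalar_number(threshold, "threshold", lower = 0)
  w <- ifelse(track$ir > threshold, track$length_cm / pmax(track$ir, 1e-300), 0)
  if (all(w == 0)) {
    abort("All intervals have IR <= threshold: the weighted denominator is undefined.")
  }
  ibd_relatedness_impl(segs, track, w, samples, hbd, map,
                       method = "ibd_weighted")
}

#' Unweighted IBD-segment relatedness
#'
#' The total genetic length of detected IBD segments for a pair divided by
#' twice the genetic length of the genome; equivalently the weighted estimator
#' with the IBD rate replaced by a constant. Computed directly from segment
#' lengths (no interval discretization), so a pair sharing the whole genome
#' gets exactly 0.5.
#'
#' @inheritParams weighted_relatedness
#' @param map Marker map defining the genome length.
#' @return A [relatedness_matrix()] with method `"ibd_unweighted"`.
#' @export
unweighted_relatedness <- function(segs, map, samples = NULL, hbd = NULL) {
  check_columns(segs, c("sample_a", "sample_b", "chrom", "start_cm", "end_cm"), "segs")
  G <- genome_length_cM(map)
  samples <- samples %||% sort(unique(c(segs$sample_a, segs$sample_b)))
  segs <- merge_segments(segs) # overlapping records must not double count
  tot <- pair_totals(segs, segs$end_cm - segs$start_cm)
  build_relatedness(samples, tot$sample_a, tot$sample_b, tot$total / (2 * G),
                    hbd = hbd, map = map, method = "ibd_unweighted")
}

# Shared engine for interval-weighted relatedness. `w` is the per-interval
# weight vector in track row order; the value for a pair is
# sum(w over covered included intervals) / (2 * sum(w)).
ibd_relatedness_impl <- function(segs, track, w, samples, hbd, map, method) {
  check_columns(segs, c("sample_a", "sample_b", "chrom", "start_cm", "end_cm"), "segs")
  samples <- samples %||% sort(unique(c(segs$sample_a, segs$sample_b)))
  segs <- merge_segments(segs) # 0-1 IBD status; also restores split records
  denom <- 2 * sum(w)
  if (!nrow(segs)) {
    return(build_relatedness(samples, character(0), character(0), numeric(0),
                             hbd = hbd, map = map, method = method))
  }
  chroms <- unique(track$chrom)
  bad <- !segs$chrom %in% chroms
  if (any(bad)) {
    abort(sprintf("Segment record %d lies on chromosome '%s' not in the track.",
                  which(bad)[1], segs$chrom[which(bad)[1]]))
  }
  csum <- c(0, cumsum(w))
  n_int <- tapply(track$interval, factor(track$chrom, levels = chroms), length)
  offset <- setNames(cumsum(c(0L, unname(n_int)))[seq_along(chroms)], chroms)
  num <- numeric(nrow(segs))
  for (c_i in chroms) {
    sel <- which(segs$chrom == c_i)
    if (!length(sel)) next
    tc <- track[track$chrom == c_i, ]
    pos <- c(tc$start_cm, tc$end_cm[nrow(tc)])
    rng <- covered_interval_range(segs$start_cm[sel], segs$end_cm[sel], pos)
    ok <- rng$first <= rng$last
    gfirst <- offset[c_i] + rng$first
    glast <- offset[c_i] + rng$last
    num[sel[ok]] <- csum[glast[ok] + 1L] - csum[gfirst[ok]]
  }
  tot <- pair_totals(segs, num)
  build_relatedness(samples, tot$sample_a, tot$sample_b, tot$total / denom,
                    hbd = hbd, map = map, method = method)
}

# Sum `values` over segments by unordered pair.
pair_totals <- function(segs, values) {
  sample_a <- sample_b <- value <- NULL # data.table NSE
  dt <- data.table::data.table(sample_a = pmin(segs$sample_a, segs$sample_b),
                               sample_b = pmax(segs$sample_a, segs$sample_b),
                               value = values)
  dt[, list(total = sum(value)), by = list(sample_a, sample_b)]
}

# Assemble a relatedness_matrix from per-pair values.
build_relatedness <- function(samples, sample_a, sample_b, values,
                              hbd = NULL, map = NULL, method = "unspecified") {
  n <- length(samples)
  A <- matrix(0, n, n, dimnames = list(samples, samples))
  if (length(values)) {
    ia <- match(sample_a, samples)
    ib <- match(sample_b, samples)
    if (anyNA(ia) || anyNA(ib)) {
      abort("Segments mention samples absent from `samples`.")
    }
    self <- ia == ib
    if (any(self)) abort("IBD segment set contains self-pairs; pass HBD records via `hbd`.")
    A[cbind(ia, ib)] <- values
    A[cbind(ib, ia)] <- values
  }
  diag(A) <- 1
  if (!is.null(hbd)) {
    if (is.null(map)) abort("`map` is required to compute inbreeding from `hbd`.")
    f <- hbd_inbreeding(hbd, map)
    idx <- match(f$sample_id, samples)
    keep <- !is.na(idx)
    diag(A)[idx[keep]] <- 1 + f$f[keep]
  }
  relatedness_matrix(A, method = method)
}

#' Inbreeding coefficients from HBD segments
#'
#' The inbreeding coefficient of an individual is estimated as the total
#' genetic length of its homozygosity-by-descent segments divided by the
#' genetic length of the genome. Overlapping HBD records are merged before
#' summation. On a relatedness matrix the result enters as the diagonal
#' `1 + f`.
#'
#' @param hbd HBD segment tibble with `sample_a == sample_b` for every record.
#' @param map Marker map defining the genome length.
#' @return A tibble `sample_id`, `f`.
#' @export
hbd_inbreeding <- function(hbd, map) {
  check_columns(hbd, c("sample_a", "sample_b", "chrom", "start_cm", "end_cm"), "hbd")
  if (any(hbd$sample_a != hbd$sample_b)) {
    abort("HBD records must have sample_a == sample_b.")
  }
  G <- genome_length_cM(map)
  if (!nrow(hbd)) return(tibble::tibble(sample_id = character(0), f = numeric(0)))
  merged <- merge_segments(hbd)
  tot <- pair_totals(merged, merged$end_cm - merged$start_cm)
  tibble::tibble(sample_id = tot$sample_a, f = tot$total / G)
}

#' Greedy removal of close relatives
#'
#' Identifies individuals to drop so that no remaining pair shares more than
#' `threshold_cM` of total detected IBD. While any pair exceeds the threshold,
#' the individual participating in the most such pairs is removed (ties broken
#' by lexicographically smallest sample id), which removes one individual from
#' each offending pair with few removals overall. The default threshold of
#' 750 cM corresponds, on a ~3,500 cM autosomal map, to first cousins or closer
#' in an outbred population.
#'
#' @param segs Detected IBD segment tibble.
#' @param map Marker map (unused for the totals, kept for interface symmetry
#'   and coordinate validation).
#' @param threshold_cM Total-sharing threshold in cM (> 0).
#' @return Character vector of removed sample ids (in removal order); empty if
#'   no pair exceeds the threshold.
#' @export
close_relative_exclusion <- function(segs, map, threshold_cM = 750) {
  check_scalar_number(threshold_cM, "threshold_cM", lower = 1e-12)
  merged <- merge_segments(segs)
  if (!nrow(merged)) return(character(0))
  tot <- pair_totals(merged, merged$end_cm - merged$start_cm)
  over <- tot[tot$total > threshold_cM, ]
  removed <- character(0)
  while (nrow(over)) {
    ids <- c(over$sample_a, over$sample_b)
    counts <- sort(table(ids), decreasing = TRUE)
    top <- names(counts)[counts == max(counts)]
    victim <- sort(top)[1]
    removed <- c(removed, victim)
    over <- over[over$sample_a != victim & over$sample_b != victim, ]
  }
  removed
}

#' X-chromosome relatedness under full dosage compensation
#'
#' Computes IBD-segment relatedness on the X chromosome and rescales it by
#' pair sex: female-female pairs keep the autosomal formula, male-female
#' values are multiplied by 2 and male-male values by 4, reflecting that males
#' carry a single X haplotype under a full-dosage-compensation model (so less
#' IBD is detectable for pairs involving males).
#'
#' @param segs_x X-chromosome segment tibble.
#' @param map_x Marker map of the X chromosome.
#' @param sexes Named character vector (`"M"`/`"F"`, names = sample ids) or a
#'   tibble with columns `sample_id`, `sex`. Every sample must have a known
#'   sex.
#' @param track_x Optional X IBD-rate track; when given the weighted estimator
#'   is used with `threshold`, otherwise the unweighted one.
#' @param threshold Rate threshold for the weighted estimator.
#' @return A [relatedness_matrix()] with method `"x_chromosome"`; off-diagonal
#'   values can reach 2 for male-male pairs.
#' @examples
#' map_x <- marker_map(c(X = 100), 11)
#' segs <- tibble::tibble(sample_a = c("F1", "M1", "M1"),
#'                        sample_b = c("F2", "F3", "M2"),
#'                        chrom = "X", start_cm = 0, end_cm = 40)
#' sexes <- c(F1 = "F", F2 = "F", F3 = "F", M1 = "M", M2 = "M")
#' x_relatedness(segs, map_x, sexes)
#' @export
x_relatedness <- function(segs_x, map_x, sexes, track_x = NULL, threshold = 0) {
  if (is.data.frame(sexes)) {
    check_columns(sexes, c("sample_id", "sex"), "sexes")
    sexes <- setNames(sexes$sex, sexes$sample_id)
  }
  if (is.null(names(sexes))) abort("`sexes` must be named by sample id.")
  if (!all(sexes %in% c("M", "F"))) {
    abort(sprintf("Unknown sex for sample(s): %s.",
                  paste(head(names(sexes)[!sexes %in% c("M", "F")], 5),
                        collapse = ", ")))
  }
  samples <- names(sexes)
  base <- if (is.null(track_x)) {
    unweighted_relatedness(segs_x, map_x, samples = samples)
  } else {
    weighted_relatedness(segs_x, track_x, threshold, samples = samples)
  }
  male <- sexes == "M"
  mult <- outer(1 + male, 1 + male) # 1 FF, 2 MF, 4 MM
  out <- unclass(base) * mult
  diag(out) <- diag(base)
  relatedness_matrix(out, method = "x_chromosome")
}
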