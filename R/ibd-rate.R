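#' Compute the IBD detection-rate track
#'
#' For every inter-marker interval of the map, the IBD rate is the number of
#' sample pairs with a detected IBD segment spanning the interval entirely,
#' divided by the total number of pairs. The track drives the detection-rate
#' weighting of segment-based relatedness: intervals with high detection are
#' down-weighted and intervals with low detection up-weighted, while intervals
#' with extremely low rates are excluded by the threshold chosen with
#' [rate_threshold()].
#'
#' @param segs Segment tibble (`sample_a`, `sample_b`, `chrom`, `start_cm`,
#'   `end_cm`). Records are normalized with [merge_segments()] first (IBD has
#'   0-1 status per pair, so overlapping records must not double count).
#' @param map Marker map covering all segment coordinates.
#' @param n_pairs Number of sample pairs in the data set (>= 1). This is
#'   `choose(n, 2)` for the sample the segments were detected in; it cannot be
#'   inferred from `segs` because pairs without segments carry no record.
#' @return An `ibd_rate_track` tibble: `chrom`, `interval`, `start_cm`,
#'   `end_cm`, `length_cm`, `n_pairs_ibd`, `ir`.
#' @examples
#' map <- marker_map(100, 11)
#' segs <- tibble::tibble(sample_a = "S1", sample_b = "S2", chrom = "1",
#'                        start_cm = 20, end_cm = 70)
#' compute_ibd_rate(segs, map, n_pairs = 10)
#' @export
compute_ibd_rate <- function(segs, map, n_pairs) {
  check_columns(segs, c("sample_a", "sample_b", "chrom", "start_cm", "end_cm"), "segs")
  check_scalar_number(n_pairs, "n_pairs", lower = 1)
  ints <- map_intervals(map)
  counts <- interval_coverage_counts(merge_segments(segs), map, ints)
  out <- ints
  out$n_pairs_ibd <- counts
  out$ir <- counts / n_pairs
  class(out) <- c("ibd_rate_track", class(out))
  out
}

# Number of segments fully covering each interval, in map_intervals() row
# order. Errors on segments outside the map.
interval_coverage_counts <- function(segs, map, ints = map_intervals(map)) {
  counts <- integer(nrow(ints))
  if (!nrow(segs)) return(counts)
  chroms <- unique(map$chrom)
  bad <- !segs$chrom %in% chroms
  if (any(bad)) {
    abort(sprintf("Segment record %d lies on chromosome '%s' not in the map.",
                  which(bad)[1], segs$chrom[which(bad)[1]]))
  }
  offset <- cumsum(c(0L, tapply(ints$chrom, factor(ints$chrom, levels = chroms),
                                length)))[seq_along(chroms)]
  names(offset) <- chroms
  for (c_i in chroms) {
    sc <- segs[segs$chrom == c_i, ]
    if (!nrow(sc)) next
    pos <- map$cM[map$chrom == c_i]
    out_of_range <- sc$start_cm < pos[1] - 1e-9 |
      sc$end_cm > pos[length(pos)] + 1e-9
    if (any(out_of_range)) {
      i <- which(out_of_range)[1]
      abort(sprintf(
        "Segment %s-%s on chromosome %s [%g, %g] extends outside the map [%g, %g].",
        sc$sample_a[i], sc$sample_b[i], c_i, sc$start_cm[i], sc$end_cm[i],
        pos[1], pos[length(pos)]))
    }
    rng <- covered_interval_range(sc$start_cm, sc$end_cm, pos)
    ok <- rng$first <= rng$last
    if (!any(ok)) next
    # difference-array trick: +1 at first covered, -1 after last covered
    nloc <- length(pos) - 1L
    d <- integer(nloc + 1L)
    add <- tabulate(rng$first[ok], nbins = nloc)
    sub <- tabulate(rng$last[ok] + 1L, nbins = nloc + 1L)
    d[seq_len(nloc)] <- add
    d <- d - sub
    counts[offset[c_i] + seq_len(nloc)] <- cumsum(d[seq_len(nloc)])
  }
  counts
}

#' Threshold on the IBD rate by empirical percentile
#'
#' Returns the nearest-rank percentile of the interval IBD rates. Regions below
#' the threshold would receive extremely large weights in the weighted
#' relatedness estimator (weights are `1 / IR`), inflating its variance, so
#' they are excluded. The default in analyses is the 0.1th percentile of the
#' track, which keeps as much of the genome as reasonably possible; the 2nd
#' and 5th percentiles are common alternatives and typically change the
#' resulting heritability standard errors very little.
#'
#' @param track An `ibd_rate_track` from [compute_ibd_rate()].
#' @param percentile Percentile in `[0, 100]` (default 0.1).
#' @return The threshold value `T` (scalar).
#' @export
rate_threshold <- function(track, percentile = 0.1) {
  check_columns(track, "ir", "track")
  check_scalar_number(percentile, "percentile", lower = 0, upper = 100)
  if (!nrow(track)) abort("`track` has no intervals.")
  x <- sort(track$ir)
  rank <- max(1L, ceiling(percentile / 100 * length(x)))
  x[rank]
}

#' @export
print.ibd_rate_track <- function(x, ...) {
  cat(sprintf("<ibd_rate_track> %d intervals on %d chromosome(s), IR %.4g .. %.4g (median %.4g)\n",
              nrow(x), length(unique(x$chrom)), min(x$ir), max(x$ir), median(x$ir)))
  invisible(x)
}

#' Plot an IBD-rate track along the genome
#'
#' @param object An `ibd_rate_track`.
#' @param threshold Optional horizontal threshold line (e.g. from
#'   [rate_threshold()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ibd_rate_track
#' @export
autoplot.ibd_rate_track <- function(object, threshold = NULL, ...) {
  df <- dplyr::mutate(object, mid = (.data$start_cm + .data$end_cm) / 2)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$ir)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "IBD rate") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  }
  p
}
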