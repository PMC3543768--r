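#' Build an evenly spaced marker map
#'
#' Creates a genetic map with markers evenly spaced on each chromosome, the
#' first marker at 0 cM and the last at the chromosome's genetic length.
#' Physical positions are laid out at `bp_per_cM` base pairs per centimorgan,
#' so base-pair and genetic coordinates are interconvertible by linear
#' interpolation.
#'
#' @param chrom_lengths_cM Numeric vector of chromosome genetic lengths (cM).
#'   Names, if present, become chromosome identifiers; otherwise chromosomes
#'   are labelled `"1"`, `"2"`, ...
#' @param n_snps Total number of markers, allocated to chromosomes
#'   proportionally to genetic length (at least 2 per chromosome).
#' @param bp_per_cM Physical scale, base pairs per cM (default 1e6).
#' @return A tibble with columns `chrom`, `id`, `bp`, `cM`, one row per marker,
#'   `cM` strictly increasing within each chromosome.
#' @examples
#' marker_map(c(100, 80), n_snps = 50)
#' @export
marker_map <- function(chrom_lengths_cM, n_snps, bp_per_cM = 1e6) {
  stopifnot(is.numeric(chrom_lengths_cM), all(chrom_lengths_cM > 0))
  check_scalar_number(n_snps, "n_snps", lower = 2 * length(chrom_lengths_cM))
  chroms <- names(chrom_lengths_cM) %||% as.character(seq_along(chrom_lengths_cM))
  # proportional allocation, >= 2 markers per chromosome, exact total
  m <- pmax(2L, floor(n_snps * chrom_lengths_cM / sum(chrom_lengths_cM)))
  while (sum(m) < n_snps) {
    i <- which.max(chrom_lengths_cM / m)
    m[i] <- m[i] + 1L
  }
  while (sum(m) > n_snps) {
    i <- which(m > 2L)[which.min((chrom_lengths_cM / m)[m > 2L])]
    m[i] <- m[i] - 1L
  }
  purrr::map2_dfr(seq_along(chroms), m, function(c_i, m_c) {
    cm <- seq(0, chrom_lengths_cM[c_i], length.out = m_c)
    tibble::tibble(chrom = chroms[c_i],
                   id = sprintf("snp_%s_%05d", chroms[c_i], seq_len(m_c)),
                   bp = as.integer(round(cm * bp_per_cM)) + 1L,
                   cM = cm)
  })
}

#' Inter-marker intervals of a genetic map
#'
#' Relatedness weighting and IBD-rate computation operate on the half-open
#' intervals between adjacent markers on each chromosome (the interval after
#' the final marker of a chromosome does not exist). A segment is counted for
#' an interval only when it covers the interval entirely.
#'
#' @param map A marker map (see [marker_map()]).
#' @return A tibble with columns `chrom`, `interval` (index within chromosome),
#'   `start_cm`, `end_cm`, `length_cm`.
#' @export
map_intervals <- function(map) {
  check_columns(map, c("chrom", "cM"), "map")
  map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(interval = seq_len(dplyr::n() - 1L),
                   start_cm = head(.data$cM, -1L),
                   end_cm = tail(.data$cM, -1L)) |>
    dplyr::mutate(length_cm = .data$end_cm - .data$start_cm)
}

#' Genetic length of the genome covered by a map
#'
#' The genome length is the sum over chromosomes of the span from the first to
#' the last marker, i.e. the total length of the inter-marker intervals.
#'
#' @param map A marker map.
#' @return Genetic length in cM (scalar).
#' @export
genome_length_cM <- function(map) {
  check_columns(map, c("chrom", "cM"), "map")
  sum(tapply(map$cM, map$chrom, function(x) max(x) - min(x)))
}

## Interval coverage ----------------------------------------------------------

# Indices of the inter-marker intervals fully covered by [start, end) on one
# chromosome with marker positions `pos` (sorted). Returns (first, last) index
# pairs; first > last means no interval is fully covered. A small tolerance
# absorbs floating-point noise in positions that were generated on the grid.
covered_interval_range <- function(start, end, pos, tol = 1e-9) {
  first <- findInterval(start - tol, pos) + 1L
  last <- findInterval(end + tol, pos) - 1L
  list(first = first, last = pmin(last, length(pos) - 1L))
}

# Linear bp -> cM interpolation on one chromosome; positions outside the map
# are clamped to the map ends with a warning (handled by the caller).
interp_bp_to_cm <- function(bp, map_chrom) {
  stats::approx(map_chrom$bp, map_chrom$cM, xout = bp, rule = 2)$y
}
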