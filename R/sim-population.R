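#' Simulate a structured population with exactly known IBD segments
#'
#' Generates diploid genotypes for one or more subpopulations together with the
#' complete list of pairwise IBD segments that the genotypes realize, so that
#' segment-based relatedness estimators can be validated against exact truth.
#'
#' Subpopulation allele frequencies diverge from ancestral frequencies
#' (Uniform(0.05, 0.95)) under a Balding-Nichols model with parameter `fst`.
#' Within each subpopulation, every haplotype is a mosaic of subpopulation
#' founder haplotypes: founder switch points are exponentially distributed
#' (mean `2 * segment_mean_cM`) and snapped to the marker grid, and the founder
#' of each mosaic piece is drawn uniformly from the pool. Two haplotypes are
#' IBD exactly where they copy the same founder, so recorded IBD is
#' transitively closed and genotypes agree at every marker inside every
#' recorded segment. The founder pool size is `F = 4 * G / pair_ibd_mean_cM`
#' (G = genome cM), which makes the expected total IBD per within-subpopulation
#' pair approximately `pair_ibd_mean_cM` and the mean pairwise relatedness
#' `2 / F`. Founder pools of different subpopulations are disjoint, so
#' across-subpopulation pairs share no IBD and have true relatedness exactly 0.
#' `pair_ibd_mean_cM = 0` gives every haplotype a private founder (no sharing).
#' Matched stretches where both haplotypes of one individual copy the same
#' founder are recorded as homozygosity-by-descent (HBD).
#'
#' @param cfg A [sim_config()].
#' @return An object of class `population_sim`: a list with elements
#'   \describe{
#'     \item{samples}{tibble `sample_id`, `subpop`, `sex`.}
#'     \item{map}{marker map tibble (`chrom`, `id`, `bp`, `cM`).}
#'     \item{genotypes}{samples x SNPs dosage matrix (0/1/2), dimnames set.}
#'     \item{allele_freq}{named vector of sample reference-allele frequencies.}
#'     \item{freqs}{tibble of ancestral and per-subpopulation frequencies.}
#'     \item{true_ibd}{tibble `sample_a`, `sample_b`, `chrom`, `start_cm`,
#'       `end_cm` of merged true IBD segments (half-open, marker-aligned).}
#'     \item{true_hbd}{same format with `sample_a == sample_b`.}
#'     \item{true_inbreeding}{tibble `sample_id`, `f` (true HBD fraction).}
#'     \item{true_relatedness}{[relatedness_matrix] with off-diagonals
#'       `total true IBD cM / (2 * genome cM)` and diagonal `1 + f`.}
#'     \item{config}{the `sim_config` used.}
#'   }
#' @examples
#' cfg <- sim_config(n_subpops = 1, n_per_subpop = 20, fst = 0, n_snps = 200,
#'                   chrom_lengths_cM = 100, pair_ibd_mean_cM = 20, seed = 7)
#' pop <- simulate_structured_population(cfg)
#' pop$true_relatedness[1:3, 1:3]
#' @export
simulate_structured_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 4L)
  map <- marker_map(cfg$chrom_lengths_cM, cfg$n_snps)
  chroms <- unique(map$chrom)
  pos_by_chrom <- split(map$cM, factor(map$chrom, levels = chroms))
  m_by_chrom <- lengths(pos_by_chrom)
  chrom_offset <- c(0L, cumsum(m_by_chrom))
  chrom_last <- cumsum(m_by_chrom)
  m <- nrow(map)
  G <- genome_length_cM(map)
  n_k <- cfg$n_per_subpop
  n <- sum(n_k)
  sample_ids <- sprintf("S%0*d", max(4L, nchar(n)), seq_len(n))
  subpop_idx <- rep(seq_len(cfg$n_subpops), n_k)

  ## 1. allele frequencies (Balding-Nichols divergence)
  freqs <- withr::with_seed(seeds[1], {
    p_anc <- runif(m, 0.05, 0.95)
    p_sub <- matrix(p_anc, m, cfg$n_subpops)
    if (cfg$fst > 0) {
      s <- (1 - cfg$fst) / cfg$fst
      for (k in seq_len(cfg$n_subpops)) {
        p_sub[, k] <- rbeta(m, p_anc * s, (1 - p_anc) * s)
      }
      # rbeta can return exact 0/1 for extreme shapes; keep frequencies interior
      p_sub <- pmin(pmax(p_sub, 1e-6), 1 - 1e-6)
    }
    list(p_anc = p_anc, p_sub = p_sub)
  })

  ## 2. founder pool sizes and mosaic pieces (marker-index coordinates)
  hap_offset <- c(0L, cumsum(2L * n_k))
  sharing <- cfg$pair_ibd_mean_cM > 0
  founder_pool <- ifelse(sharing,
                         pmax(2L, as.integer(round(4 * G / pmax(cfg$pair_ibd_mean_cM, 1e-12)))),
                         2L * n_k)
  founder_offset <- c(0L, cumsum(founder_pool))
  switch_rate <- 1 / (2 * cfg$segment_mean_cM)
  pieces <- withr::with_seed(seeds[3], {
    tabs <- list()
    for (k in seq_len(cfg$n_subpops)) {
      H <- 2L * n_k[k]
      for (ci in seq_along(chroms)) {
        pos <- pos_by_chrom[[ci]]
        m_c <- length(pos)
        L_c <- pos[m_c]
        spacing <- L_c / (m_c - 1)
        sl <- el <- fl <- vector("list", H)
        for (h in seq_len(H)) {
          cuts <- hap_cut_positions(L_c, switch_rate)
          b <- sort(unique(pmin(pmax(as.integer(round(cuts / spacing)) + 1L, 2L), m_c)))
          sl[[h]] <- c(1L, b)
          el[[h]] <- c(b, m_c + 1L)
          fl[[h]] <- if (sharing[k]) {
            sample.int(founder_pool[k], length(b) + 1L, replace = TRUE)
          } else {
            rep(h, length(b) + 1L)
          }
        }
        np <- lengths(sl)
        tabs[[length(tabs) + 1L]] <- data.table::data.table(
          hap = rep(seq_len(H) + hap_offset[k], np),
          founder = unlist(fl) + founder_offset[k],
          gstart = unlist(sl) + chrom_offset[ci],
          gend = unlist(el) + chrom_offset[ci])
      }
    }
    data.table::rbindlist(tabs)
  })

  ## 3. founder haplotypes and genotype assembly
  genotypes <- withr::with_seed(seeds[2], {
    geno <- matrix(0L, n, m, dimnames = list(sample_ids, map$id))
    for (k in seq_len(cfg$n_subpops)) {
      Fk <- founder_pool[k]
      fh <- matrix(rbinom(Fk * m, 1L, rep(freqs$p_sub[, k], each = Fk)),
                   nrow = Fk)
      pk <- pieces[pieces$hap > hap_offset[k] & pieces$hap <= hap_offset[k + 1L], ]
      data.table::setorder(pk, hap, gstart)
      fidx <- rep(pk$founder - founder_offset[k], pk$gend - pk$gstart)
      snp_idx <- sequence(pk$gend - pk$gstart, from = pk$gstart)
      hapmat <- matrix(fh[cbind(fidx, snp_idx)], nrow = m)
      H <- 2L * n_k[k]
      gk <- hapmat[, seq(1L, H, by = 2L), drop = FALSE] +
        hapmat[, seq(2L, H, by = 2L), drop = FALSE]
      geno[hap_offset[k] / 2L + seq_len(n_k[k]), ] <- t(gk)
    }
    geno
  })

  ## 4. true IBD/HBD: overlaps of same-founder mosaic pieces
  snp_chrom <- rep(seq_along(chroms), m_by_chrom)
  segs <- founder_match_segments(pieces, snp_chrom)

  ## 5. convert marker-index ranges to cM coordinates
  posg <- map$cM
  end_pos <- c(posg[-1], 0)
  end_pos[chrom_last] <- posg[chrom_last]
  seg_tbl <- tibble::tibble(
    sample_a = sample_ids[segs$ind_a],
    sample_b = sample_ids[segs$ind_b],
    chrom = map$chrom[segs$u],
    start_cm = posg[segs$u],
    end_cm = end_pos[segs$v])
  seg_tbl <- seg_tbl[seg_tbl$end_cm > seg_tbl$start_cm, ]
  is_hbd <- seg_tbl$sample_a == seg_tbl$sample_b
  true_ibd <- seg_tbl[!is_hbd, ]
  true_hbd <- seg_tbl[is_hbd, ]

  ## 6. true relatedness matrix from recorded segments
  f_true <- setNames(numeric(n), sample_ids)
  if (nrow(true_hbd)) {
    fs <- tapply(true_hbd$end_cm - true_hbd$start_cm, true_hbd$sample_a, sum) / G
    f_true[names(fs)] <- fs
  }
  A <- matrix(0, n, n, dimnames = list(sample_ids, sample_ids))
  if (nrow(true_ibd)) {
    tot <- true_ibd |>
      dplyr::group_by(.data$sample_a, .data$sample_b) |>
      dplyr::summarise(cm = sum(.data$end_cm - .data$start_cm), .groups = "drop")
    ia <- match(tot$sample_a, sample_ids)
    ib <- match(tot$sample_b, sample_ids)
    A[cbind(ia, ib)] <- tot$cm / (2 * G)
    A[cbind(ib, ia)] <- tot$cm / (2 * G)
  }
  diag(A) <- 1 + f_true

  sexes <- withr::with_seed(seeds[4], sample(c("F", "M"), n, replace = TRUE))
  structure(
    list(samples = tibble::tibble(sample_id = sample_ids,
                                  subpop = paste0("P", subpop_idx),
                                  sex = sexes),
         map = map,
         genotypes = genotypes,
         allele_freq = colMeans(genotypes) / 2,
         freqs = tibble::as_tibble(
           cbind(tibble::tibble(id = map$id, ancestral = freqs$p_anc),
                 setNames(as.data.frame(freqs$p_sub),
                          paste0("P", seq_len(cfg$n_subpops))))),
         true_ibd = true_ibd,
         true_hbd = true_hbd,
         true_inbreeding = tibble::tibble(sample_id = sample_ids, f = unname(f_true)),
         true_relatedness = relatedness_matrix(A, method = "true_ibd"),
         founder_pool = founder_pool,
         config = cfg),
    class = "population_sim")
}

#' @export
print.population_sim <- function(x, ...) {
  cat("<population_sim>\n")
  cat(sprintf("  %d samples (%s), %d SNPs, genome %g cM\n",
              nrow(x$samples),
              paste(table(x$samples$subpop), collapse = "/"),
              nrow(x$map), genome_length_cM(x$map)))
  cat(sprintf("  %d true IBD segments, %d HBD segments\n",
              nrow(x$true_ibd), nrow(x$true_hbd)))
  off <- x$true_relatedness[upper.tri(x$true_relatedness)]
  cat(sprintf("  mean true relatedness %.4g\n", mean(off)))
  invisible(x)
}

# Exponentially spaced cut positions in (0, L).
hap_cut_positions <- function(L, rate) {
  cuts <- numeric(0)
  last <- 0
  chunk <- max(8L, ceiling(L * rate))
  while (last < L) {
    new <- last + cumsum(rexp(chunk, rate))
    cuts <- c(cuts, new)
    last <- cuts[length(cuts)]
  }
  cuts[cuts < L]
}

# All maximal marker-index ranges over which two haplotypes copy the same
# founder, merged per individual pair (0-1 IBD status). Input: data.table with
# hap, founder, gstart, gend (end exclusive, global marker indices) and the
# chromosome index of each global marker. Output: data.table with
# ind_a <= ind_b (individual indices), u, v (first/last shared marker).
founder_match_segments <- function(pieces, snp_chrom) {
  hap <- i.hap <- end_in <- gend <- NULL # data.table NSE
  dt <- data.table::copy(pieces)
  dt[, end_in := gend - 1L]
  data.table::setkey(dt, founder, gstart, end_in)
  ov <- data.table::foverlaps(dt, dt, type = "any")
  ov <- ov[hap < i.hap]
  if (!nrow(ov)) {
    return(data.table::data.table(ind_a = integer(), ind_b = integer(),
                                  u = integer(), v = integer()))
  }
  ha <- (ov$hap + 1L) %/% 2L
  hb <- (ov$i.hap + 1L) %/% 2L
  u <- pmax(ov$gstart, ov$i.gstart)
  seg <- data.table::data.table(
    ind_a = pmin(ha, hb),
    ind_b = pmax(ha, hb),
    chrom_i = snp_chrom[u],
    u = u,
    v = pmin(ov$end_in, ov$i.end_in))
  merge_marker_ranges(seg)
}

# Merge overlapping or abutting [u, v] marker ranges per pair per chromosome
# (abutting global ranges on *different* chromosomes must stay separate).
merge_marker_ranges <- function(seg) {
  ind_a <- ind_b <- chrom_i <- u <- v <- run_end <- block <- NULL # NSE
  data.table::setorder(seg, ind_a, ind_b, chrom_i, u, v)
  seg[, run_end := cummax(v), by = list(ind_a, ind_b, chrom_i)]
  prev_end <- data.table::shift(seg$run_end, 1L, fill = -2L)
  first_of_group <- !duplicated(seg[, list(ind_a, ind_b, chrom_i)])
  seg[, block := cumsum(first_of_group | u > prev_end + 1L)]
  out <- seg[, list(ind_a = ind_a[1L], ind_b = ind_b[1L],
                    u = min(u), v = max(v)),
             by = block]
  out[, list(ind_a, ind_b, u, v)]
}
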