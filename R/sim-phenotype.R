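#' Simulate an additive polygenic trait
#'
#' Draws `n_causal` causal SNPs uniformly without replacement from the
#' polymorphic SNPs of the sample and simulates
#' `y_j = sum_i alpha_i (x_ij - 2 p_i) + e_j`, where `x_ij` is the dosage of
#' individual `j` at causal SNP `i`, `p_i` is the *sample* reference-allele
#' frequency, `alpha_i = sqrt(per_snp_var / (2 p_i (1 - p_i)))` (see
#' [causal_effect()]) so every causal SNP contributes `per_snp_var` of trait
#' variance, and `e_j ~ Normal(0, env_var)`. SNPs that are monomorphic in the
#' sample are never selected (the effect size is undefined at `p in {0, 1}`).
#'
#' @param pop A [simulate_structured_population()] result.
#' @param cfg The [sim_config()] providing `n_causal`, `per_snp_var`,
#'   `env_var`; defaults to the one stored in `pop`.
#' @param seed Seed for this trait replicate (causal SNP choice and
#'   environmental noise). Defaults to the config's master seed; study drivers
#'   pass an independent sub-seed per replicate.
#' @param causal_pool Optional integer vector of SNP indices from which causal
#'   SNPs are drawn (default: all SNPs). Monomorphic SNPs are excluded from the
#'   pool either way. Used e.g. to confine causal variants to regions with
#'   degraded IBD detection.
#' @return An object of class `sim_trait`: list with `trait` (tibble
#'   `sample_id`, `value`), `genetic_values` (named vector), `causal` (tibble
#'   `snp`, `id`, `freq`, `effect`), and `true_h2`.
#' @examples
#' cfg <- sim_config(n_subpops = 1, n_per_subpop = 50, fst = 0, n_snps = 300,
#'                   chrom_lengths_cM = 100, pair_ibd_mean_cM = 10,
#'                   n_causal = 20, seed = 3)
#' pop <- simulate_structured_population(cfg)
#' tr <- simulate_phenotype(pop)
#' var(tr$trait$value)
#' @export
simulate_phenotype <- function(pop, cfg = pop$config, seed = cfg$seed,
                               causal_pool = NULL) {
  stopifnot(inherits(pop, "population_sim"), inherits(cfg, "sim_config"))
  p <- pop$allele_freq
  m <- length(p)
  pool <- causal_pool %||% seq_len(m)
  stopifnot(all(pool >= 1), all(pool <= m))
  pool <- pool[p[pool] > 0 & p[pool] < 1]
  if (length(pool) < cfg$n_causal) {
    abort(sprintf("Only %d polymorphic SNPs available for %d causal SNPs.",
                  length(pool), cfg$n_causal))
  }
  n <- nrow(pop$genotypes)
  withr::with_seed(as.integer(seed), {
    idx <- if (cfg$n_causal > 0) sort(sample(pool, cfg$n_causal)) else integer(0)
    e <- rnorm(n, 0, sqrt(cfg$env_var))
  })
  if (length(idx)) {
    alpha <- causal_effect(p[idx], cfg$per_snp_var)
    g <- as.vector(pop$genotypes[, idx, drop = FALSE] %*% alpha) -
      sum(2 * p[idx] * alpha)
  } else {
    alpha <- numeric(0)
    g <- numeric(n)
  }
  structure(
    list(trait = tibble::tibble(sample_id = pop$samples$sample_id,
                                value = g + e),
         genetic_values = setNames(g, pop$samples$sample_id),
         causal = tibble::tibble(snp = idx, id = pop$map$id[idx],
                                 freq = unname(p[idx]), effect = unname(alpha)),
         true_h2 = cfg$true_h2),
    class = "sim_trait")
}

#' @export
print.sim_trait <- function(x, ...) {
  cat(sprintf("<sim_trait> %d samples, %d causal SNPs, true h2 = %.3f, var(y) = %.3f\n",
              nrow(x$trait), nrow(x$causal), x$true_h2, var(x$trait$value)))
  invisible(x)
}

#' Thin and jitter IBD segments to emulate imperfect detection
#'
#' Real IBD detection misses segments at rates that vary along the genome and
#' misplaces segment endpoints. This utility turns a set of true segments into
#' "detected" segments: each segment is retained independently with the
#' detection probability of the region containing its midpoint, and retained
#' endpoints are perturbed by zero-mean Gaussian noise truncated to the
#' chromosome bounds.
#'
#' @param segs Segment tibble (`sample_a`, `sample_b`, `chrom`, `start_cm`,
#'   `end_cm`).
#' @param power Either a single detection probability in `[0, 1]` applied
#'   everywhere, or a tibble with columns `chrom`, `start_cm`, `end_cm`,
#'   `power` of non-overlapping regions (segments whose midpoint falls in no
#'   region get power 1).
#' @param map Marker map, used for chromosome bounds when jittering.
#' @param endpoint_jitter_cM Standard deviation of the endpoint noise (cM);
#'   0 leaves endpoints untouched.
#' @param seed Integer seed.
#' @return A segment tibble of the same shape; with `power = 1` everywhere and
#'   no jitter it equals the input.
#' @export
degrade_ibd_detection <- function(segs, power, map, endpoint_jitter_cM = 0,
                                  seed = 1L) {
  check_columns(segs, c("sample_a", "sample_b", "chrom", "start_cm", "end_cm"), "segs")
  check_scalar_number(endpoint_jitter_cM, "endpoint_jitter_cM", lower = 0)
  mid <- (segs$start_cm + segs$end_cm) / 2
  if (is.data.frame(power)) {
    check_columns(power, c("chrom", "start_cm", "end_cm", "power"), "power")
    stopifnot(all(power$power >= 0), all(power$power <= 1))
    pr <- rep(1, nrow(segs))
    for (r in seq_len(nrow(power))) {
      hit <- segs$chrom == power$chrom[r] &
        mid >= power$start_cm[r] & mid < power$end_cm[r]
      pr[hit] <- power$power[r]
    }
  } else {
    check_scalar_number(power, "power", lower = 0, upper = 1)
    pr <- rep(power, nrow(segs))
  }
  withr::with_seed(as.integer(seed), {
    keep <- runif(nrow(segs)) < pr
    out <- segs[keep, , drop = FALSE]
    if (endpoint_jitter_cM > 0 && nrow(out)) {
      lim <- tapply(map$cM, map$chrom, max)
      hi <- unname(lim[out$chrom])
      s <- pmin(pmax(out$start_cm + rnorm(nrow(out), 0, endpoint_jitter_cM), 0), hi)
      e <- pmin(pmax(out$end_cm + rnorm(nrow(out), 0, endpoint_jitter_cM), 0), hi)
      out$start_cm <- s
      out$end_cm <- e
      out <- out[out$end_cm > out$start_cm, , drop = FALSE]
    }
  })
  tibble::as_tibble(out)
}
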