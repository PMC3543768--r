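#' Configure a structured-population simulation
#'
#' Bundles the parameters of the synthetic cohort generator: a sample divided
#' into subpopulations whose allele frequencies diverge under a
#' Balding-Nichols model, within-subpopulation IBD sharing realized as
#' founder-haplotype mosaics, and an additive polygenic trait. The defaults are
#' the package's structured-study conditions: two subpopulations of 500, FST
#' 0.05, 5,000 markers on four 150 cM chromosomes, markedly different
#' within-subpopulation IBD levels (mean 36 vs 6 cM of shared segments per
#' pair, i.e. mean relatedness 0.03 vs 0.005), and a trait with 100 causal
#' SNPs each contributing 0.005 of variance plus environmental variance 0.5,
#' giving true narrow-sense heritability 0.5.
#'
#' @param n_subpops Number of subpopulations.
#' @param n_per_subpop Individuals per subpopulation (recycled to `n_subpops`).
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`; 0 collapses to
#'   a homogeneous population.
#' @param n_snps Total number of markers.
#' @param chrom_lengths_cM Chromosome genetic lengths in cM.
#' @param snp_spacing Optional mean cM between adjacent markers; when supplied,
#'   `n_snps` is derived as `sum(chrom_lengths_cM) / snp_spacing`.
#' @param pair_ibd_mean_cM Expected total detected-IBD length (cM) shared by a
#'   within-subpopulation pair (recycled to `n_subpops`). Mean pairwise
#'   relatedness within a subpopulation is `pair_ibd_mean_cM / (2 * genome cM)`.
#'   0 means no sharing.
#' @param segment_mean_cM Mean length of an individual IBD segment (cM).
#' @param n_causal Number of causal SNPs for the simulated trait.
#' @param per_snp_var Trait variance contributed by each causal SNP.
#' @param env_var Environmental (residual) trait variance.
#' @param seed Master seed; all randomness derives from it (see
#'   [derive_seeds()]).
#' @return An object of class `sim_config` (a validated named list) with the
#'   derived field `true_h2 = n_causal * per_snp_var /
#'   (n_causal * per_snp_var + env_var)`.
#' @examples
#' cfg <- sim_config(n_subpops = 1, n_per_subpop = 100, fst = 0,
#'                   n_snps = 500, chrom_lengths_cM = 100,
#'                   pair_ibd_mean_cM = 10)
#' cfg$true_h2
#' @export
sim_config <- function(n_subpops = 2,
                       n_per_subpop = 500,
                       fst = 0.05,
                       n_snps = 5000,
                       chrom_lengths_cM = rep(150, 4),
                       snp_spacing = NULL,
                       pair_ibd_mean_cM = c(36, 6),
                       segment_mean_cM = 3,
                       n_causal = 100,
                       per_snp_var = 0.005,
                       env_var = 0.5,
                       seed = 1L) {
  check_scalar_number(n_subpops, "n_subpops", lower = 1)
  check_scalar_number(fst, "fst", lower = 0, upper = 1 - 1e-12)
  check_scalar_number(segment_mean_cM, "segment_mean_cM", lower = 1e-12)
  check_scalar_number(n_causal, "n_causal", lower = 0)
  check_scalar_number(per_snp_var, "per_snp_var", lower = 0)
  check_scalar_number(env_var, "env_var", lower = 0)
  check_scalar_number(seed, "seed", lower = 1)
  stopifnot(is.numeric(chrom_lengths_cM), all(chrom_lengths_cM > 0))
  if (!is.null(snp_spacing)) {
    check_scalar_number(snp_spacing, "snp_spacing", lower = 1e-12)
    n_snps <- max(2 * length(chrom_lengths_cM),
                  round(sum(chrom_lengths_cM) / snp_spacing))
  }
  check_scalar_number(n_snps, "n_snps", lower = 2 * length(chrom_lengths_cM))
  n_per_subpop <- as.integer(rep_len(n_per_subpop, n_subpops))
  pair_ibd_mean_cM <- rep_len(pair_ibd_mean_cM, n_subpops)
  stopifnot(all(n_per_subpop >= 1), all(pair_ibd_mean_cM >= 0))
  genetic_var <- n_causal * per_snp_var
  if (genetic_var + env_var <= 0) {
    abort("Total trait variance `n_causal * per_snp_var + env_var` must be positive.")
  }
  structure(
    list(n_subpops = as.integer(n_subpops),
         n_per_subpop = n_per_subpop,
         fst = fst,
         n_snps = as.integer(n_snps),
         chrom_lengths_cM = chrom_lengths_cM,
         pair_ibd_mean_cM = pair_ibd_mean_cM,
         segment_mean_cM = segment_mean_cM,
         n_causal = as.integer(n_causal),
         per_snp_var = per_snp_var,
         env_var = env_var,
         seed = as.integer(seed),
         true_h2 = genetic_var / (genetic_var + env_var)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subpopulation(s) of %s individuals, FST = %g\n",
              x$n_subpops, paste(x$n_per_subpop, collapse = "/"), x$fst))
  cat(sprintf("  %d SNPs on %d chromosome(s), genome %g cM\n",
              x$n_snps, length(x$chrom_lengths_cM), sum(x$chrom_lengths_cM)))
  cat(sprintf("  mean pair IBD %s cM, segment mean %g cM\n",
              paste(x$pair_ibd_mean_cM, collapse = "/"), x$segment_mean_cM))
  cat(sprintf("  trait: %d causal SNPs x %g + env %g => true h2 = %.3f\n",
              x$n_causal, x$per_snp_var, x$env_var, x$true_h2))
  invisible(x)
}

#' Effect size of a causal SNP
#'
#' The additive trait model assigns each causal SNP `i` the effect
#' `alpha_i = sqrt(per_snp_var / (2 p_i (1 - p_i)))`, so that under
#' Hardy-Weinberg dosage variance `2 p_i (1 - p_i)` the SNP contributes exactly
#' `per_snp_var` to the trait variance. With the default `per_snp_var = 0.005`
#' this is `(400 p_i (1 - p_i))^(-1/2)`.
#'
#' @param p Reference allele frequency (strictly inside (0, 1)).
#' @param per_snp_var Variance contributed by the SNP.
#' @return The effect size `alpha`.
#' @examples
#' causal_effect(0.5) # 0.1
#' @export
causal_effect <- function(p, per_snp_var = 0.005) {
  stopifnot(all(p > 0 & p < 1))
  sqrt(per_snp_var / (2 * p * (1 - p)))
}
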