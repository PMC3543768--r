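# ibdherit

Narrow-sense heritability estimation from detected identity-by-descent (IBD)
segments in population samples — for statistical geneticists working with
founder-population cohorts where nominally unrelated individuals share
detectable IBD, and for anyone studying how relatedness estimators behave
under population structure.

In a population sample, the relatedness of a pair \(j,k\) can be estimated
from the genetic length of their detected IBD segments. Because segment
detection rates vary along the genome, `ibdherit` weights each inter-marker
interval by its inverse IBD rate:

```
               Σᵢ 1{IRᵢ > T} · IBD(j,k,i) · Lᵢ / IRᵢ
R_IBD(j,k) =  ───────────────────────────────────────
               Σᵢ 2 · 1{IRᵢ > T} · Lᵢ / IRᵢ
```

where `IRᵢ` is the proportion of pairs with a segment spanning interval `i`,
`Lᵢ` the interval's genetic length, and `T` a low-rate exclusion threshold
(default: the 0.1th percentile of the track). Heritability is then estimated
two ways:

* **Variance components (REML)** — `y = Xβ + g + ε`, `Var(g) = σ²g A`,
  `Var(ε) = σ²ε I`, with `h² = σ²g / (σ²g + σ²ε)` and a boundary-mixture
  (½χ²₀ + ½χ²₁) likelihood-ratio test;
* **Pairwise-product regression (Zuk-style)** — products of standardized
  trait values regressed on relatedness over a restricted range; `h²` is the
  slope × (1 − mean kinship), clipped to [0, 1].

The package also provides the GCTA-style allele-sharing relatedness matrix,
PCA with 3×IQR outlier removal, trait preparation (log transforms, covariate
and PC adjustment, 4 SD truncation), greedy close-relative exclusion,
X-chromosome relatedness under full dosage compensation, and a
structured-population simulator whose genotypes come with *exactly known*
true IBD segments (founder-haplotype mosaics under a Balding–Nichols model).
Its central reproducible result: with trait heritability 0.5, the IBD-based
variance-component estimator is unbiased on a structured population while the
regression estimator is strongly biased downward — and unbiased again once
structure is removed. See `vignettes/ibd-heritability.Rmd` for the models,
defaults and design choices.

## Worked example

Simulate a two-subpopulation cohort, build the weighted IBD relatedness
matrix, and estimate heritability both ways for one simulated trait:

```r
library(ibdherit)

cfg <- sim_config(n_subpops = 2, n_per_subpop = 150, fst = 0.05,
                  n_snps = 1500, chrom_lengths_cM = c(150, 150),
                  pair_ibd_mean_cM = c(30, 8), seed = 7)
pop <- simulate_structured_population(cfg)
pop
#> <population_sim>
#>   300 samples (150/150), 1500 SNPs, genome 300 cM
#>   126718 true IBD segments, 431 HBD segments
#>   mean true relatedness 0.01532

track <- compute_ibd_rate(pop$true_ibd, pop$map, n_pairs = choose(300, 2))
A <- weighted_relatedness(pop$true_ibd, track, rate_threshold(track, 0.1),
                          samples = pop$samples$sample_id,
                          hbd = pop$true_hbd, map = pop$map)
A
#> <relatedness_matrix> 300 samples, method 'ibd_weighted'
#>   off-diagonal mean 0.01531 (range 0 .. 0.1483), mean diagonal 1.015

adj <- pca_adjustment(pop$genotypes, k = 20)      # PCs + 3xIQR outlier removal
trait <- simulate_phenotype(pop, cfg, seed = 99)  # additive trait, true h2 = 0.5
y <- setNames(trait$trait$value, trait$trait$sample_id)[adj$samples]
Ak <- relatedness_matrix(unclass(A)[adj$samples, adj$samples], "ibd_weighted")

fit <- fit_reml(y, Ak, X = adj$pcs$vectors)
glance(fit)
#>      h2 se_h2 sigma_g2 sigma_e2 loglik loglik_null   lrt p_value     n
#> 1 0.807 0.396    0.880    0.211  -402.       -403.  3.76  0.0262   297

z <- prepare_trait(y, pcs = adj$pcs$vectors)      # adjust, truncate, standardize
zuk_estimate(pair_products(setNames(z, adj$samples)), Ak)
#> <zuk_fit> h2 = 0.000 [clipped] (slope -0.812, se 0.657, p = 0.216)
#>   34422 pairs with relatedness in [0, 0.03028]; mean relatedness 0.01514
```

A single replicate of a 300-sample cohort is noisy (note the REML standard
error of 0.40); the systematic picture appears over replicates. The study
driver redraws the trait many times over one population and applies the full
exclusion pipeline:

```r
st <- run_simulation_study(structured_study_config(seed = 1), n_reps = 50,
                           methods = c("ibd_vc", "zuk"), seed = 101)
st
#> <study_summary> true h2 = 0.500, 50 replicates, seed 101
#>   990 analyzed samples (0 relatives, 10 PC outliers removed); IR threshold 0.01634
#>  method mean_h2 sd_h2 se_mean mean_reported_se frac_clipped n_reps
#>  ibd_vc  0.5297 0.205  0.0289            0.233         0.02     50
#>     zuk  0.0421 0.128  0.0181            0.414         0.82     50
```

At true h² = 0.5, the IBD variance-component mean (0.530 ± 0.029) covers the
truth, while the regression estimator collapses to 0.04: the two
subpopulations differ in average relatedness, across-group pairs share no
IBD, and the pooled product-vs-relatedness line is far flatter than the
within-group lines. `autoplot(st)` draws the estimate distributions;
`run_homogeneous_control()` shows the regression estimator unbiased without
structure, and `run_detection_bias_study()` shows why the inverse-rate
weighting matters when causal variants sit in poorly detected regions.

## File formats

Refined-IBD-style segment tables (8-column or minimal 5-column TSV), PLINK
4-column MAP files, GCTA-style text GRMs (`.grm` triplets + `.grm.id`),
square relatedness TSVs, samples × SNPs dosage TSVs, GT-only VCF, and trait
TSVs — see `read_ibd_segments()`, `read_map()`, `read_grm()`,
`read_dosage_tsv()`, `read_vcf()` and their `write_*` counterparts.
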