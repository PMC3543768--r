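test_that("sim_config validates and derives true h2", {
  cfg <- sim_config(n_causal = 100, per_snp_var = 0.005, env_var = 0.5)
  expect_equal(cfg$true_h2, 0.5)
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(n_causal = 0, env_var = 0), "variance")
  expect_equal(sim_config(pair_ibd_mean_cM = 5)$pair_ibd_mean_cM, c(5, 5))
})

test_that("causal effect sizes give the stated per-SNP variance", {
  expect_equal(causal_effect(0.5), 0.1) # (400 * 0.25)^(-1/2)
  for (p in c(0.1, 0.25, 0.5, 0.9)) {
    a <- causal_effect(p, 0.005)
    expect_equal(a, (400 * p * (1 - p))^(-1/2))
    expect_equal(a^2 * 2 * p * (1 - p), 0.005)
  }
  expect_error(causal_effect(0), "p >")
})

pop <- tiny_pop(seed = 42)

test_that("recorded true relatedness equals direct segment summation", {
  G <- genome_length_cM(pop$map)
  tot <- pop$true_ibd |>
    dplyr::group_by(sample_a, sample_b) |>
    dplyr::summarise(cm = sum(end_cm - start_cm), .groups = "drop")
  for (i in seq_len(nrow(tot))) {
    expect_equal(pop$true_relatedness[tot$sample_a[i], tot$sample_b[i]],
                 tot$cm[i] / (2 * G))
  }
  # pairs without records are exactly zero
  A <- unclass(pop$true_relatedness)
  n_nonzero <- sum(A[upper.tri(A)] > 0)
  expect_equal(n_nonzero, nrow(tot))
})

test_that("genotypes are consistent with every recorded IBD segment", {
  # a shared haplotype forbids opposite homozygotes anywhere in the segment
  segs <- pop$true_ibd
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    idx <- pop$map$chrom == s$chrom &
      pop$map$cM >= s$start_cm - 1e-9 & pop$map$cM < s$end_cm - 1e-9
    ga <- pop$genotypes[s$sample_a, idx]
    gb <- pop$genotypes[s$sample_b, idx]
    expect_true(all(abs(ga - gb) <= 1))
  }
  # within HBD segments the individual is fully homozygous
  for (i in seq_len(nrow(pop$true_hbd))) {
    s <- pop$true_hbd[i, ]
    idx <- pop$map$chrom == s$chrom &
      pop$map$cM >= s$start_cm - 1e-9 & pop$map$cM < s$end_cm - 1e-9
    expect_true(all(pop$genotypes[s$sample_a, idx] %in% c(0, 2)))
  }
})

test_that("sharing levels match the configuration", {
  # pair_ibd_mean_cM = 0: no off-diagonal sharing at all
  p0 <- simulate_structured_population(
    sim_config(n_subpops = 1, n_per_subpop = 15, fst = 0, n_snps = 100,
               chrom_lengths_cM = 100, pair_ibd_mean_cM = 0, seed = 1))
  expect_equal(nrow(p0$true_ibd), 0)
  expect_true(all(p0$true_relatedness[upper.tri(p0$true_relatedness)] == 0))

  # across-subpopulation pairs share exactly zero
  p2 <- simulate_structured_population(
    sim_config(n_subpops = 2, n_per_subpop = 20, fst = 0.1, n_snps = 200,
               chrom_lengths_cM = 100, pair_ibd_mean_cM = c(30, 10), seed = 2))
  across <- unclass(p2$true_relatedness)[1:20, 21:40]
  expect_true(all(across == 0))

  # full-genome sharing: relatedness approaches 0.5 (union-merging keeps it
  # a little below), and equals the direct segment sum exactly (checked above)
  pf <- simulate_structured_population(
    sim_config(n_subpops = 1, n_per_subpop = 20, fst = 0, n_snps = 200,
               chrom_lengths_cM = 100, pair_ibd_mean_cM = 100,
               segment_mean_cM = 10, seed = 3))
  off <- unclass(pf$true_relatedness)[upper.tri(pf$true_relatedness)]
  expect_gt(mean(off), 0.3)
  expect_lt(mean(off), 0.5 + 1e-9)
})

test_that("subpopulation frequencies are centred on ancestral frequencies", {
  cfg <- sim_config(n_subpops = 2, n_per_subpop = 10, fst = 0.1, n_snps = 2000,
                    chrom_lengths_cM = c(100, 100), pair_ibd_mean_cM = 5,
                    seed = 9)
  p <- simulate_structured_population(cfg)
  d <- rowMeans(as.matrix(p$freqs[, c("P1", "P2")])) - p$freqs$ancestral
  # mean deviation over SNPs within 3 SE of zero
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  # per-SNP Balding-Nichols variance is fst * p(1-p): compare aggregates
  expect_equal(var(d) * 2, mean(cfg$fst * p$freqs$ancestral * (1 - p$freqs$ancestral)),
               tolerance = 0.15)
})

test_that("phenotype model follows the stated additive law", {
  cfg <- pop$config
  tr <- simulate_phenotype(pop, cfg, seed = 7)
  expect_equal(nrow(tr$trait), nrow(pop$samples))
  # effects match alpha_i = sqrt(v / (2 p (1-p))) at the sample frequency
  expect_equal(tr$causal$effect,
               causal_effect(tr$causal$freq, cfg$per_snp_var))
  # genetic values recompute from genotypes and effects
  g <- as.vector(pop$genotypes[, tr$causal$snp] %*% tr$causal$effect) -
    sum(2 * tr$causal$freq * tr$causal$effect)
  expect_equal(unname(tr$genetic_values), g)
  # bit reproducibility
  tr2 <- simulate_phenotype(pop, cfg, seed = 7)
  expect_identical(tr$trait$value, tr2$trait$value)
  # a different seed redraws the causal set
  tr3 <- simulate_phenotype(pop, cfg, seed = 8)
  expect_false(identical(tr$causal$snp, tr3$causal$snp))
})

test_that("n_causal = 0 gives pure environmental noise", {
  cfg0 <- sim_config(n_subpops = 1, n_per_subpop = 40, fst = 0, n_snps = 300,
                     chrom_lengths_cM = c(80, 70), pair_ibd_mean_cM = 20,
                     n_causal = 0, env_var = 0.5, seed = 42)
  tr <- simulate_phenotype(pop, cfg0, seed = 5)
  expect_true(all(tr$genetic_values == 0))
  expect_equal(var(tr$trait$value), 0.5, tolerance = 0.25)
})

test_that("empirical heritability matches the configured true h2", {
  big <- simulate_structured_population(
    sim_config(n_subpops = 1, n_per_subpop = 400, fst = 0, n_snps = 1000,
               chrom_lengths_cM = c(150, 150), pair_ibd_mean_cM = 10,
               n_causal = 100, seed = 21))
  seeds <- derive_seeds(22, 200)
  ratio <- vapply(seeds, function(s) {
    tr <- simulate_phenotype(big, big$config, seed = s)
    var(tr$genetic_values) / var(tr$trait$value)
  }, numeric(1))
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - big$config$true_h2), 3 * se)
})

test_that("degrade_ibd_detection thins and jitters as specified", {
  map <- pop$map
  segs <- pop$true_ibd
  # power 1, no jitter: identity
  expect_equal(degrade_ibd_detection(segs, 1, map, 0, seed = 1), segs)
  # power 0: empty set
  expect_equal(nrow(degrade_ibd_detection(segs, 0, map, 0, seed = 1)), 0)
  # power 0.5 on 10,000 synthetic segments: binomial retention within 3 sigma
  many <- seg(rep("A", 10000), rep("B", 10000), "1",
              rep(0, 10000), rep(1, 10000))
  kept <- nrow(degrade_ibd_detection(many, 0.5, tiny_map(), 0, seed = 3))
  expect_lt(abs(kept - 5000), 3 * sqrt(10000 * 0.25))
  # regional power: only segments with midpoint in the region are thinned
  reg <- tibble::tibble(chrom = "1", start_cm = 0, end_cm = 81, power = 0)
  out <- degrade_ibd_detection(pop$true_ibd, reg, map, 0, seed = 4)
  expect_true(all(out$chrom == "2"))
  # jitter stays within chromosome bounds and keeps start < end
  out2 <- degrade_ibd_detection(segs, 1, map, endpoint_jitter_cM = 2, seed = 5)
  lim <- tapply(map$cM, map$chrom, max)
  expect_true(all(out2$start_cm >= 0 & out2$end_cm <= lim[out2$chrom] + 1e-9))
  expect_true(all(out2$end_cm > out2$start_cm))
})

test_that("simulation is reproducible from the master seed", {
  p1 <- tiny_pop(seed = 13)
  p2 <- tiny_pop(seed = 13)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$true_ibd, p2$true_ibd)
  p3 <- tiny_pop(seed = 14)
  expect_false(identical(p1$genotypes, p3$genotypes))
})
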