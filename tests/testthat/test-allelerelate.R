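test_that("grm matches hand-evaluated allele-sharing terms", {
  # two samples, one informative SNP at p = 0.5 plus a filler SNP
  g <- rbind(S1 = c(2, 1), S2 = c(0, 1))
  A <- grm(g)
  # SNP1: (2-1)(0-1)/0.5 = -2; SNP2: (1-1)^2 terms = 0 -> mean = -1
  expect_equal(A["S1", "S2"], -1)
  # both heterozygous at p = 0.5 contributes 0
  g2 <- rbind(S1 = c(1, 2), S2 = c(1, 0))
  expect_equal(grm(g2)["S1", "S2"], -1) # SNP1: 0, SNP2: -2 -> mean -1
  # diagonal: 1 + f_hat with f_hat = (x^2 - (1+2p)x + 2p^2) / (2p(1-p))
  x <- c(2, 1); p <- c(0.5, 0.5)
  fhat <- mean((x^2 - (1 + 2 * p) * x + 2 * p^2) / (2 * p * (1 - p)))
  expect_equal(A["S1", "S1"], 1 + fhat)
  # monomorphic SNPs dropped with a warning
  g3 <- cbind(g, mono = c(2, 2))
  expect_warning(A3 <- grm(g3), "monomorphic")
  expect_equal(bare(A3), bare(A))
})

test_that("grm handles missing dosages pairwise", {
  g <- rbind(S1 = c(2, 1, 0, NA), S2 = c(0, 1, NA, 2), S3 = c(1, 0, 2, 1))
  A <- grm(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  z <- sweep(g, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = 3)
  manual <- function(j, k) {
    ok <- !is.na(z[j, ]) & !is.na(z[k, ])
    sum(z[j, ok] * z[k, ok]) / sum(ok)
  }
  expect_equal(A["S1", "S2"], manual(1, 2))
  expect_equal(A["S1", "S3"], manual(1, 3))
  expect_error(grm(rbind(S1 = c(NA, NA), S2 = c(1, 0))), "all-missing")
})

test_that("grm is symmetric with centring identity on homogeneous data", {
  pop <- tiny_pop(seed = 51, n = 60, n_snps = 400, pair_ibd = 5)
  A <- grm(pop$genotypes)
  expect_lt(max(abs(unclass(A) - t(unclass(A)))), 1e-12)
  off <- unclass(A)[upper.tri(A)]
  n <- nrow(A)
  expect_lt(abs(mean(off) - (-1 / (n - 1))), 5 / sqrt(ncol(pop$genotypes)))
})

test_that("unrelated pairs have near-zero allele-sharing relatedness", {
  pop <- simulate_structured_population(
    sim_config(n_subpops = 1, n_per_subpop = 200, fst = 0, n_snps = 10000,
               chrom_lengths_cM = c(100, 100), pair_ibd_mean_cM = 0, seed = 6))
  A <- grm(pop$genotypes)
  # spot-check 500 pairs: sampling bound 4/sqrt(N) around the centring
  # offset -1/(n-1)
  withr::with_seed(1, idx <- cbind(sample(200, 500, TRUE), sample(200, 500, TRUE)))
  idx <- idx[idx[, 1] < idx[, 2], ]
  off <- unclass(A)[idx]
  expect_true(all(abs(off + 1 / (nrow(A) - 1)) < 4 / sqrt(ncol(pop$genotypes))))
})

test_that("pca separates subpopulations and is deterministic", {
  pop <- simulate_structured_population(
    sim_config(n_subpops = 2, n_per_subpop = 30, fst = 0.1, n_snps = 800,
               chrom_lengths_cM = c(100, 100), pair_ibd_mean_cM = 5, seed = 8))
  pcs <- pca(pop$genotypes, k = 5)
  pc1 <- split(pcs$vectors[, 1], pop$samples$subpop)
  # zero overlap between subpopulation PC1 ranges
  expect_true(max(pc1$P1) < min(pc1$P2) || max(pc1$P2) < min(pc1$P1))
  expect_true(all(diff(pcs$values) <= 1e-12))
  # orthonormal within tolerance
  expect_lt(max(abs(crossprod(pcs$vectors) - diag(5))), 1e-8)
  # deterministic, including the sign convention
  expect_identical(pcs$vectors, pca(pop$genotypes, k = 5)$vectors)
  expect_true(all(apply(pcs$vectors, 2, function(v) v[which.max(abs(v))] > 0)))
  # duplicated sample -> identical eigenvector rows
  g2 <- rbind(pop$genotypes, DUP = pop$genotypes[1, ])
  p2 <- pca(g2, k = 3)
  expect_equal(p2$vectors["DUP", ], p2$vectors[1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("pca caps k at the available rank with a warning", {
  # duplicated / complementary SNP columns: standardized rank is 1
  g <- rbind(S1 = c(2, 0, 2), S2 = c(0, 2, 0), S3 = c(1, 1, 1),
             S4 = c(2, 0, 2))
  expect_warning(p <- pca(g, k = 3), "rank")
  expect_lt(p$k, 3)
  expect_error(pca(g, k = 10), "exceeds")
})

test_that("pc_outliers flags by the median +/- multiplier * IQR rule", {
  # all samples identical: IQR = 0 on every axis -> nobody flagged
  vec <- matrix(1 / sqrt(10), 10, 2,
                dimnames = list(sprintf("S%02d", 1:10), c("PC1", "PC2")))
  pcs0 <- structure(list(vectors = vec, values = c(2, 1), k = 2L),
                    class = "pc_result")
  expect_length(pc_outliers(pcs0), 0)
  # planted outlier at median + 10 IQR on PC3
  set.seed(4)
  v <- cbind(PC1 = rnorm(50), PC2 = rnorm(50), PC3 = rnorm(50))
  v[7, "PC3"] <- median(v[, "PC3"]) + 10 * IQR(v[, "PC3"])
  rownames(v) <- sprintf("S%02d", 1:50)
  pcs <- structure(list(vectors = v, values = c(3, 2, 1), k = 3L),
                   class = "pc_result")
  expect_true("S07" %in% pc_outliers(pcs, multiplier = 3))
  # scanning only the first 2 components misses it
  expect_false("S07" %in% pc_outliers(pcs, k = 2, multiplier = 3))
})

test_that("pc outlier rate on homogeneous data is near the nominal rate", {
  pop <- simulate_structured_population(
    sim_config(n_subpops = 1, n_per_subpop = 150, fst = 0, n_snps = 1000,
               chrom_lengths_cM = c(100, 100), pair_ibd_mean_cM = 4, seed = 12))
  adj <- pca_adjustment(pop$genotypes, k = 20)
  # 3 x IQR under near-normal loadings flags ~1e-4 per test; with 150 x 20
  # tests expect a handful at most, and no systematic removal
  expect_lt(length(adj$outliers), 0.05 * nrow(pop$samples))
})
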