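std <- function(x) (x - mean(x)) / sd(x)

test_that("pair_products enumerates unordered pairs", {
  pp <- suppressWarnings(pair_products(c(S1 = -1, S2 = 0, S3 = 1)))
  expect_equal(nrow(pp), 3)
  expect_equal(pp$product, c(-1 * 0, -1 * 1, 0 * 1))
  # z identically zero: all products zero (and a standardization warning)
  expect_warning(p0 <- pair_products(rep(0, 4)), "standardized")
  expect_true(all(p0$product == 0))
  # products match direct multiplication on a random fixture
  withr::with_seed(1, z <- std(rnorm(12)))
  names(z) <- sprintf("S%02d", 1:12)
  pp2 <- pair_products(z)
  expect_equal(pp2$product, z[pp2$sample_a] * z[pp2$sample_b],
               ignore_attr = TRUE)
  expect_equal(nrow(pp2), choose(12, 2))
})

# A synthetic relatedness matrix plus products with a known regression law.
synthetic_A <- function(n, seed, mean_rel = 0.02, sd_rel = 0.008) {
  withr::with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n))
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    r <- pmax(rnorm(choose(n, 2), mean_rel, sd_rel), 0)
    A[upper.tri(A)] <- r
    A <- A + t(A)
    diag(A) <- 1
    relatedness_matrix(A, "synthetic")
  })
}

test_that("zuk slope equals closed-form OLS and the lm oracle exactly", {
  n <- 40
  A <- synthetic_A(n, seed = 2)
  withr::with_seed(3, z <- std(rnorm(n)))
  names(z) <- rownames(A)
  pp <- pair_products(z)
  fit <- zuk_estimate(pp, A)
  # independent oracle: stats::lm on the same restricted pairs
  rel <- unclass(A)[cbind(match(pp$sample_a, rownames(A)),
                          match(pp$sample_b, rownames(A)))]
  keep <- rel >= fit$range["lo"] & rel <= fit$range["hi"]
  ofit <- lm(pp$product[keep] ~ rel[keep])
  expect_equal(fit$slope, unname(coef(ofit)[2]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(coef(ofit)[1]), tolerance = 1e-12)
  sm <- summary(ofit)$coefficients
  expect_equal(fit$se_slope, sm[2, 2], tolerance = 1e-12)
  expect_equal(fit$p_value, sm[2, 4], tolerance = 1e-12)
  expect_equal(fit$n_pairs, sum(keep))
  # h2 = slope * (1 - mean kinship), kinship = mean relatedness / 2
  expect_equal(fit$mean_kinship, mean(rel) / 2)
  expect_equal(fit$h2_raw, fit$slope * (1 - fit$mean_kinship))
})

test_that("degenerate product sets are handled as specified", {
  A <- synthetic_A(10, seed = 4)
  pp <- suppressWarnings(pair_products(rep(0, 10)))
  pp$sample_a <- rownames(A)[t(combn(10, 2))[, 1]]
  pp$sample_b <- rownames(A)[t(combn(10, 2))[, 2]]
  # constant products: slope 0 -> h2 = 0
  fit <- zuk_estimate(pp, A)
  expect_equal(fit$slope, 0)
  expect_equal(fit$h2, 0)
  # engineered negative slope clips to 0
  rel <- unclass(A)[cbind(match(pp$sample_a, rownames(A)),
                          match(pp$sample_b, rownames(A)))]
  pp$product <- -5 * rel
  fit2 <- zuk_estimate(pp, A)
  expect_lt(fit2$h2_raw, 0)
  expect_equal(fit2$h2, 0)
  expect_true(fit2$clipped)
  # a large positive slope clips to 1
  pp$product <- 100 * rel
  expect_equal(zuk_estimate(pp, A)$h2, 1)
  # too few pairs in range / zero variance errors
  expect_error(zuk_estimate(pp[1:2, ], A), "Fewer than 3")
  cA <- unclass(A); cA[upper.tri(cA)] <- 0.02; cA[lower.tri(cA)] <- 0.02
  expect_error(zuk_estimate(pp, relatedness_matrix(cA, "c")),
               "Zero relatedness variance")
})

test_that("estimator recovers h2 from products generated by the additive law", {
  # products = h2 * relatedness + independent noise (the regression identity)
  A <- synthetic_A(60, seed = 6)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  rel <- unclass(A)[ut]
  h2 <- 0.5
  ests <- vapply(derive_seeds(7, 150), function(s) {
    withr::with_seed(s, prod <- h2 * rel + rnorm(length(rel), sd = 0.05))
    pp <- tibble::tibble(sample_a = rownames(A)[ut[, 1]],
                         sample_b = rownames(A)[ut[, 2]], product = prod)
    zuk_estimate(pp, A)$h2
  }, numeric(1))
  expect_lt(abs(mean(ests) - h2), 2 * sd(ests) / sqrt(length(ests)))
})

test_that("relabeling samples leaves the estimate unchanged", {
  A <- synthetic_A(30, seed = 8)
  withr::with_seed(9, z <- std(rnorm(30)))
  names(z) <- rownames(A)
  f1 <- zuk_estimate(pair_products(z), A)
  new <- sprintf("X%03d", sample(30))
  A2 <- unclass(A)
  dimnames(A2) <- list(new, new)
  z2 <- setNames(z, new)
  f2 <- zuk_estimate(pair_products(z2), relatedness_matrix(A2, "synthetic"))
  expect_equal(f1$h2, f2$h2)
  expect_equal(f1$slope, f2$slope)
})

test_that("two groups with unequal relatedness attenuate the pooled slope", {
  # Within-group product clouds each follow slope h2 through their own group
  # mean relatedness; across-group pairs sit at zero relatedness with zero
  # expected product. Pooling the clouds flattens the fitted line.
  h2 <- 0.5
  withr::with_seed(10, {
    r <- c(rep(c(0.028, 0.030, 0.032), 1000),   # high-sharing group
           rep(c(0.003, 0.005, 0.007), 1000),   # low-sharing group
           rep(0, 3000))                        # across-group pairs
    m <- c(rep(0.030, 3000), rep(0.005, 3000), rep(0, 3000))
    prod <- h2 * (r - m) + rnorm(length(r), 0, 0.01)
  })
  keep <- r >= 0 & r <= 2 * mean(r) # excludes the high-sharing cloud
  pooled <- unname(coef(lm(prod[keep] ~ r[keep]))[2])
  within <- unname(coef(lm(prod[m == 0.005] ~ r[m == 0.005]))[2])
  expect_equal(within, h2, tolerance = 0.15)
  expect_lt(pooled, 0.5 * h2)
  expect_lt(pooled, within - 0.1)
})

test_that("alternative range presets restrict the pair set", {
  A <- synthetic_A(50, seed = 11)
  withr::with_seed(12, z <- std(rnorm(50)))
  names(z) <- rownames(A)
  pp <- pair_products(z)
  f_default <- zuk_estimate(pp, A, range_mult = c(0, 2))
  f_mid <- zuk_estimate(pp, A, range_mult = c(0.5, 1.5))
  f_narrow <- zuk_estimate(pp, A, range_mult = c(0.9, 1.1))
  expect_gt(f_default$n_pairs, f_mid$n_pairs)
  expect_gt(f_mid$n_pairs, f_narrow$n_pairs)
  expect_equal(f_mid$range[["lo"]], 0.5 * f_mid$mean_relatedness)
})
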