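# Shared fixtures, all generated in code.

# Strip class and method tag for pure numeric comparison of matrices.
bare <- function(A) {
  a <- unclass(A)
  attr(a, "method") <- NULL
  a
}

# A small single-chromosome map: markers at 0, 10, ..., 100 cM.
tiny_map <- function(len = 100, n = 11, chrom = "1") {
  marker_map(setNames(len, chrom), n)
}

# Segment tibble shorthand.
seg <- function(a, b, chrom, start, end) {
  tibble::tibble(sample_a = a, sample_b = b, chrom = as.character(chrom),
                 start_cm = start, end_cm = end)
}

# Random segment fixture on a given map: segments snapped to marker positions
# so that interval-based and length-based accounting agree exactly.
random_segments <- function(map, samples, n_segs, seed) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_segs), function(i) {
      pair <- sample(samples, 2)
      c_i <- sample(unique(map$chrom), 1)
      pos <- map$cM[map$chrom == c_i]
      ij <- sort(sample(length(pos), 2))
      if (ij[1] == ij[2]) ij[2] <- ij[1] + 1
      seg(min(pair), max(pair), c_i, pos[ij[1]], pos[ij[2]])
    })
    merge_segments(dplyr::bind_rows(rows))
  })
}

# A small homogeneous simulated population used across tests.
tiny_pop <- function(seed = 42, n = 40, n_snps = 300, pair_ibd = 20) {
  simulate_structured_population(
    sim_config(n_subpops = 1, n_per_subpop = n, fst = 0, n_snps = n_snps,
               chrom_lengths_cM = c(80, 70), pair_ibd_mean_cM = pair_ibd,
               segment_mean_cM = 4, n_causal = 30, seed = seed))
}

# Brute-force weighted relatedness (Eq.-style double loop over pairs and
# intervals), independent of the package's prefix-sum implementation.
brute_weighted <- function(segs, track, threshold, samples) {
  ints <- track
  n <- length(samples)
  A <- matrix(0, n, n, dimnames = list(samples, samples))
  w <- ifelse(ints$ir > threshold, ints$length_cm / ints$ir, 0)
  denom <- 2 * sum(w)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      sjk <- segs[(segs$sample_a == samples[j] & segs$sample_b == samples[k]) |
                    (segs$sample_a == samples[k] & segs$sample_b == samples[j]), ]
      num <- 0
      for (i in seq_len(nrow(ints))) {
        covered <- any(sjk$chrom == ints$chrom[i] &
                         sjk$start_cm <= ints$start_cm[i] + 1e-9 &
                         sjk$end_cm >= ints$end_cm[i] - 1e-9)
        num <- num + covered * w[i]
      }
      A[j, k] <- A[k, j] <- num / denom
    }
  }
  diag(A) <- 1
  A
}

# Dense REML restricted log-likelihood (profiled over the total variance),
# written independently of the package's rotated implementation: direct
# solve/determinant evaluation of
#   -0.5 [ log|V| + log|X'V^-1 X| + (n-p)(1 + log(2 pi rss/(n-p))) ]
# with V = h A + (1-h) I and rss the GLS weighted residual sum of squares.
dense_reml_loglik <- function(h, y, A, X) {
  n <- length(y)
  V <- h * A + (1 - h) * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  np <- n - ncol(X)
  ld_v <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ld_x <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  -0.5 * (ld_v + ld_x + np * (1 + log(2 * pi * rss / np)))
}
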