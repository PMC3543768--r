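test_that("merge_segments collapses overlapping and abutting records", {
  s <- dplyr::bind_rows(seg("B", "A", 1, 10, 30), seg("A", "B", 1, 20, 50),
                        seg("A", "B", 1, 50, 60), seg("A", "B", 2, 0, 10),
                        seg("A", "C", 1, 70, 80))
  m <- merge_segments(s)
  expect_equal(nrow(m), 3)
  ab1 <- m[m$sample_b == "B" & m$chrom == "1", ]
  expect_equal(c(ab1$start_cm, ab1$end_cm), c(10, 60))
  expect_error(merge_segments(seg("A", "B", 1, 5, 5)), "start_cm >= end_cm")
})

test_that("IBD rate counts pairs covering each interval", {
  map <- tiny_map() # markers at 0, 10, ..., 100
  # one segment covering intervals 3..7 (cM 20..70) among 10 pairs
  tr <- compute_ibd_rate(seg("S1", "S2", 1, 20, 70), map, n_pairs = 10)
  expect_equal(tr$ir, c(0, 0, rep(0.1, 5), 0, 0, 0))
  expect_equal(sum(tr$length_cm), genome_length_cM(map))
  # empty set: IR identically zero
  tr0 <- compute_ibd_rate(seg(character(0), character(0), character(0),
                              numeric(0), numeric(0)), map, 10)
  expect_true(all(tr0$ir == 0))
  # partial interval coverage does not count
  tr2 <- compute_ibd_rate(seg("S1", "S2", 1, 25, 70), map, 10)
  expect_equal(tr2$ir[3], 0)
  expect_equal(tr2$ir[4], 0.1)
  # segment outside the map errors with the record named
  expect_error(compute_ibd_rate(seg("S1", "S2", 1, 90, 120), map, 10),
               "S1-S2.*outside the map")
  expect_error(compute_ibd_rate(seg("S1", "S2", "7", 0, 10), map, 10),
               "chromosome '7'")
})

test_that("IBD rate matches brute-force pair x interval enumeration", {
  map <- marker_map(c(50, 40, 30), 30)
  samples <- sprintf("S%02d", 1:20)
  segs <- random_segments(map, samples, 50, seed = 5)
  tr <- compute_ibd_rate(segs, map, n_pairs = choose(20, 2))
  ints <- map_intervals(map)
  brute <- vapply(seq_len(nrow(ints)), function(i) {
    cov <- segs$chrom == ints$chrom[i] &
      segs$start_cm <= ints$start_cm[i] + 1e-9 &
      segs$end_cm >= ints$end_cm[i] - 1e-9
    length(unique(paste(segs$sample_a[cov], segs$sample_b[cov])))
  }, numeric(1))
  expect_equal(tr$n_pairs_ibd, brute)
})

test_that("rate_threshold is the nearest-rank percentile", {
  map <- tiny_map()
  tr <- compute_ibd_rate(seg("S1", "S2", 1, 0, 100), map, 10)
  tr$ir <- rep(0.25, nrow(tr))
  for (p in c(0.1, 2, 5, 50, 100)) expect_equal(rate_threshold(tr, p), 0.25)
  # IR values 1..1000 / 1000, percentile 10 -> sorted element at rank 100
  tr2 <- tr[rep(1, 1000), ]
  tr2$ir <- sample(seq_len(1000) / 1000)
  expect_equal(rate_threshold(tr2, 10), 0.1)
  expect_equal(rate_threshold(tr2, 0.1), 0.001)
  expect_error(rate_threshold(tr2[0, ], 5), "no intervals")
})

test_that("weighted relatedness reduces exactly to unweighted at constant IR", {
  map <- marker_map(c(60, 40), 25)
  samples <- sprintf("S%02d", 1:10)
  segs <- random_segments(map, samples, 40, seed = 8)
  tr <- compute_ibd_rate(segs, map, choose(10, 2))
  tr$ir <- rep(0.2, nrow(tr))
  Aw <- weighted_relatedness(segs, tr, 0, samples = samples)
  Au <- unweighted_relatedness(segs, map, samples = samples)
  expect_equal(bare(Aw), bare(Au), tolerance = 1e-14)
  expect_equal(attr(Aw, "method"), "ibd_weighted")
})

test_that("full-genome sharing gives relatedness one half", {
  map <- tiny_map()
  samples <- c("S1", "S2", "S3")
  full <- seg("S1", "S2", 1, 0, 100)
  Au <- unweighted_relatedness(full, map, samples = samples)
  expect_equal(Au["S1", "S2"], 0.5)
  expect_equal(Au["S1", "S3"], 0)
  tr <- compute_ibd_rate(full, map, 3)
  Aw <- weighted_relatedness(full, tr, 0, samples = samples)
  expect_equal(Aw["S1", "S2"], 0.5)
})

test_that("weighted relatedness matches an independent brute-force oracle", {
  map <- marker_map(c(50, 40, 30), 24)
  samples <- sprintf("S%02d", 1:10)
  segs <- random_segments(map, samples, 60, seed = 17)
  track <- compute_ibd_rate(segs, map, choose(10, 2))
  thr <- rate_threshold(track, 5)
  Aw <- weighted_relatedness(segs, track, thr, samples = samples)
  expect_equal(bare(Aw), brute_weighted(segs, track, thr, samples),
               tolerance = 1e-12)
})

test_that("relatedness is invariant to splitting segments and permuting samples", {
  map <- marker_map(c(60, 40), 25)
  samples <- sprintf("S%02d", 1:8)
  segs <- random_segments(map, samples, 30, seed = 23)
  track <- compute_ibd_rate(segs, map, choose(8, 2))
  A1 <- weighted_relatedness(segs, track, 0, samples = samples)
  # split every segment into two abutting halves
  mid <- (segs$start_cm + segs$end_cm) / 2
  split <- dplyr::bind_rows(
    dplyr::mutate(segs, end_cm = mid),
    dplyr::mutate(segs, start_cm = mid))
  A2 <- weighted_relatedness(split, track, 0, samples = samples)
  expect_equal(bare(A1), bare(A2), tolerance = 1e-12)
  # permuted sample universe permutes the matrix consistently
  perm <- rev(samples)
  A3 <- weighted_relatedness(segs, track, 0, samples = perm)
  expect_equal(bare(A3), bare(A1)[perm, perm])
})

test_that("all intervals excluded is an error", {
  map <- tiny_map()
  segs <- seg("S1", "S2", 1, 0, 100)
  track <- compute_ibd_rate(segs, map, 2)
  expect_error(weighted_relatedness(segs, track, threshold = 2), "denominator")
})

test_that("segment-based estimators recover simulated truth exactly", {
  pop <- tiny_pop(seed = 31)
  ids <- pop$samples$sample_id
  Au <- unweighted_relatedness(pop$true_ibd, pop$map, samples = ids,
                               hbd = pop$true_hbd)
  expect_equal(bare(Au), bare(pop$true_relatedness), tolerance = 1e-12)
  # weighted agrees exactly when IR is constant across intervals
  track <- compute_ibd_rate(pop$true_ibd, pop$map, choose(length(ids), 2))
  track$ir <- rep(mean(track$ir), nrow(track))
  Aw <- weighted_relatedness(pop$true_ibd, track, 0, samples = ids,
                             hbd = pop$true_hbd, map = pop$map)
  expect_equal(bare(Aw), bare(pop$true_relatedness), tolerance = 1e-12)
})

test_that("HBD inbreeding is total HBD length over genome length", {
  map <- tiny_map()
  # no HBD: f = 0 -> diagonal 1
  A <- unweighted_relatedness(seg("S1", "S2", 1, 0, 10), map,
                              samples = c("S1", "S2"))
  expect_equal(diag(unclass(A)), c(S1 = 1, S2 = 1))
  # genome-wide HBD: f = 1 -> diagonal 2
  hbd <- seg("S1", "S1", 1, 0, 100)
  f <- hbd_inbreeding(hbd, map)
  expect_equal(f$f, 1)
  # overlapping records merged before summation
  hbd2 <- dplyr::bind_rows(seg("S2", "S2", 1, 0, 50), seg("S2", "S2", 1, 30, 60))
  expect_equal(hbd_inbreeding(hbd2, map)$f, 0.6)
  A2 <- unweighted_relatedness(seg("S1", "S2", 1, 0, 10), map,
                               samples = c("S1", "S2"),
                               hbd = dplyr::bind_rows(hbd, hbd2))
  expect_equal(diag(unclass(A2)), c(S1 = 2, S2 = 1.6))
  expect_error(hbd_inbreeding(seg("S1", "S2", 1, 0, 10), map), "sample_a == sample_b")
})

test_that("close relative exclusion is greedy and deterministic", {
  map <- tiny_map(len = 1000, n = 101)
  # one pair sharing 800 cM: exactly one removed at the default 750
  one <- seg("S1", "S2", 1, 0, 800)
  expect_length(close_relative_exclusion(one, map), 1)
  # nobody over threshold: empty set
  expect_length(close_relative_exclusion(seg("S1", "S2", 1, 0, 700), map), 0)
  # triangle: A-B and A-C over, B-C under -> only A removed
  tri <- dplyr::bind_rows(seg("A", "B", 1, 0, 800), seg("A", "C", 1, 100, 900),
                          seg("B", "C", 1, 0, 100))
  expect_equal(close_relative_exclusion(tri, map), "A")
  # tie broken by lexicographically smallest id
  pair <- seg("B", "D", 1, 0, 800)
  expect_equal(close_relative_exclusion(pair, map), "B")
})

test_that("X relatedness applies full-dosage-compensation multipliers", {
  map_x <- marker_map(c(X = 100), 11)
  sexes <- c(F1 = "F", F2 = "F", F3 = "F", M1 = "M", M2 = "M")
  segs <- dplyr::bind_rows(seg("F1", "F2", "X", 0, 40),
                           seg("M1", "F3", "X", 0, 40),
                           seg("M1", "M2", "X", 0, 40))
  A <- x_relatedness(segs, map_x, sexes)
  r_ff <- A["F1", "F2"]
  expect_equal(r_ff, 0.2) # 40 / (2 * 100)
  expect_equal(A["M1", "F3"] / r_ff, 2)
  expect_equal(A["M1", "M2"] / r_ff, 4)
  expect_true(all(diag(unclass(A)) == 1))
  # no segments: all zeros regardless of sex
  A0 <- x_relatedness(segs[0, ], map_x, sexes)
  expect_true(all(unclass(A0)[upper.tri(A0)] == 0))
  # unknown sex errors
  expect_error(x_relatedness(segs, map_x, c(sexes, Z1 = "U")), "Unknown sex")
  # brute force: unweighted base with multipliers applied post hoc
  segs2 <- random_segments(map_x, names(sexes), 20, seed = 3)
  base <- unweighted_relatedness(segs2, map_x, samples = names(sexes))
  mult <- outer(1 + (sexes == "M"), 1 + (sexes == "M"))
  expected <- unclass(base) * mult
  diag(expected) <- 1
  expect_equal(bare(x_relatedness(segs2, map_x, sexes)), bare(expected))
})
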