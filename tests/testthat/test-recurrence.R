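chrom1 <- data.frame(name = "chr1", length = 10e6)

test_that("marker scores follow G = frequency x mean amplitude", {
  # one tumor, log2 = 1 everywhere: frequency 1, amplitude 1, G = 1
  seg <- flat_segment_set("T1", value = 1)
  tr <- build_marker_track(seg, 1e4, "amplification", 0.1,
                           chromosomes = chrom1)
  expect_true(all(tr$frequency == 1))
  expect_true(all(tr$amplitude == 1))
  expect_true(all(tr$g_score == 1))

  # 2 of 4 tumors altered at 0.8 on one interval: G = 0.5 * 0.8
  ev <- data.frame(sample = c("T1", "T2"), chromosome = "chr1",
                   start = 2e6, end = 3e6, log2_ratio = 0.8)
  seg4 <- flat_segment_set(paste0("T", 1:4), events = ev)
  tr4 <- build_marker_track(seg4, 1e4, "amplification", 0.1,
                            chromosomes = chrom1)
  inside <- tr4$start >= 2e6 & tr4$end <= 3e6
  expect_equal(unique(tr4$frequency[inside]), 0.5)
  expect_equal(unique(tr4$amplitude[inside]), 0.8)
  expect_equal(unique(tr4$g_score[inside]), 0.4)
  expect_true(all(tr4$g_score[!inside] == 0))

  # all-zero cohort scores 0 everywhere; opposite direction sees nothing
  tr0 <- build_marker_track(flat_segment_set(paste0("T", 1:3)), 1e4,
                            "amplification", 0.1, chromosomes = chrom1)
  expect_true(all(tr0$g_score == 0))
  trd <- build_marker_track(seg4, 1e4, "deletion", 0.1,
                            chromosomes = chrom1)
  expect_true(all(trd$g_score == 0))
})

test_that("a cohort without tumors is rejected", {
  seg <- flat_segment_set("N1", labels = c(N1 = "normal"))
  expect_error(build_marker_track(seg, 1e4, "amplification", 0.1,
                                  chromosomes = chrom1),
               "no tumor samples")
})

test_that("empirical q matches hand BH step-up and is rank-monotone", {
  # hand-checked BH: p = (.01,.02,.03) -> q = (.03,.03,.03)
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }

  # on a real track: q order respects p order
  ev <- data.frame(sample = paste0("T", 1:3), chromosome = "chr1",
                   start = 4e6, end = 4.3e6, log2_ratio = 1.2)
  seg <- flat_segment_set(paste0("T", 1:10), events = ev)
  tr <- build_marker_track(seg, 1e4, "amplification", 0.1,
                           chromosomes = chrom1)
  null <- permutation_null(seg, tr, 100, seed = 2)
  tr <- empirical_q(tr, null)
  o <- order(tr$p_value)
  expect_true(all(diff(tr$q_value[o]) >= -1e-12))
  expect_equal(tr$q_value, bh_stepup(tr$p_value), tolerance = 1e-12)
  # zero-G markers carry p = 1 (null contains mass at 0)
  expect_true(all(tr$p_value[tr$g_score == 0] == 1))
})

test_that("the permutation null is seed-deterministic", {
  seg <- flat_segment_set(paste0("T", 1:5),
                          events = data.frame(sample = "T1",
                                              chromosome = "chr1",
                                              start = 1e6, end = 2e6,
                                              log2_ratio = 1))
  tr <- build_marker_track(seg, 5e4, "amplification", 0.1,
                           chromosomes = chrom1)
  n1 <- permutation_null(seg, tr, 100, seed = 5)
  n2 <- permutation_null(seg, tr, 100, seed = 5)
  expect_identical(n1, n2)
  n3 <- permutation_null(seg, tr, 100, seed = 6)
  expect_false(identical(n1, n3))
  expect_error(permutation_null(seg, tr, 50, seed = 1), "n_perm")
})

test_that("a planted alteration produces one overlapping peak", {
  g <- make_genome(2, 10e6, 20, 10, 2, 0, seed = 1)
  alt <- planted_alteration("chr1", 4e6, 5e6, "amplification",
                            carrier_frequency = 0.2, amplitude = 1.5)
  seg <- simulate_cohort(g, list(alt), n_tumor = 100, n_normal = 0,
                         seed = 7)
  tr <- build_marker_track(seg, 1e4, "amplification", 0.1,
                           chromosomes = g$chromosomes)
  tr <- empirical_q(tr, permutation_null(seg, tr, 100, seed = 8))
  peaks <- call_alterations(tr, 0.25)
  expect_equal(nrow(peaks), 1L)
  expect_true(peaks$focal_start < 5e6 && peaks$focal_end > 4e6)
  expect_lt(peaks$q_value, 0.25)
  # nesting invariant
  expect_true(peaks$region_start <= peaks$enlarged_start)
  expect_true(peaks$enlarged_start <= peaks$focal_start)
  expect_true(peaks$focal_end <= peaks$enlarged_end)
  expect_true(peaks$enlarged_end <= peaks$region_end)
  # nothing on the untouched chromosome, nothing in the other direction
  expect_true(all(peaks$chromosome == "chr1"))
  trd <- build_marker_track(seg, 1e4, "deletion", 0.1,
                            chromosomes = g$chromosomes)
  trd <- empirical_q(trd, permutation_null(seg, trd, 100, seed = 8))
  expect_true(all(trd$g_score[tr$start >= 4e6 & tr$end <= 5e6 &
                                tr$chromosome == "chr1"] <
                    max(tr$g_score)))
})

test_that("two separated planted alterations give two peaks", {
  g <- make_genome(1, 10e6, 10, 6, 1, 0, seed = 2)
  alts <- list(
    planted_alteration("chr1", 1e6, 1.8e6, "amplification", 0.25, 1.5),
    planted_alteration("chr1", 6e6, 6.8e6, "amplification", 0.25, 1.5))
  seg <- simulate_cohort(g, alts, n_tumor = 100, n_normal = 0, seed = 3)
  tr <- build_marker_track(seg, 1e4, "amplification", 0.1,
                           chromosomes = g$chromosomes)
  tr <- empirical_q(tr, permutation_null(seg, tr, 100, seed = 4))
  peaks <- call_alterations(tr, 0.25)
  expect_equal(nrow(peaks), 2L)
  hits1 <- peaks$focal_start < 1.8e6 & peaks$focal_end > 1e6
  hits2 <- peaks$focal_start < 6.8e6 & peaks$focal_end > 6e6
  expect_equal(sum(hits1), 1L)
  expect_equal(sum(hits2), 1L)
})

test_that("no significant markers yields an empty peak list", {
  seg <- flat_segment_set(paste0("T", 1:5))
  tr <- build_marker_track(seg, 1e5, "amplification", 0.1,
                           chromosomes = chrom1)
  tr <- empirical_q(tr, permutation_null(seg, tr, 100, seed = 1))
  expect_equal(nrow(call_alterations(tr, 0.25)), 0L)
})

test_that("peel-off removes support, never raises G, and finds co-located events", {
  # group A (8 tumors): [1.0, 1.3) Mb at +2.0; group B (6 tumors,
  # disjoint carriers): [1.3, 1.6) Mb at +1.8; 6 quiet tumors
  evA <- data.frame(sample = paste0("A", 1:8), chromosome = "chr1",
                    start = 1.0e6, end = 1.3e6, log2_ratio = 2.0)
  evB <- data.frame(sample = paste0("B", 1:6), chromosome = "chr1",
                    start = 1.3e6, end = 1.6e6, log2_ratio = 1.8)
  samples <- c(paste0("A", 1:8), paste0("B", 1:6), paste0("Q", 1:6))
  seg <- flat_segment_set(samples, events = rbind(evA, evB))
  tr <- build_marker_track(seg, 1e4, "amplification", 0.1,
                           chromosomes = chrom1)
  tr <- empirical_q(tr, permutation_null(seg, tr, 100, seed = 9))
  peaks <- call_alterations(tr, 0.25)
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$focal_start, c(1.0e6, 1.3e6))
  expect_equal(peaks$focal_end, c(1.3e6, 1.6e6))
  expect_setequal(peaks$supporting[[1]], paste0("A", 1:8))
  expect_setequal(peaks$supporting[[2]], paste0("B", 1:6))
  # both peaks cover one contiguous region
  expect_equal(unique(peaks$region_start), 1.0e6)
  expect_equal(unique(peaks$region_end), 1.6e6)

  # explicit peel-off: monotone, and a single-sample region collapses to 0
  res <- peel_off(tr, seg, peaks[1, ])
  expect_true(all(res$g_score <= tr$g_score + 1e-12))

  ev1 <- data.frame(sample = "T1", chromosome = "chr1",
                    start = 2e6, end = 2.5e6, log2_ratio = 1.5)
  seg1 <- flat_segment_set(paste0("T", 1:4), events = ev1)
  tr1 <- build_marker_track(seg1, 1e4, "amplification", 0.1,
                            chromosomes = chrom1)
  tr1 <- empirical_q(tr1, permutation_null(seg1, tr1, 100, seed = 1))
  pk <- toy_peak(2e6, 2.5e6)
  res1 <- peel_off(tr1, seg1, pk)
  inside <- res1$start >= 2e6 & res1$end <= 2.5e6
  expect_true(all(res1$g_score[inside] == 0))
})
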