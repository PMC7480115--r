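test_that("welch_t matches the textbook formulas", {
  # hand-checkable case: x = 1:3, y = 4:6 -> t = -3.674, df = 4
  wt <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(wt$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(wt$df, 4, tolerance = 1e-10)
  expect_equal(wt$p_value, 0.02131164, tolerance = 1e-6)

  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    a <- welch_t(x, y)
    b <- welch_oracle(x, y)
    expect_equal(a$t, b$t, tolerance = 1e-10)
    expect_equal(a$df, b$df, tolerance = 1e-10)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
    # shift invariance
    s <- welch_t(x + 5, y + 5)
    expect_equal(s$t, a$t, tolerance = 1e-10)
    expect_equal(s$p_value, a$p_value, tolerance = 1e-10)
  }

  # identical groups: t = 0, p = 1; degenerate cases error
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
  expect_error(welch_t(c(2, 2, 2), c(3, 3, 3)), "degenerate")
})

test_that("the concordance screen enforces the direction rule", {
  ann <- toy_annotation()
  up <- classify_peaks(toy_peak(7e5, 8e5), ann)           # covers LNC1
  down <- classify_peaks(toy_peak(9e5, 10e5, rank = 2L), ann) # covers LNC2
  down$direction <- "deletion"

  # LNC1 higher in tumor, LNC2 lower in tumor: both concordant
  ex <- toy_expression(c("LNC1", "LNC2"), tumor_means = c(40, 5),
                       normal_means = c(10, 20), sd = 2, seed = 2)
  res <- concordance_filter(rbind(up, down), ex, alpha = 0.05)
  expect_true(all(res$verdicts$putative_functional))
  expect_equal(nrow(res$survivors), 2L)

  # an amplified SCNA whose lncRNA is LOWER in tumor never survives,
  # however significant the difference
  ex_rev <- toy_expression("LNC1", tumor_means = 5, normal_means = 50,
                           sd = 1, seed = 3)
  res_rev <- concordance_filter(up, ex_rev, alpha = 0.05)
  expect_false(res_rev$verdicts$direction_match)
  expect_false(res_rev$verdicts$putative_functional)
  expect_lt(res_rev$verdicts$p_value, 0.05)
  expect_equal(nrow(res_rev$survivors), 0L)

  # survivors are always a subset of the input
  expect_true(all(res$survivors$rank %in% c(up$rank, down$rank)))
})

test_that("the screen demands normals and warns on missing genes", {
  ann <- toy_annotation()
  cl <- classify_peaks(toy_peak(7e5, 8e5), ann)
  ex <- toy_expression("LNC1", 20, 10, sd = 1, seed = 1)
  ex_no_norm <- ex
  ex_no_norm$labels[] <- "tumor"
  expect_error(concordance_filter(cl, ex_no_norm), "no normal samples")

  ex_missing <- ex
  rownames(ex_missing$values) <- "OTHER"
  expect_warning(res <- concordance_filter(cl, ex_missing), "absent")
  expect_equal(nrow(res$verdicts), 0L)
})

test_that("amplified-vs-rest grouping behaves and rejects degenerate splits", {
  set.seed(5)
  expr <- setNames(c(2^rnorm(30, 6, 0.3), 2^rnorm(10, 8, 0.3)),
                   sprintf("T%02d", 1:40))
  amp <- sprintf("T%02d", 31:40)
  res <- amplification_group_test(expr, amp)
  expect_gt(res$mean_amplified, res$mean_other)
  expect_lt(res$p_value, 1e-4)
  expect_error(amplification_group_test(expr, names(expr)),
               "empty complement")
  expect_error(amplification_group_test(expr, character()), "no amplified")
})

test_that("cohort summary reproduces the 43-in-493 amplification percent", {
  # 493 tumors, 43 with the focal amplification: 8.72% amplified
  n <- 493
  samples <- sprintf("T%03d", seq_len(n))
  ev <- data.frame(sample = samples[1:43], chromosome = "chr1",
                   start = 2e6, end = 2.5e6, log2_ratio = 1.0)
  seg <- flat_segment_set(samples, events = ev)
  values <- matrix(c(rep(5, 400), rep(0, 93)), nrow = 1,
                   dimnames = list("LNC1", samples))
  ex <- structure(list(values = values,
                       labels = setNames(rep("tumor", n), samples)),
                  class = "labeled_matrix")
  s <- cohort_summary(toy_peak(2e6, 2.5e6), seg, ex, "LNC1")
  expect_equal(s$percent_amplified, 100 * 43 / 493, tolerance = 1e-12)
  expect_equal(round(s$percent_amplified, 2), 8.72)
  expect_equal(s$percent_expressed, 100 * 400 / 493, tolerance = 1e-12)
  expect_equal(s$percent_amplified_and_expressed, 100 * 43 / 493)

  # all-zero expression: nothing expressed
  ex0 <- ex
  ex0$values[] <- 0
  expect_equal(cohort_summary(toy_peak(2e6, 2.5e6), seg, ex0,
                              "LNC1")$percent_expressed, 0)
})

test_that("differential methylation flags planted hypomethylation", {
  g <- make_genome(1, 5e6, 10, 6, 0, 0, seed = 4)
  lnc <- g$genes$gene_id[g$genes$biotype == "lncRNA"][1]
  m <- simulate_methylation(g, lnc, beta_normal_mean = 0.7,
                            beta_tumor_delta = 0.2, beta_sd = 0.05,
                            n_tumor = 50, n_normal = 50, seed = 5)
  res <- differential_methylation(m)
  target <- res[res$gene_id == lnc, ]
  expect_true(all(target$p_value < 1e-3))
  expect_true(all(target$hypomethylated))
  # background CpGs are mostly quiet
  bg <- res[res$gene_id != lnc, ]
  expect_lt(mean(bg$p_value < 0.05, na.rm = TRUE), 0.2)

  # constant beta in both groups: NA p with a note, run continues
  tum <- names(m$labels)[m$labels == "tumor"]
  nor <- names(m$labels)[m$labels == "normal"]
  m$values[1, tum] <- 0.5
  m$values[1, nor] <- 0.6
  res2 <- differential_methylation(m)
  expect_true(is.na(res2$p_value[1]))
  expect_match(res2$note[1], "degenerate")
  expect_false(anyNA(res2$p_value[-1]))
})
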