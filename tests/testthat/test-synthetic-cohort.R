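test_that("make_genome handles the empty genome and is seed-deterministic", {
  g0 <- make_genome(1, 10e6, 0, 0, 0, 0, seed = 1)
  expect_s3_class(g0, "genome_spec")
  expect_equal(nrow(g0$genes), 0L)

  g1 <- make_genome(1, 10e6, 10, 5, 2, 0, seed = 7)
  g2 <- make_genome(1, 10e6, 10, 5, 2, 0, seed = 7)
  expect_identical(g1, g2)
  g3 <- make_genome(1, 10e6, 10, 5, 2, 0, seed = 8)
  expect_false(identical(g1$genes, g3$genes))
})

test_that("make_genome errors when genes cannot be placed", {
  expect_error(
    make_genome(1, 1e3, 10000, 0, 0, 0, gene_length_range = c(1e3, 2e3),
                seed = 1),
    "capacity"
  )
})

test_that("generated genomes satisfy the annotation invariants", {
  for (seed in c(2, 5)) {
    g <- make_genome(2, 5e6, 30, 15, 4, 5, seed = seed)
    genes <- g$genes
    expect_false(anyDuplicated(genes$gene_id) > 0)
    expect_true(all(genes$driver == (genes$biotype == "protein_coding" &
                                       genes$driver)))
    expect_equal(sum(genes$driver), 4)
    # strand rule for the TSS
    expect_equal(genes$tss[genes$strand == "+"],
                 genes$start[genes$strand == "+"])
    expect_equal(genes$tss[genes$strand == "-"],
                 genes$end[genes$strand == "-"])
    # no overlap within a chromosome
    for (chrom in unique(genes$chromosome)) {
      gc <- genes[genes$chromosome == chrom, ]
      gc <- gc[order(gc$start), ]
      if (nrow(gc) > 1) expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
    }
  }
})

test_that("a noiseless unplanted cohort is exactly zero", {
  g <- make_genome(1, 2e6, 5, 3, 1, 0, seed = 3)
  seg <- simulate_cohort(g, list(), n_tumor = 5, n_normal = 2,
                         noise_sd = 0, seed = 4)
  expect_true(all(seg$segments$log2_ratio == 0))
})

test_that("deterministic planting yields the exact amplitude in carriers", {
  g <- make_genome(1, 2e6, 5, 3, 1, 0, seed = 3)
  alt <- planted_alteration("chr1", 5e5, 8e5, "amplification",
                            carrier_frequency = 1, amplitude = 1.25,
                            amplitude_sd = 0)
  seg <- simulate_cohort(g, list(alt), n_tumor = 6, n_normal = 2,
                         noise_sd = 0, seed = 4)
  s <- seg$segments
  tumors <- names(seg$labels)[seg$labels == "tumor"]
  expect_setequal(seg$carriers[[1]], tumors)
  for (smp in tumors) {
    inside <- s$sample == smp & s$start >= 5e5 & s$end <= 8e5
    expect_true(all(abs(s$log2_ratio[inside] - 1.25) < 1e-12))
    outside <- s$sample == smp & (s$end <= 5e5 | s$start >= 8e5)
    expect_true(all(s$log2_ratio[outside] == 0))
  }
  # normals untouched
  expect_true(all(s$log2_ratio[grepl("^N", s$sample)] == 0))
  # deletions flip the sign
  del <- planted_alteration("chr1", 5e5, 8e5, "deletion",
                            carrier_frequency = 1, amplitude = 0.8,
                            amplitude_sd = 0)
  segd <- simulate_cohort(g, list(del), n_tumor = 3, n_normal = 0,
                          noise_sd = 0, seed = 4)
  sd_ <- segd$segments
  expect_true(all(abs(sd_$log2_ratio[sd_$start >= 5e5 & sd_$end <= 8e5] +
                        0.8) < 1e-12))
})

test_that("carrier fraction falls in the binomial 99% interval", {
  g <- make_genome(1, 2e6, 2, 2, 0, 0, seed = 3)
  alt <- planted_alteration("chr1", 5e5, 8e5, "amplification",
                            carrier_frequency = 0.1)
  seg <- simulate_cohort(g, list(alt), n_tumor = 500, n_normal = 0,
                         noise_sd = 0, seed = 42)
  n_carrier <- length(seg$carriers[[1]])
  bounds <- qbinom(c(0.005, 0.995), 500, 0.1)
  expect_gte(n_carrier, bounds[1])
  expect_lte(n_carrier, bounds[2])
  # ground-truth closure: exactly the carriers were modified
  s <- seg$segments
  modified <- unique(s$sample[s$log2_ratio != 0])
  expect_setequal(modified, seg$carriers[[1]])
})

test_that("cohort segments are sorted, non-overlapping and reproducible", {
  g <- make_genome(2, 5e6, 10, 5, 2, 0, seed = 1)
  alt <- planted_alteration("chr2", 1e6, 2e6, "deletion",
                            carrier_frequency = 0.4)
  a <- simulate_cohort(g, list(alt), n_tumor = 20, n_normal = 5, seed = 9)
  b <- simulate_cohort(g, list(alt), n_tumor = 20, n_normal = 5, seed = 9)
  expect_identical(a, b)
  expect_silent(scnalnc:::validate_segment_set(a))
})

test_that("expression has no tumor/normal difference without dosage", {
  g <- make_genome(1, 2e6, 4, 2, 0, 0, seed = 3)
  alt <- planted_alteration("chr1", 5e5, 8e5, "amplification",
                            carrier_frequency = 1, amplitude = 2,
                            amplitude_sd = 0)
  seg <- simulate_cohort(g, list(alt), n_tumor = 5, n_normal = 5,
                         noise_sd = 0, seed = 4)
  ex <- simulate_expression(g, seg, dosage_slope = 0, base_log_expr = 3,
                            expr_sd = 0, seed = 5)
  expect_true(all(ex$values == 2^3))
})

test_that("full dosage coupling shifts carrier log-expression by the amplitude", {
  g <- make_genome(1, 2e6, 4, 2, 0, 0, seed = 3)
  lnc <- g$genes[g$genes$biotype == "lncRNA", ][1, ]
  alt <- planted_alteration("chr1", lnc$start, lnc$end, "amplification",
                            carrier_frequency = 1, amplitude = 1,
                            amplitude_sd = 0)
  seg <- simulate_cohort(g, list(alt), n_tumor = 5, n_normal = 5,
                         noise_sd = 0, seed = 4)
  ex <- simulate_expression(g, seg, dosage_slope = 1, base_log_expr = 3,
                            expr_sd = 0, seed = 5)
  lv <- log2(ex$values)
  tum <- names(ex$labels)[ex$labels == "tumor"]
  nor <- names(ex$labels)[ex$labels == "normal"]
  expect_equal(unname(lv[lnc$gene_id, tum] - mean(lv[lnc$gene_id, nor])),
               rep(1, length(tum)), tolerance = 1e-12)
})

test_that("TF sites: empty case, planted promoters, Poisson background", {
  g <- make_genome(1, 10e6, 10, 5, 0, 0, seed = 2)
  empty <- simulate_tf_sites(g, "TFX", enriched = list(),
                             background_rate = 0, seed = 1)
  expect_equal(nrow(empty), 0L)

  lnc <- g$genes$gene_id[g$genes$biotype == "lncRNA"][1]
  sites <- simulate_tf_sites(g, "TFX", enriched = list(TFX = lnc),
                             background_rate = 0, seed = 1)
  win <- promoter_windows(g$genes[g$genes$gene_id == lnc, ], 1000)
  expect_true(any(sites$start < win$end & sites$end > win$start))

  bg <- simulate_tf_sites(g, "TFY", enriched = list(),
                          background_rate = 10, seed = 5)
  bounds <- qpois(c(0.005, 0.995), 10 * 10)   # 10 per Mb on a 10 Mb genome
  expect_gte(nrow(bg), bounds[1])
  expect_lte(nrow(bg), bounds[2])

  expect_error(simulate_tf_sites(g, "TFX", enriched = list(TFX = "nope")),
               "unknown gene id")
})

test_that("methylation: exact shift at zero sd and clipped betas", {
  g <- make_genome(1, 2e6, 4, 2, 0, 0, seed = 3)
  lnc <- g$genes$gene_id[g$genes$biotype == "lncRNA"][1]
  m <- simulate_methylation(g, hypo_targets = lnc,
                            beta_normal_mean = 0.7, beta_tumor_delta = 0.2,
                            beta_sd = 0, n_tumor = 4, n_normal = 4, seed = 6)
  tum <- names(m$labels)[m$labels == "tumor"]
  nor <- names(m$labels)[m$labels == "normal"]
  target_cpgs <- m$map$cpg_id[m$map$gene_id == lnc]
  expect_true(all(m$values[target_cpgs, tum] == 0.7 - 0.2))
  expect_true(all(m$values[target_cpgs, nor] == 0.7))
  other <- setdiff(rownames(m$values), target_cpgs)
  expect_true(all(m$values[other, ] == 0.7))
  expect_true(all(m$values >= 0 & m$values <= 1))
  # two CpGs per gene, within 500 bp of the TSS
  expect_equal(nrow(m$map), 2L * nrow(g$genes))
  tss <- g$genes$tss[match(m$map$gene_id, g$genes$gene_id)]
  expect_true(all(abs(m$map$pos - tss) <= 500))
})
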