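# Orchestration: simulate -> detect -> classify -> enrich -> concord ->
# immune, from one declarative config, with persisted intermediates and
# a JSON run report.

#' Default pipeline configuration
#'
#' All tunable parameters of the screen with their defaults, plus the
#' simulation stanza describing the synthetic cohort. Every stochastic
#' stage derives its own seed from the root seed by a fixed offset.
#'
#' @param seed root seed (mandatory for any stochastic stage).
#' @param out_dir where intermediates are written (`NULL` for a temp dir).
#' @return named list of parameters.
#' @export
default_config <- function(seed = 1, out_dir = NULL) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    # synthetic cohort
    n_chrom = 2, chrom_length = 10e6,
    n_coding = 60, n_lnc = 30, n_driver = 5, n_pseudo = 10,
    n_tumor = 200, n_normal = 30,
    noise_sd = 0.1, segment_mean_len = 2e6,
    planted = list(),
    dosage_slope = 1, base_log_expr = 3, expr_sd = 0.5,
    tf_names = paste0("TF", 1:8), tf_enriched = list(),
    tf_background_rate = 10,
    hypo_targets = character(),
    beta_normal_mean = 0.7, beta_tumor_delta = 0.2, beta_sd = 0.05,
    n_signatures = 5, genes_per_signature = 10,
    # detection
    bin_size = 10e3, amp_threshold = 0.1, n_perm = 1000,
    q_threshold = 0.25, enlarged_epsilon = 0.05, max_peaks_per_region = 5,
    # downstream
    flank = 1000, alpha = 0.05, ssgsea_alpha = 0.25,
    min_reciprocal_overlap = 0.25
  )
}

#' @keywords internal
validate_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed))
  with(config, {
    stopifnot(n_tumor >= 1, bin_size >= 1, amp_threshold > 0,
              n_perm >= 100, q_threshold > 0, q_threshold < 1,
              enlarged_epsilon >= 0, enlarged_epsilon < 1,
              flank > 0, alpha > 0, alpha < 1, ssgsea_alpha >= 0)
  })
  invisible(config)
}

#' Run the full discovery pipeline
#'
#' Runs all stages in order on a synthetic cohort described by the
#' config: simulation with planted ground truth, recurrence detection in
#' both directions, biotype classification of focal peaks, promoter TF
#' enrichment of altered lncRNAs, expression concordance screening, and
#' immune-signature contrasts against the top amplification's carriers.
#' All intermediate artifacts are written under `config$out_dir` so each
#' stage is independently inspectable; rerunning with the same config
#' and seed reproduces identical outputs.
#'
#' @param config a list as from [default_config()].
#' @return A `run_report` list: per-stage counts, funnel, parameter echo
#'   and file paths. Also written as `report.json` in the output
#'   directory.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("scnalnc_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  # --- stage 1: simulate -------------------------------------------------
  genome <- make_genome(config$n_chrom, config$chrom_length,
                        config$n_coding, config$n_lnc, config$n_driver,
                        config$n_pseudo, seed = seed)
  segments <- simulate_cohort(genome, config$planted,
                              n_tumor = config$n_tumor,
                              n_normal = config$n_normal,
                              noise_sd = config$noise_sd,
                              segment_mean_len = config$segment_mean_len,
                              seed = seed + 1L)
  expression <- simulate_expression(genome, segments,
                                    dosage_slope = config$dosage_slope,
                                    base_log_expr = config$base_log_expr,
                                    expr_sd = config$expr_sd,
                                    seed = seed + 2L)
  sites <- simulate_tf_sites(genome, config$tf_names, config$tf_enriched,
                             background_rate = config$tf_background_rate,
                             seed = seed + 3L)
  meth <- simulate_methylation(genome, config$hypo_targets,
                               beta_normal_mean = config$beta_normal_mean,
                               beta_tumor_delta = config$beta_tumor_delta,
                               beta_sd = config$beta_sd,
                               n_tumor = min(50, config$n_tumor),
                               n_normal = max(2, config$n_normal),
                               seed = seed + 4L)
  signatures <- simulate_signatures(genome, config$n_signatures,
                                    config$genes_per_signature,
                                    seed = seed + 5L)
  write_seg(segments, file.path(out_dir, "cohort.seg"))
  write_genes(genome$genes, file.path(out_dir, "genes.gtf"))
  write_bed(sites, file.path(out_dir, "tf_sites.bed"))
  write_matrix(expression, file.path(out_dir, "expression.tsv"))
  write_matrix(meth, file.path(out_dir, "methylation.tsv"))
  write_gmt(signatures, file.path(out_dir, "signatures.gmt"))

  # --- stage 2: detect ---------------------------------------------------
  peaks_by_dir <- lapply(c("amplification", "deletion"), function(dir) {
    track <- build_marker_track(segments, config$bin_size, dir,
                                config$amp_threshold,
                                chromosomes = genome$chromosomes)
    null <- permutation_null(segments, track, config$n_perm,
                             seed = seed + 6L)
    track <- empirical_q(track, null)
    write.table(as.data.frame(track)[, 1:8],
                file.path(out_dir, paste0("track_", dir, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    call_alterations(track, config$q_threshold, config$enlarged_epsilon,
                     config$max_peaks_per_region)
  })
  peaks <- do.call(rbind, peaks_by_dir)
  if (nrow(peaks)) {
    peaks <- peaks[order(-peaks$g_score), ]
    peaks$rank <- seq_len(nrow(peaks))
    rownames(peaks) <- NULL
  }
  peak_cols <- setdiff(names(peaks), "supporting")
  write.table(as.data.frame(peaks)[, peak_cols],
              file.path(out_dir, "peaks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 3: classify -------------------------------------------------
  classified <- classify_peaks(peaks, genome$genes, level = "focal",
                               cohort = "synthetic")
  cls <- as.data.frame(classified)
  cls$genes <- vapply(classified$genes, paste, character(1), collapse = ",")
  write.table(cls[, setdiff(names(cls), "supporting")],
              file.path(out_dir, "classified.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 4: promoter TF enrichment -----------------------------------
  lnc_universe <- genome$genes$gene_id[genome$genes$biotype == "lncRNA"]
  windows <- promoter_windows(genome$genes, config$flank,
                              setNames(genome$chromosomes$length,
                                       genome$chromosomes$name))
  enrich <- list()
  for (dir in c("amplification", "deletion")) {
    altered_lnc <- intersect(
      unique(unlist(classified$genes[classified$direction == dir])),
      lnc_universe)
    enrich[[dir]] <- if (length(altered_lnc)) {
      enrichment_table(altered_lnc, lnc_universe, windows, sites)
    } else {
      NULL
    }
    if (!is.null(enrich[[dir]])) {
      write.table(enrich[[dir]],
                  file.path(out_dir, paste0("enrichment_", dir, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- stage 5: expression concordance -----------------------------------
  concord <- concordance_filter(classified, expression, config$alpha,
                                annotation = genome$genes)
  write.table(concord$verdicts, file.path(out_dir, "verdicts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 6: methylation + immune -------------------------------------
  meth_res <- differential_methylation(meth)
  write.table(meth_res, file.path(out_dir, "methylation_welch.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tumors <- names(segments$labels)[segments$labels == "tumor"]
  tumor_expr <- list(values = expression$values[, tumors, drop = FALSE],
                     labels = expression$labels[tumors])
  scores <- score_signatures(tumor_expr, signatures, config$ssgsea_alpha)
  amp_peaks <- classified[classified$direction == "amplification", ]
  immune <- NULL
  if (nrow(amp_peaks)) {
    amplified_ids <- amp_peaks$supporting[[1]]
    if (length(amplified_ids) &&
        length(setdiff(tumors, amplified_ids))) {
      immune <- infiltration_contrast(scores, amplified_ids)
      write.table(immune, file.path(out_dir, "immune_contrast.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- report ------------------------------------------------------------
  category_counts <- table(factor(classified$category,
                                  levels = c("contains_driver", "coding",
                                             "lncRNA_only",
                                             "other_noncoding_only",
                                             "gene_desert")))
  report <- list(
    parameters = config[setdiff(names(config), "out_dir")],
    out_dir = out_dir,
    n_peaks = nrow(peaks),
    n_amplifications = sum(peaks$direction == "amplification"),
    n_deletions = sum(peaks$direction == "deletion"),
    category_counts = as.list(category_counts),
    n_lncRNA_only = unname(category_counts[["lncRNA_only"]]),
    n_enriched_tfs = sum(vapply(enrich, function(e) {
      if (is.null(e)) 0L else sum(e$q_value < 0.05)
    }, numeric(1))),
    n_putative_functional = sum(concord$verdicts$putative_functional),
    n_surviving_scnas = nrow(concord$survivors),
    surviving_ranks = concord$survivors$rank,
    n_hypomethylated_cpgs = sum(meth_res$hypomethylated &
                                  !is.na(meth_res$p_value) &
                                  meth_res$p_value < 0.05),
    n_contrasted_signatures = if (is.null(immune)) 0L else nrow(immune)
  )
  report$funnel <- funnel_counts(report, classified, concord)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report)[setdiff(names(report),
                                               c("parameters", "out_dir"))],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @keywords internal
funnel_counts <- function(report, classified, concord) {
  lnc_only <- classified$category == "lncRNA_only"
  list(
    detected = nrow(classified),
    classified = nrow(classified),
    lncRNA_only = sum(lnc_only),
    concordant = sum(lnc_only &
                       classified$rank %in% concord$survivors$rank)
  )
}

#' Funnel table of a run report
#'
#' The selection funnel: detected alterations, classified alterations,
#' lncRNA-only alterations, and lncRNA-only alterations passing the
#' expression concordance screen. Counts are monotone non-increasing.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return data frame with `stage` and `count`.
#' @export
funnel_table <- function(report) {
  f <- report$funnel
  data.frame(stage = c("detected", "classified", "lncRNA_only",
                       "concordant"),
             count = c(f$detected, f$classified, f$lncRNA_only,
                       f$concordant))
}
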