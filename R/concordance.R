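# Expression / methylation concordance screens.
#
# An alteration is "putative functional" when at least one contained
# lncRNA changes expression between tumor and normal in the direction of
# the copy-number change (higher in tumor for amplifications, lower for
# deletions) with Welch-test p below alpha.

#' Welch two-sample t-test
#'
#' Two-tailed unpaired t-test with Welch-Satterthwaite degrees of
#' freedom (no equal-variance assumption).
#'
#' @param x,y numeric vectors, each of length >= 2; at least one group
#'   must have nonzero variance.
#' @return list with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t needs >= 2 observations per group")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      # identical constant groups: no evidence of difference
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    stop("degenerate variances: both groups constant")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Concordance screen of classified alterations
#'
#' For every contained lncRNA of every alteration, tests tumor vs normal
#' expression on the log2(x + 1) scale and checks that the change agrees
#' with the alteration direction. An alteration survives when at least
#' one of its lncRNAs is putative functional.
#'
#' @param classified a `classified_scna` data frame ([classify_peaks()]).
#' @param expression a `labeled_matrix` with tumor and normal samples.
#' @param alpha per-gene significance level (default 0.05, uncorrected:
#'   this is a directional agreement screen, not a discovery procedure).
#' @param annotation gene data frame, used to restrict verdicts to
#'   lncRNA genes; when `NULL` all contained genes are tested.
#' @return list with `verdicts` (data frame: `peak_rank`, `gene_id`,
#'   `direction`, `tumor_mean`, `normal_mean` (linear scale), `t`, `df`,
#'   `p_value`, `direction_match`, `putative_functional`) and `survivors`
#'   (the surviving subset of `classified`).
#' @export
concordance_filter <- function(classified, expression, alpha = 0.05,
                               annotation = NULL) {
  labels <- expression$labels
  if (!any(labels == "normal")) {
    stop("expression matrix has no normal samples; cannot run the screen")
  }
  if (!any(labels == "tumor")) stop("expression matrix has no tumor samples")
  v <- expression$values
  lv <- log2(v + 1)
  tum <- names(labels)[labels == "tumor"]
  nor <- names(labels)[labels == "normal"]
  rows <- list()
  surviving <- logical(nrow(classified))
  for (i in seq_len(nrow(classified))) {
    genes <- classified$genes[[i]]
    if (!is.null(annotation)) {
      bt <- annotation$biotype[match(genes, annotation$gene_id)]
      genes <- genes[!is.na(bt) & bt == "lncRNA"]
    }
    for (gid in genes) {
      if (!gid %in% rownames(v)) {
        warning("gene ", gid, " absent from expression matrix; skipped")
        next
      }
      wt <- welch_t(lv[gid, tum], lv[gid, nor])
      tumor_mean <- mean(v[gid, tum])
      normal_mean <- mean(v[gid, nor])
      match_dir <- if (classified$direction[i] == "amplification") {
        tumor_mean > normal_mean
      } else {
        tumor_mean < normal_mean
      }
      functional <- match_dir && wt$p_value < alpha
      surviving[i] <- surviving[i] || functional
      rows[[length(rows) + 1L]] <- data.frame(
        peak_rank = classified$rank[i], gene_id = gid,
        direction = classified$direction[i],
        tumor_mean = tumor_mean, normal_mean = normal_mean,
        t = wt$t, df = wt$df, p_value = wt$p_value,
        direction_match = match_dir, putative_functional = functional,
        stringsAsFactors = FALSE)
    }
  }
  verdicts <- if (length(rows)) do.call(rbind, rows) else data.frame(
    peak_rank = integer(), gene_id = character(), direction = character(),
    tumor_mean = numeric(), normal_mean = numeric(), t = numeric(),
    df = numeric(), p_value = numeric(), direction_match = logical(),
    putative_functional = logical())
  rownames(verdicts) <- NULL
  list(verdicts = verdicts, survivors = classified[surviving, , drop = FALSE])
}

#' Expression contrast by amplification status
#'
#' Welch test of one gene's expression (log2(x + 1)) between samples
#' with and without the amplification.
#'
#' @param expr named numeric vector of one gene's linear expression
#'   across tumor samples.
#' @param amplified_ids sample ids carrying the amplification; must be a
#'   non-empty, proper subset of `names(expr)`.
#' @return list `t`, `df`, `p_value`, `mean_amplified`, `mean_other`
#'   (linear-scale group means).
#' @export
amplification_group_test <- function(expr, amplified_ids) {
  stopifnot(!is.null(names(expr)))
  amplified_ids <- intersect(amplified_ids, names(expr))
  other <- setdiff(names(expr), amplified_ids)
  if (!length(amplified_ids)) stop("no amplified samples in the matrix")
  if (!length(other)) stop("all samples amplified: empty complement")
  wt <- welch_t(log2(expr[amplified_ids] + 1), log2(expr[other] + 1))
  list(t = wt$t, df = wt$df, p_value = wt$p_value,
       mean_amplified = mean(expr[amplified_ids]),
       mean_other = mean(expr[other]))
}

#' Percent of tumors amplified / expressing a gene
#'
#' A tumor counts as "amplified" when its mean log2 ratio over the focal
#' interval is beyond `amp_threshold` in the alteration direction, and
#' as "expressed" when the gene's linear value exceeds `expr_threshold`
#' (FPKM > 0 by default).
#'
#' @param scna one-row peaks data frame (focal interval + direction).
#' @param segments a `segment_set`.
#' @param expression a `labeled_matrix`.
#' @param gene_id the gene to summarize.
#' @param expr_threshold expression cutoff (default 0).
#' @param amp_threshold |log2| cutoff for the per-sample call.
#' @return list `percent_amplified`, `percent_expressed`,
#'   `percent_amplified_and_expressed`, `n_tumor` (percent scale 0-100).
#' @export
cohort_summary <- function(scna, segments, expression, gene_id,
                           expr_threshold = 0, amp_threshold = 0.1) {
  labels <- segments$labels
  tumors <- names(labels)[labels == "tumor"]
  seg <- segments$segments
  seg <- seg[seg$sample %in% tumors & seg$chromosome == scna$chromosome, ]
  # mean log2 over the focal interval per tumor (width-weighted)
  ov_lo <- pmax(seg$start, scna$focal_start)
  ov_hi <- pmin(seg$end, scna$focal_end)
  keep <- ov_hi > ov_lo
  seg <- seg[keep, ]
  w <- (ov_hi - ov_lo)[keep]
  means <- rowsum(w * seg$log2_ratio, seg$sample)[, 1] /
    rowsum(w, seg$sample)[, 1]
  means <- means[tumors]
  means[is.na(means)] <- 0
  amplified <- if (scna$direction == "amplification") {
    means > amp_threshold
  } else {
    means < -amp_threshold
  }
  ex <- expression$values[gene_id, intersect(tumors,
                                             colnames(expression$values))]
  expressed <- ex > expr_threshold
  common <- intersect(tumors, names(ex))
  list(
    percent_amplified = 100 * mean(amplified),
    percent_expressed = 100 * mean(expressed),
    percent_amplified_and_expressed =
      100 * mean(amplified[common] & expressed[common]),
    n_tumor = length(tumors))
}

#' Differential CpG methylation, tumor vs normal
#'
#' Per-CpG Welch test of beta values between tumor and normal samples,
#' with a hypomethylated-in-tumor flag (tumor mean below normal mean).
#' Degenerate CpGs (constant in both groups at different means cannot be
#' tested) are reported with `NA` p and a note; the run continues.
#'
#' @param meth a `methylation_set` (or `labeled_matrix` of beta values).
#' @return data frame `cpg_id`, `gene_id` (when a CpG map is present),
#'   `tumor_mean`, `normal_mean`, `t`, `df`, `p_value`, `q_value`,
#'   `hypomethylated`, `note`.
#' @export
differential_methylation <- function(meth) {
  labels <- meth$labels
  v <- meth$values
  tum <- names(labels)[labels == "tumor"]
  nor <- names(labels)[labels == "normal"]
  if (!length(tum) || !length(nor)) stop("need tumor and normal samples")
  rows <- lapply(rownames(v), function(cg) {
    x <- v[cg, tum]; y <- v[cg, nor]
    res <- tryCatch(welch_t(x, y), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(cpg_id = cg, tumor_mean = mean(x), normal_mean = mean(y),
                 t = NA_real_, df = NA_real_, p_value = NA_real_,
                 hypomethylated = mean(x) < mean(y),
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(cpg_id = cg, tumor_mean = mean(x), normal_mean = mean(y),
                 t = res$t, df = res$df, p_value = res$p_value,
                 hypomethylated = mean(x) < mean(y), note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  if (!is.null(meth$map)) {
    out$gene_id <- meth$map$gene_id[match(out$cpg_id, meth$map$cpg_id)]
  }
  rownames(out) <- NULL
  out
}
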