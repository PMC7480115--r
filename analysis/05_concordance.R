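#!/usr/bin/env Rscript
# Stage 5: expression concordance. An alteration is kept as "putative
# functional" when a contained lncRNA changes tumor-vs-normal expression
# (Welch test on log2(x+1)) in the direction of the copy-number change.
# Also: amplified-vs-non-amplified expression contrast, percent of
# tumors amplified/expressing, and differential CpG methylation.

suppressPackageStartupMessages(library(scnalnc))

gt <- jsonlite::read_json("results/data/ground_truth.json",
                          simplifyVector = TRUE)
labels <- setNames(unlist(gt$labels), names(gt$labels))
cohort <- read_seg("results/data/cohort.seg", labels = labels)
genes <- read_genes("results/data/genes.gtf")
expression <- read_matrix("results/data/expression.tsv")
peaks <- read.table("results/peaks.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
classified <- classify_peaks(peaks, genes, level = "focal")

res <- concordance_filter(classified, expression, alpha = 0.05,
                          annotation = genes)
write.table(res$verdicts, "results/verdicts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(nrow(res$verdicts), "lncRNA verdict(s);",
    sum(res$verdicts$putative_functional), "putative functional;",
    nrow(res$survivors), "of", nrow(classified),
    "alteration(s) survive the screen\n")
for (i in seq_len(nrow(res$verdicts))) {
  v <- res$verdicts[i, ]
  cat(sprintf("  %s (%s): tumor %.1f vs normal %.1f, t = %.2f, p = %.3g -> %s\n",
              v$gene_id, v$direction, v$tumor_mean, v$normal_mean, v$t,
              v$p_value,
              if (v$putative_functional) "concordant" else "rejected"))
}

# group contrast and cohort summary for the top surviving alteration
if (nrow(res$survivors)) {
  top <- res$survivors[1, ]
  gene <- res$verdicts$gene_id[res$verdicts$putative_functional][1]
  support <- read.table("results/peak_support.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  amp_ids <- support$sample[support$rank == top$rank]
  tumors <- names(labels)[labels == "tumor"]
  gt_test <- amplification_group_test(
    expression$values[gene, tumors], intersect(amp_ids, tumors))
  cat(sprintf("%s amplified (n=%d) vs non-amplified (n=%d) tumors: mean %.1f vs %.1f, t = %.2f, p = %.3g\n",
              gene, length(intersect(amp_ids, tumors)),
              length(tumors) - length(intersect(amp_ids, tumors)),
              gt_test$mean_amplified, gt_test$mean_other, gt_test$t,
              gt_test$p_value))
  cs <- cohort_summary(top, cohort, expression, gene)
  cat(sprintf("Percent of tumors: amplified %.1f%%, expressed (FPKM > 0) %.1f%%, both %.1f%%\n",
              cs$percent_amplified, cs$percent_expressed,
              cs$percent_amplified_and_expressed))
}

# differential CpG methylation, tumor vs normal
meth <- read_matrix("results/data/methylation.tsv")
meth$map <- as.data.frame(gt$cpg_map)
dm <- differential_methylation(meth)
write.table(dm, "results/methylation_welch.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tgt <- dm[dm$gene_id == gt$target$gene_id, ]
cat(sprintf("Target 5' CpGs (%s): beta tumor %.2f vs normal %.2f, min p = %.3g, hypomethylated = %s\n",
            paste(tgt$cpg_id, collapse = ","), mean(tgt$tumor_mean),
            mean(tgt$normal_mean), min(tgt$p_value),
            all(tgt$hypomethylated)))
cat("Wrote results/verdicts.tsv and results/methylation_welch.tsv\n")
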