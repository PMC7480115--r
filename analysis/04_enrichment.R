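#!/usr/bin/env Rscript
# Stage 4: transcription-factor enrichment at the promoters (TSS +/- 1 kb)
# of copy-number-altered lncRNAs, against the all-lncRNA universe, by
# hypergeometric upper-tail test.

suppressPackageStartupMessages(library(scnalnc))

gt <- jsonlite::read_json("results/data/ground_truth.json",
                          simplifyVector = TRUE)
genes <- read_genes("results/data/genes.gtf")
sites <- read_bed("results/data/tf_sites.bed")
classified <- read.table("results/classified.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)

lnc_universe <- genes$gene_id[genes$biotype == "lncRNA"]
altered <- unlist(strsplit(classified$genes[
  classified$direction == "amplification"], ","))
altered <- intersect(altered, lnc_universe)
cat("Testing", length(altered), "amplified lncRNA promoter(s) against",
    length(lnc_universe), "lncRNAs x", length(unique(sites$name)),
    "factors\n")

chrom_len <- setNames(gt$chromosomes$length, gt$chromosomes$name)
windows <- promoter_windows(genes, flank = 1000, chrom_lengths = chrom_len)
tab <- enrichment_table(altered, lnc_universe, windows, sites)
write.table(tab, "results/tf_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- tab[1, ]
cat(sprintf("Top factor: %s (k=%d/%d bound, K=%d/%d universe), p = %.3g (-log10 p = %.2f), q = %.3g\n",
            top$tf, top$k, top$n, top$K, top$N, top$p_value,
            top$neg_log10_p, top$q_value))
cat("Wrote results/tf_enrichment.tsv\n")
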