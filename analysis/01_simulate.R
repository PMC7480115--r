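#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# A 2 x 10 Mb genome with coding genes, lncRNAs, pseudogenes and five
# flagged drivers; a 100-tumor / 30-normal cohort with one recurrent
# amplification planted on an isolated lncRNA (the ground truth all
# later stages are judged against); dosage-coupled expression; TF
# binding sites enriched at the altered lncRNA promoters; promoter CpG
# methylation with the target hypomethylated in tumors; and five immune
# gene signatures.

suppressPackageStartupMessages(library(scnalnc))

SEED <- 42L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- make_genome(n_chrom = 2, chrom_length = 10e6, n_coding = 60,
                      n_lnc = 30, n_driver = 5, n_pseudo = 10, seed = SEED)
target <- isolated_lncrna(genome, bin_size = 10e3)
cat("Genome:", nrow(genome$genes), "genes; planting a 10%-frequency",
    "amplification (|log2| = 1.5) on", target$gene_id, "at",
    sprintf("%s:%d-%d\n", target$chromosome, target$start, target$end))

alt <- planted_alteration(target$chromosome, target$start, target$end,
                          "amplification", carrier_frequency = 0.10,
                          amplitude = 1.5, amplitude_sd = 0.2)
cohort <- simulate_cohort(genome, list(alt), n_tumor = 100, n_normal = 30,
                          seed = SEED + 1L)
cat("Cohort:", sum(cohort$labels == "tumor"), "tumors /",
    sum(cohort$labels == "normal"), "normals;",
    length(cohort$carriers[[1]]), "true carriers\n")

expression <- simulate_expression(genome, cohort, dosage_slope = 1,
                                  seed = SEED + 2L)
sites <- simulate_tf_sites(genome, paste0("TF", 1:8),
                           enriched = list(TF1 = target$gene_id),
                           background_rate = 10, seed = SEED + 3L)
meth <- simulate_methylation(genome, hypo_targets = target$gene_id,
                             n_tumor = 50, n_normal = 50, seed = SEED + 4L)
signatures <- simulate_signatures(genome, 5, 10, seed = SEED + 5L)

write_seg(cohort, file.path(out, "cohort.seg"))
write_genes(genome$genes, file.path(out, "genes.gtf"))
write_bed(sites, file.path(out, "tf_sites.bed"))
write_matrix(expression, file.path(out, "expression.tsv"))
write_matrix(meth, file.path(out, "methylation.tsv"))
write_gmt(signatures, file.path(out, "signatures.gmt"))
jsonlite::write_json(
  list(seed = SEED, target = target,
       carrier_frequency = 0.10, amplitude = 1.5,
       carriers = cohort$carriers[[1]],
       labels = as.list(cohort$labels),
       chromosomes = genome$chromosomes,
       cpg_map = meth$map),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
cat("Wrote SEG/GTF/BED/TSV/GMT inputs and ground truth under", out, "\n")
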