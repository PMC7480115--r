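#!/usr/bin/env Rscript
# Stage 3: biotype classification of the called peaks, and cross-cohort
# collapse: a second, independent cohort carrying the same planted
# amplification is detected and merged with the first by reciprocal
# focal overlap, mimicking recurrence of one alteration across tumor
# types.

suppressPackageStartupMessages(library(scnalnc))

gt <- jsonlite::read_json("results/data/ground_truth.json",
                          simplifyVector = TRUE)
genes <- read_genes("results/data/genes.gtf")
peaks <- read.table("results/peaks.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)

classified <- classify_peaks(peaks, genes, level = "focal", cohort = "cohortA")
counts <- table(classified$category)
cat("Classification of", nrow(classified), "peak(s):",
    paste(names(counts), counts, sep = " = ", collapse = ", "), "\n")
out <- as.data.frame(classified)
out$genes <- vapply(classified$genes, paste, character(1), collapse = ",")
write.table(out, "results/classified.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# an independent cohort with the same planted event
alt <- planted_alteration(gt$target$chromosome, gt$target$start,
                          gt$target$end, "amplification",
                          carrier_frequency = gt$carrier_frequency,
                          amplitude = gt$amplitude)
genome <- make_genome(seed = gt$seed)   # same annotation universe
cohortB <- simulate_cohort(genome, list(alt), n_tumor = 100, n_normal = 0,
                           seed = gt$seed + 100L)
trB <- build_marker_track(cohortB, 10e3, "amplification", 0.1,
                          chromosomes = genome$chromosomes)
trB <- empirical_q(trB, permutation_null(cohortB, trB, 1000,
                                         seed = gt$seed + 101L))
peaksB <- call_alterations(trB, 0.25)
peaksB$cohort <- rep("cohortB", nrow(peaksB))
cat("Cohort B:", nrow(peaksB), "amplification peak(s)\n")

both <- rbind(classified[, c("direction", "chromosome", "focal_start",
                             "focal_end", "cohort")],
              peaksB[, c("direction", "chromosome", "focal_start",
                         "focal_end", "cohort")])
regions <- cross_cohort_collapse(both, min_reciprocal_overlap = 0.25)
regions$cohorts <- vapply(regions$cohorts, paste, character(1),
                          collapse = ",")
cat(nrow(regions), "unique region(s);",
    sum(regions$specific), "cohort-specific,",
    sum(!regions$specific), "shared across cohorts\n")
write.table(regions, "results/unique_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
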