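# Hand-built fixtures used across test files.

# a segment set where every listed sample has one flat profile per
# chromosome, optionally with extra event segments layered on top
flat_segment_set <- function(samples, chrom_len = 10e6, value = 0,
                             chromosomes = "chr1", labels = NULL,
                             events = NULL) {
  rows <- expand.grid(sample = samples, chromosome = chromosomes,
                      stringsAsFactors = FALSE)
  rows$start <- 0
  rows$end <- chrom_len
  rows$log2_ratio <- value
  if (!is.null(events)) {
    # events: data.frame(sample, chromosome, start, end, log2_ratio)
    pieces <- list()
    for (i in seq_len(nrow(rows))) {
      ev <- events[events$sample == rows$sample[i] &
                     events$chromosome == rows$chromosome[i], , drop = FALSE]
      if (!nrow(ev)) {
        pieces[[length(pieces) + 1L]] <- rows[i, ]
        next
      }
      cuts <- sort(unique(c(0, chrom_len, ev$start, ev$end)))
      st <- cuts[-length(cuts)]; en <- cuts[-1]
      val <- rep(value, length(st))
      for (j in seq_len(nrow(ev))) {
        inside <- st >= ev$start[j] & en <= ev$end[j]
        val[inside] <- val[inside] + ev$log2_ratio[j]
      }
      pieces[[length(pieces) + 1L]] <- data.frame(
        sample = rows$sample[i], chromosome = rows$chromosome[i],
        start = st, end = en, log2_ratio = val, stringsAsFactors = FALSE)
    }
    rows <- do.call(rbind, pieces)
  }
  if (is.null(labels)) labels <- setNames(rep("tumor", length(samples)),
                                          samples)
  structure(list(segments = rows, labels = labels, carriers = list()),
            class = "segment_set")
}

# minimal annotation table for classification tests
toy_annotation <- function() {
  data.frame(
    gene_id = c("DRV1", "PC1", "PC2", "LNC1", "LNC2", "PS1"),
    chromosome = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1"),
    start = c(1e5, 3e5, 5e5, 7e5, 9e5, 11e5),
    end = c(2e5, 4e5, 6e5, 8e5, 10e5, 12e5),
    strand = c("+", "-", "+", "+", "-", "+"),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lncRNA", "lncRNA", "pseudogene"),
    driver = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# one-row peak covering [lo, hi) at every level
toy_peak <- function(lo, hi, chromosome = "chr1",
                     direction = "amplification", rank = 1L) {
  data.frame(direction = direction, chromosome = chromosome,
             region_start = lo, region_end = hi,
             enlarged_start = lo, enlarged_end = hi,
             focal_start = lo, focal_end = hi,
             g_score = 1, q_value = 0.01, n_support = 1L,
             rank = rank, stringsAsFactors = FALSE)
}

# a small labeled expression matrix built from explicit group means
toy_expression <- function(gene_ids, tumor_means, normal_means,
                           n_tumor = 10, n_normal = 10, sd = 0, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("T%02d", seq_len(n_tumor)),
               sprintf("N%02d", seq_len(n_normal)))
  labels <- setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                     samples)
  values <- rbind()
  values <- t(vapply(seq_along(gene_ids), function(i) {
    c(rnorm(n_tumor, tumor_means[i], sd), rnorm(n_normal, normal_means[i], sd))
  }, numeric(n_tumor + n_normal)))
  dimnames(values) <- list(gene_ids, samples)
  structure(list(values = pmax(values, 0), labels = labels),
            class = "labeled_matrix")
}
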