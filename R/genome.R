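#' Build a synthetic genome annotation
#'
#' Places non-overlapping genes of three biotypes (`protein_coding`,
#' `lncRNA`, `pseudogene`) on a set of chromosomes. A subset of the
#' protein-coding genes is flagged as known cancer drivers. Strands are
#' assigned uniformly at random; the transcription start site (TSS) is the
#' interval start on the + strand and the interval end on the - strand.
#' Coordinates are 0-based half-open.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp (recycled).
#' @param n_coding,n_lnc,n_driver,n_pseudo gene counts per biotype;
#'   `n_driver` protein-coding genes (`n_driver <= n_coding`) carry the
#'   driver flag.
#' @param gene_length_range min/max gene length in bp; lengths are drawn
#'   uniformly.
#' @param seed integer seed; output is deterministic for a fixed seed.
#' @param max_attempts rejection-sampling attempts per gene before a
#'   capacity error is raised.
#'
#' @return An object of class `genome_spec`: a list with `chromosomes`
#'   (data frame: `name`, `length`), `genes` (data frame: `gene_id`,
#'   `chromosome`, `start`, `end`, `strand`, `biotype`, `driver`, `tss`)
#'   and `seed`.
#' @export
make_genome <- function(n_chrom = 2, chrom_length = 10e6,
                        n_coding = 60, n_lnc = 30, n_driver = 5,
                        n_pseudo = 10,
                        gene_length_range = c(5e3, 3e4),
                        seed = 1, max_attempts = 1000) {
  stopifnot(n_chrom >= 1, all(chrom_length >= 1),
            n_coding >= 0, n_lnc >= 0, n_pseudo >= 0,
            n_driver >= 0, n_driver <= n_coding)
  set.seed(as.integer(seed))
  chroms <- data.frame(
    name = paste0("chr", seq_len(n_chrom)),
    length = as.numeric(rep_len(chrom_length, n_chrom)),
    stringsAsFactors = FALSE
  )

  biotypes <- c(rep("protein_coding", n_coding),
                rep("lncRNA", n_lnc),
                rep("pseudogene", n_pseudo))
  n_genes <- length(biotypes)
  if (n_genes == 0L) {
    genes <- data.frame(gene_id = character(), chromosome = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), biotype = character(),
                        driver = logical(), tss = numeric(),
                        stringsAsFactors = FALSE)
    return(structure(list(chromosomes = chroms, genes = genes, seed = seed),
                     class = "genome_spec"))
  }

  # rejection-sample non-overlapping placements, per chromosome
  placed <- vector("list", n_genes)
  occupied <- lapply(chroms$name, function(x) IRanges::IRanges())
  names(occupied) <- chroms$name
  for (i in seq_len(n_genes)) {
    len <- floor(runif(1, gene_length_range[1], gene_length_range[2] + 1))
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      ci <- sample.int(nrow(chroms), 1)
      L <- chroms$length[ci]
      if (L < len) next
      start <- floor(runif(1, 0, L - len + 1))
      cand <- IRanges::IRanges(start + 1, start + len)  # 1-based closed for IRanges
      if (!any(IRanges::overlapsAny(cand, occupied[[ci]]))) {
        occupied[[ci]] <- c(occupied[[ci]], cand)
        placed[[i]] <- list(chromosome = chroms$name[ci],
                            start = start, end = start + len)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("capacity error: could not place gene ", i, " of ", n_genes,
           " without overlap in ", max_attempts, " attempts")
    }
  }

  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  prefix <- c(protein_coding = "PC", lncRNA = "LNC", pseudogene = "PS")
  idx_within <- stats::ave(seq_len(n_genes), biotypes, FUN = seq_along)
  genes <- data.frame(
    gene_id = sprintf("%s%03d", prefix[biotypes], idx_within),
    chromosome = vapply(placed, `[[`, character(1), "chromosome"),
    start = vapply(placed, `[[`, numeric(1), "start"),
    end = vapply(placed, `[[`, numeric(1), "end"),
    strand = strand,
    biotype = biotypes,
    driver = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_driver > 0) {
    genes$driver[sample(which(genes$biotype == "protein_coding"), n_driver)] <- TRUE
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes <- genes[order(genes$chromosome, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  out <- structure(list(chromosomes = chroms, genes = genes, seed = seed),
                   class = "genome_spec")
  validate_genome(out)
  out
}

#' @keywords internal
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  g <- genome$genes
  if (anyDuplicated(g$gene_id)) stop("gene ids are not unique")
  if (!all(g$biotype %in% c("protein_coding", "lncRNA", "pseudogene"))) {
    stop("unknown biotype")
  }
  if (any(g$driver & g$biotype != "protein_coding")) {
    stop("driver flag on a non-protein-coding gene")
  }
  if (nrow(g)) {
    L <- setNames(genome$chromosomes$length, genome$chromosomes$name)
    if (!all(g$chromosome %in% names(L))) stop("gene on unknown chromosome")
    if (any(g$start < 0) || any(g$end > L[g$chromosome]) ||
        any(g$start >= g$end)) {
      stop("gene interval outside chromosome bounds")
    }
  }
  invisible(genome)
}

#' Describe a planted copy-number alteration
#'
#' Ground-truth description of one recurrent alteration to plant into a
#' simulated cohort. Carriers receive a log2-ratio shift of
#' `Normal(amplitude, amplitude_sd)` over the interval (negated for
#' deletions); each tumor is a carrier independently with probability
#' `carrier_frequency`.
#'
#' @param chromosome chromosome name.
#' @param start,end interval (0-based half-open, bp).
#' @param direction `"amplification"` or `"deletion"`.
#' @param carrier_frequency fraction of tumors carrying the event, in (0, 1].
#' @param amplitude mean absolute log2 ratio in carriers (> 0).
#' @param amplitude_sd standard deviation of the carrier amplitude.
#' @return A `planted_alteration` list.
#' @export
planted_alteration <- function(chromosome, start, end,
                               direction = c("amplification", "deletion"),
                               carrier_frequency = 0.5,
                               amplitude = 1.5, amplitude_sd = 0.2) {
  direction <- match.arg(direction)
  stopifnot(start >= 0, start < end,
            carrier_frequency > 0, carrier_frequency <= 1,
            amplitude > 0, amplitude_sd >= 0)
  structure(list(chromosome = chromosome, start = start, end = end,
                 direction = direction,
                 carrier_frequency = carrier_frequency,
                 amplitude = amplitude, amplitude_sd = amplitude_sd),
            class = "planted_alteration")
}

#' Pick an isolated lncRNA and its plantable interval
#'
#' Returns the lncRNA whose nearest same-chromosome neighbor gene is
#' farthest away (at least `min_gap` bp on both sides), together with a
#' planting interval: the gene body widened to marker-bin boundaries.
#' Planting an alteration on this interval guarantees that any focal
#' sub-run of the called peak overlaps the lncRNA and no other gene, so
#' the called alteration classifies as lncRNA-only.
#'
#' @param genome a `genome_spec`.
#' @param bin_size marker bin size the interval is aligned to.
#' @param min_gap required clearance to the nearest neighbor gene (bp).
#' @return list with `gene_id`, `chromosome`, `start`, `end` (the
#'   bin-aligned planting interval).
#' @export
isolated_lncrna <- function(genome, bin_size = 10e3, min_gap = 50e3) {
  g <- genome$genes
  lnc <- g[g$biotype == "lncRNA", ]
  if (!nrow(lnc)) stop("genome has no lncRNA genes")
  gap <- vapply(seq_len(nrow(lnc)), function(i) {
    othr <- g[g$chromosome == lnc$chromosome[i] &
                g$gene_id != lnc$gene_id[i], ]
    if (!nrow(othr)) return(Inf)
    min(pmax(othr$start - lnc$end[i], lnc$start[i] - othr$end))
  }, numeric(1))
  best <- which.max(gap)
  if (gap[best] < min_gap + 2 * bin_size) {
    stop("no lncRNA with >= ", min_gap, " bp clearance; regenerate genome")
  }
  start <- floor(lnc$start[best] / bin_size) * bin_size
  end <- ceiling(lnc$end[best] / bin_size) * bin_size
  list(gene_id = lnc$gene_id[best], chromosome = lnc$chromosome[best],
       start = start, end = end)
}
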