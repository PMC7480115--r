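# Classification of called alterations by the biotypes of contained genes.

#' Genes inside a peak interval
#'
#' A gene is "inside" when its gene body overlaps the chosen peak
#' interval by at least 1 bp (overlap, not containment).
#'
#' @param peak one-row `scna_peaks` data frame (or list with interval
#'   fields).
#' @param annotation gene data frame (`gene_id`, `chromosome`, `start`,
#'   `end`, `biotype`, `driver`, ...).
#' @param level `"focal"` (default), `"enlarged"` or `"region"`.
#' @return character vector of gene ids (empty for gene deserts).
#' @export
genes_in_peak <- function(peak, annotation,
                          level = c("focal", "enlarged", "region")) {
  level <- match.arg(level)
  lo <- peak[[paste0(level, "_start")]]
  hi <- peak[[paste0(level, "_end")]]
  if (!peak$chromosome %in% annotation$chromosome) {
    warning("chromosome ", peak$chromosome, " absent from annotation")
    return(character())
  }
  g <- annotation[annotation$chromosome == peak$chromosome, ]
  hit <- g$start < hi & g$end > lo            # >= 1 bp overlap, half-open
  g$gene_id[hit]
}

#' Classify an alteration by its contained genes
#'
#' Precedence: any driver gene gives `contains_driver`; else any
#' protein-coding gene gives `coding`; else all-lncRNA gives
#' `lncRNA_only`; any other non-empty set (pseudogenes, mixed noncoding)
#' gives `other_noncoding_only`; an empty set is a `gene_desert`.
#'
#' @param gene_ids character vector of gene ids inside the alteration.
#' @param annotation gene data frame.
#' @return one of `"contains_driver"`, `"coding"`, `"lncRNA_only"`,
#'   `"other_noncoding_only"`, `"gene_desert"`.
#' @export
classify_scna <- function(gene_ids, annotation) {
  if (!length(gene_ids)) return("gene_desert")
  idx <- match(gene_ids, annotation$gene_id)
  if (anyNA(idx)) {
    stop("unknown gene id: ", paste(gene_ids[is.na(idx)], collapse = ", "))
  }
  g <- annotation[idx, ]
  if (any(g$driver)) return("contains_driver")
  if (any(g$biotype == "protein_coding")) return("coding")
  if (all(g$biotype == "lncRNA")) return("lncRNA_only")
  "other_noncoding_only"
}

#' Classify every called peak
#'
#' @param peaks an `scna_peaks` data frame.
#' @param annotation gene data frame.
#' @param level peak level used for gene containment (default focal).
#' @param cohort optional cohort label attached to each row.
#' @return A `classified_scna` data frame: the peaks plus `genes`
#'   (list column), `n_genes`, `category` and `cohort`.
#' @export
classify_peaks <- function(peaks, annotation,
                           level = c("focal", "enlarged", "region"),
                           cohort = NA_character_) {
  level <- match.arg(level)
  genes <- lapply(seq_len(nrow(peaks)), function(i) {
    genes_in_peak(peaks[i, ], annotation, level)
  })
  peaks$genes <- I(genes)
  peaks$n_genes <- lengths(genes)
  peaks$category <- vapply(genes, classify_scna, character(1),
                           annotation = annotation)
  peaks$cohort <- rep(cohort, nrow(peaks))
  class(peaks) <- c("classified_scna", class(peaks))
  peaks
}

#' Collapse peaks across cohorts into unique regions
#'
#' Same-direction focal peaks from different cohorts merge when their
#' reciprocal overlap (overlap width divided by each peak's width) is at
#' least `min_reciprocal_overlap` for both; merging is transitive
#' (single linkage). Each merged region spans the union of its members
#' and lists the member cohorts.
#'
#' @param peaks a peaks data frame carrying a `cohort` column.
#' @param min_reciprocal_overlap threshold in (0, 1], default 0.25.
#' @return data frame of unique regions: `direction`, `chromosome`,
#'   `start`, `end`, `n_peaks`, `cohorts` (list column),
#'   `shared_across` (number of distinct cohorts), `specific` (logical).
#' @export
cross_cohort_collapse <- function(peaks, min_reciprocal_overlap = 0.25) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  # accept either raw peaks (focal_*) or already-collapsed regions
  if (!"focal_start" %in% names(peaks) && "start" %in% names(peaks)) {
    peaks$focal_start <- peaks$start
    peaks$focal_end <- peaks$end
  }
  if (!"cohort" %in% names(peaks) && "cohorts" %in% names(peaks)) {
    peaks$cohort <- NA
  }
  n <- nrow(peaks)
  if (!n) {
    return(data.frame(direction = character(), chromosome = character(),
                      start = numeric(), end = numeric(),
                      n_peaks = integer(), shared_across = integer(),
                      specific = logical()))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (peaks$direction[i] != peaks$direction[j]) next
      if (peaks$chromosome[i] != peaks$chromosome[j]) next
      ov <- min(peaks$focal_end[i], peaks$focal_end[j]) -
        max(peaks$focal_start[i], peaks$focal_start[j])
      if (ov <= 0) next
      wi <- peaks$focal_end[i] - peaks$focal_start[i]
      wj <- peaks$focal_end[j] - peaks$focal_start[j]
      if (ov / wi >= min_reciprocal_overlap &&
          ov / wj >= min_reciprocal_overlap) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    m <- which(comp == cc)
    cohorts <- if ("cohorts" %in% names(peaks)) {
      unique(unlist(peaks$cohorts[m]))
    } else {
      unique(peaks$cohort[m])
    }
    data.frame(direction = peaks$direction[m[1]],
               chromosome = peaks$chromosome[m[1]],
               start = min(peaks$focal_start[m]),
               end = max(peaks$focal_end[m]),
               n_peaks = length(m),
               cohorts = I(list(cohorts)),
               shared_across = length(cohorts),
               specific = length(cohorts) == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
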