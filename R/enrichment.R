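# Promoter transcription-factor enrichment by hypergeometric upper tail.

#' Promoter windows around TSS
#'
#' The promoter of a gene is `[tss - flank, tss + flank)` (strand-aware
#' TSS: interval start on +, interval end on -), clipped to chromosome
#' bounds when lengths are supplied and to zero always.
#'
#' @param genes gene data frame with `tss` (as produced by
#'   [make_genome()] / [read_genes()]).
#' @param flank half-width in bp (default 1 kb each side).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right-side clipping.
#' @return data frame `gene_id`, `chromosome`, `start`, `end`.
#' @export
promoter_windows <- function(genes, flank = 1000, chrom_lengths = NULL) {
  stopifnot(flank > 0)
  start <- pmax(0, genes$tss - flank)
  end <- genes$tss + flank
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, chrom_lengths[genes$chromosome])
  }
  data.frame(gene_id = genes$gene_id, chromosome = genes$chromosome,
             start = start, end = unname(end), stringsAsFactors = FALSE)
}

#' Promoters bound by each transcription factor
#'
#' A promoter is bound by a factor when at least 1 bp of its window
#' overlaps any site of that factor (half-open intervals: abutting does
#' not count).
#'
#' @param windows promoter windows from [promoter_windows()].
#' @param sites site data frame (`chromosome`, `start`, `end`, `name`);
#'   `name` is the factor.
#' @return named list: factor -> character vector of bound gene ids.
#' @export
bound_promoters <- function(windows, sites) {
  tfs <- unique(sites$name)
  out <- setNames(vector("list", length(tfs)), tfs)
  for (tf in tfs) {
    s <- sites[sites$name == tf, ]
    bound <- character()
    for (chrom in unique(s$chromosome)) {
      wi <- which(windows$chromosome == chrom)
      si <- which(s$chromosome == chrom)
      if (!length(wi)) next
      wr <- IRanges::IRanges(windows$start[wi] + 1, windows$end[wi])
      sr <- IRanges::IRanges(s$start[si] + 1, s$end[si])
      hit <- IRanges::overlapsAny(wr, sr)
      bound <- c(bound, windows$gene_id[wi[hit]])
    }
    out[[tf]] <- unique(bound)
  }
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` promoters
#' from a universe of `N` of which `K` are bound, the probability of
#' seeing `k` or more bound. Computed by summing exact terms on the log
#' scale (log-binomial coefficients), so it is stable for large counts.
#'
#' @param k observed bound promoters in the tested set.
#' @param K bound promoters in the universe.
#' @param n size of the tested set.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(length(k) == 1, k >= 0, K >= 0, n >= 0, N >= 1,
            k <= n, k <= K, n <= N, K <= N)
  if (k == 0) return(1)
  i <- k:min(n, K)
  terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(terms)
  min(1, exp(m) * sum(exp(terms - m)))
}

#' Per-factor promoter enrichment table
#'
#' For every factor, tests whether promoters of the altered gene set are
#' over-represented among its bound promoters, against the supplied
#' universe (hypergeometric upper tail). BH q-values across factors are
#' reported as an addition to the raw p-values.
#'
#' @param altered character vector of altered gene ids (must be a subset
#'   of `universe`).
#' @param universe character vector of universe gene ids (typically all
#'   genes of the tested biotype).
#' @param windows promoter windows covering at least the universe.
#' @param sites TF site data frame.
#' @return data frame sorted by p: `tf`, `k`, `n`, `K`, `N`, `p_value`,
#'   `q_value`, `neg_log10_p`.
#' @export
enrichment_table <- function(altered, universe, windows, sites) {
  stopifnot(all(altered %in% universe))
  universe <- unique(universe)
  altered <- unique(altered)
  windows <- windows[windows$gene_id %in% universe, ]
  bound <- bound_promoters(windows, sites)
  N <- length(universe)
  n <- length(altered)
  rows <- lapply(names(bound), function(tf) {
    Kset <- intersect(bound[[tf]], universe)
    K <- length(Kset)
    k <- length(intersect(Kset, altered))
    data.frame(tf = tf, k = k, n = n, K = K, N = N,
               p_value = hypergeom_upper(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric())
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$neg_log10_p <- -log10(out$p_value)
  out <- out[order(out$p_value, out$tf), ]
  rownames(out) <- NULL
  out
}
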