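#' Simulate a segmented copy-number cohort with planted alterations
#'
#' Generates per-sample piecewise-constant log2-ratio profiles emulating
#' segmented SNP-array output. Background segments have exponentially
#' distributed lengths (mean `segment_mean_len`) and means drawn from
#' `Normal(0, noise_sd)`. Each tumor carries each planted alteration
#' independently with its `carrier_frequency`; carriers receive an added
#' shift of `Normal(amplitude, amplitude_sd)` (negated for deletions) over
#' the planted interval. Normal samples receive background noise only.
#'
#' @param genome a `genome_spec` from [make_genome()].
#' @param planted list of [planted_alteration()] objects (may be empty).
#' @param n_tumor,n_normal sample counts; `n_tumor >= 1`.
#' @param noise_sd standard deviation of background segment means.
#' @param segment_mean_len mean background segment length (bp).
#' @param seed integer seed.
#' @return A `segment_set`: list with `segments` (data frame `sample`,
#'   `chromosome`, `start`, `end`, `log2_ratio`; 0-based half-open,
#'   non-overlapping and sorted within sample x chromosome), `labels`
#'   (named vector, `"tumor"`/`"normal"`), and `carriers` (per planted
#'   alteration, the tumor sample ids actually modified).
#' @export
simulate_cohort <- function(genome, planted = list(),
                            n_tumor = 200, n_normal = 30,
                            noise_sd = 0.1, segment_mean_len = 2e6,
                            seed = 1) {
  validate_genome(genome)
  stopifnot(n_tumor >= 1, n_normal >= 0, noise_sd >= 0, segment_mean_len > 0)
  for (p in planted) {
    stopifnot(inherits(p, "planted_alteration"))
    L <- genome$chromosomes$length[match(p$chromosome, genome$chromosomes$name)]
    if (is.na(L) || p$start < 0 || p$end > L) {
      stop("planted interval outside chromosome bounds: ", p$chromosome)
    }
  }
  set.seed(as.integer(seed))

  samples <- c(sprintf("T%03d", seq_len(n_tumor)),
               if (n_normal > 0) sprintf("N%03d", seq_len(n_normal)))
  labels <- setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samples)

  # carrier draws first, in fixed order, so ground truth is reproducible
  tumors <- samples[seq_len(n_tumor)]
  carriers <- lapply(planted, function(p) {
    tumors[runif(n_tumor) < p$carrier_frequency]
  })
  shifts <- lapply(seq_along(planted), function(i) {
    p <- planted[[i]]
    s <- abs(rnorm(length(carriers[[i]]), p$amplitude, p$amplitude_sd))
    if (p$direction == "deletion") s <- -s
    setNames(s, carriers[[i]])
  })

  rows <- vector("list", length(samples) * nrow(genome$chromosomes))
  k <- 0L
  for (s in samples) {
    for (ci in seq_len(nrow(genome$chromosomes))) {
      chrom <- genome$chromosomes$name[ci]
      L <- genome$chromosomes$length[ci]
      # background breakpoints: exponential segment lengths
      brk <- 0
      while (brk[length(brk)] < L) {
        brk <- c(brk, brk[length(brk)] + ceiling(rexp(1, 1 / segment_mean_len)))
      }
      brk[length(brk)] <- L
      brk <- unique(brk)
      bg_val <- rnorm(length(brk) - 1L, 0, noise_sd)

      # planted shifts carried by this sample on this chromosome
      shift_iv <- list()
      if (labels[[s]] == "tumor" && length(planted)) {
        for (i in seq_along(planted)) {
          p <- planted[[i]]
          if (p$chromosome == chrom && s %in% carriers[[i]]) {
            shift_iv[[length(shift_iv) + 1L]] <-
              c(p$start, p$end, shifts[[i]][[s]])
          }
        }
      }
      if (length(shift_iv)) {
        cuts <- sort(unique(c(brk, unlist(lapply(shift_iv, function(x) x[1:2])))))
        cuts <- cuts[cuts >= 0 & cuts <= L]
        st <- cuts[-length(cuts)]
        en <- cuts[-1]
        val <- bg_val[findInterval(st, brk, rightmost.closed = TRUE)]
        for (iv in shift_iv) {
          hit <- st >= iv[1] & en <= iv[2]
          val[hit] <- val[hit] + iv[3]
        }
      } else {
        st <- brk[-length(brk)]
        en <- brk[-1]
        val <- bg_val
      }
      k <- k + 1L
      rows[[k]] <- data.frame(sample = s, chromosome = chrom,
                              start = st, end = en, log2_ratio = val,
                              stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, rows[seq_len(k)])
  rownames(segments) <- NULL
  structure(list(segments = segments, labels = labels, carriers = carriers),
            class = "segment_set")
}

#' @keywords internal
validate_segment_set <- function(x) {
  stopifnot(inherits(x, "segment_set"))
  s <- x$segments
  stopifnot(all(is.finite(s$log2_ratio)), all(s$start < s$end))
  sp <- split(s, list(s$sample, s$chromosome), drop = TRUE)
  for (g in sp) {
    g <- g[order(g$start), ]
    if (any(g$start[-1] < g$end[-nrow(g)])) {
      stop("overlapping segments within sample ", g$sample[1],
           " on ", g$chromosome[1])
    }
  }
  invisible(x)
}

#' Mean log2 copy ratio per gene per sample
#'
#' Width-weighted mean of the segment log2 ratios overlapping each gene
#' body, per sample. Positions not covered by any segment contribute 0.
#'
#' @param genome a `genome_spec`.
#' @param segments a `segment_set`.
#' @return numeric matrix, genes x samples.
#' @export
gene_cn_matrix <- function(genome, segments) {
  genes <- genome$genes
  samples <- names(segments$labels)
  mat <- matrix(0, nrow(genes), length(samples),
                dimnames = list(genes$gene_id, samples))
  seg <- segments$segments
  for (chrom in unique(genes$chromosome)) {
    gi <- which(genes$chromosome == chrom)
    si <- which(seg$chromosome == chrom)
    if (!length(gi) || !length(si)) next
    gr <- IRanges::IRanges(genes$start[gi] + 1, genes$end[gi])
    sr <- IRanges::IRanges(seg$start[si] + 1, seg$end[si])
    ov <- IRanges::findOverlaps(gr, sr)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                            sr[S4Vectors::subjectHits(ov)]))
    val <- seg$log2_ratio[si[S4Vectors::subjectHits(ov)]]
    smp <- seg$sample[si[S4Vectors::subjectHits(ov)]]
    gid <- genes$gene_id[gi[S4Vectors::queryHits(ov)]]
    key <- paste(gid, smp, sep = "\r")
    wsum <- rowsum(w * val, key)
    wtot <- rowsum(w, key)
    parts <- strsplit(rownames(wsum), "\r", fixed = TRUE)
    gids <- vapply(parts, `[[`, character(1), 1L)
    smps <- vapply(parts, `[[`, character(1), 2L)
    # weighted mean over the covered part of the gene body
    mat[cbind(gids, smps)] <- wsum[, 1] / wtot[, 1]
  }
  mat
}

#' Simulate dosage-coupled expression
#'
#' Each gene's log2 expression in a sample is
#' `base_log_expr + dosage_slope * cn + Normal(0, expr_sd)` where `cn` is
#' the sample's mean log2 copy ratio over the gene body. Values are
#' returned on a linear FPKM-like scale (`2^log2expr`, hence >= 0).
#'
#' @param genome a `genome_spec`.
#' @param segments a `segment_set` (provides per-sample dosage and labels).
#' @param dosage_slope copy-number coupling (>= 0; 1 = full coupling).
#' @param base_log_expr baseline log2 expression.
#' @param expr_sd biological noise sd on the log2 scale.
#' @param seed integer seed.
#' @return A `labeled_matrix`: list with `values` (genes x samples, linear
#'   scale) and `labels` (`"tumor"`/`"normal"` per sample).
#' @export
simulate_expression <- function(genome, segments, dosage_slope = 1,
                                base_log_expr = 3, expr_sd = 0.5, seed = 1) {
  stopifnot(dosage_slope >= 0, expr_sd >= 0)
  set.seed(as.integer(seed))
  cn <- gene_cn_matrix(genome, segments)
  logexpr <- base_log_expr + dosage_slope * cn +
    matrix(rnorm(length(cn), 0, expr_sd), nrow(cn), ncol(cn))
  values <- 2^logexpr
  dimnames(values) <- dimnames(cn)
  structure(list(values = values, labels = segments$labels),
            class = "labeled_matrix")
}

#' Simulate transcription-factor binding sites
#'
#' Each gene named in `enriched` receives one 200-bp site of that factor
#' placed inside its TSS +/- 1 kb promoter window; background sites are
#' placed uniformly over the genome at `background_rate` sites per Mb per
#' factor (Poisson counts).
#'
#' @param genome a `genome_spec`.
#' @param tf_names character vector of factor names.
#' @param enriched named list mapping a factor name to a character vector
#'   of gene ids whose promoters it must bind.
#' @param background_rate background sites per Mb per factor.
#' @param site_width site width in bp.
#' @param seed integer seed.
#' @return data frame of intervals (`chromosome`, `start`, `end`, `name`,
#'   `score`, `strand`), 0-based half-open; `name` is the factor.
#' @export
simulate_tf_sites <- function(genome, tf_names, enriched = list(),
                              background_rate = 10, site_width = 200,
                              seed = 1) {
  validate_genome(genome)
  stopifnot(background_rate >= 0, site_width >= 1)
  bad <- setdiff(unlist(enriched), genome$genes$gene_id)
  if (length(bad)) stop("unknown gene id in enriched map: ",
                        paste(bad, collapse = ", "))
  if (length(enriched) && !all(names(enriched) %in% tf_names)) {
    stop("enriched map names a factor absent from tf_names")
  }
  set.seed(as.integer(seed))
  chroms <- genome$chromosomes
  total_mb <- sum(chroms$length) / 1e6
  rows <- list()
  for (tf in tf_names) {
    # planted promoter sites
    for (gid in enriched[[tf]]) {
      g <- genome$genes[genome$genes$gene_id == gid, ]
      L <- chroms$length[match(g$chromosome, chroms$name)]
      lo <- max(0, g$tss - 1000)
      hi <- min(L, g$tss + 1000)
      start <- floor(runif(1, lo, max(lo, hi - site_width) + 1))
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = g$chromosome, start = start,
        end = min(L, start + site_width),
        name = tf, score = 1000, strand = ".", stringsAsFactors = FALSE)
    }
    # background sites
    n_bg <- rpois(1, background_rate * total_mb)
    if (n_bg > 0) {
      pos <- runif(n_bg, 0, sum(chroms$length))
      cum <- c(0, cumsum(chroms$length))
      ci <- findInterval(pos, cum, rightmost.closed = TRUE)
      start <- floor(pos - cum[ci])
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chroms$name[ci], start = start,
        end = pmin(chroms$length[ci], start + site_width),
        name = tf, score = 0, strand = ".", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$start), ]
  rownames(out) <- NULL
  out
}

#' Simulate promoter CpG methylation
#'
#' Gives every gene two CpGs within 500 bp of its TSS. Beta values are
#' `Normal(beta_normal_mean, beta_sd)` clipped to \[0, 1\]; tumors of genes
#' in `hypo_targets` have their mean shifted down by `beta_tumor_delta`
#' (promoter hypomethylation in tumors).
#'
#' @param genome a `genome_spec`.
#' @param hypo_targets character vector of gene ids hypomethylated in
#'   tumors.
#' @param beta_normal_mean,beta_tumor_delta,beta_sd beta-value parameters.
#' @param n_tumor,n_normal sample counts.
#' @param seed integer seed.
#' @return list with `values` (CpG x sample beta matrix), `labels`, and
#'   `map` (data frame `cpg_id`, `gene_id`, `chromosome`, `pos`); class
#'   `methylation_set`.
#' @export
simulate_methylation <- function(genome, hypo_targets = character(),
                                 beta_normal_mean = 0.7,
                                 beta_tumor_delta = 0.2, beta_sd = 0.05,
                                 n_tumor = 50, n_normal = 50, seed = 1) {
  validate_genome(genome)
  stopifnot(beta_normal_mean >= 0, beta_normal_mean <= 1,
            beta_tumor_delta >= 0, beta_sd >= 0, n_tumor >= 1, n_normal >= 1)
  bad <- setdiff(hypo_targets, genome$genes$gene_id)
  if (length(bad)) stop("unknown gene id in hypo_targets: ",
                        paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  genes <- genome$genes
  n_cpg <- 2L * nrow(genes)
  offs <- floor(runif(n_cpg, -500, 500))
  map <- data.frame(
    cpg_id = sprintf("cg%05d", seq_len(n_cpg)),
    gene_id = rep(genes$gene_id, each = 2L),
    chromosome = rep(genes$chromosome, each = 2L),
    pos = pmax(0, rep(genes$tss, each = 2L) + offs),
    stringsAsFactors = FALSE
  )
  samples <- c(sprintf("T%03d", seq_len(n_tumor)),
               sprintf("N%03d", seq_len(n_normal)))
  labels <- setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samples)
  mu <- matrix(beta_normal_mean, n_cpg, length(samples),
               dimnames = list(map$cpg_id, samples))
  target_rows <- map$gene_id %in% hypo_targets
  mu[target_rows, labels == "tumor"] <-
    beta_normal_mean - beta_tumor_delta
  values <- mu + matrix(rnorm(length(mu), 0, beta_sd), n_cpg, length(samples))
  values <- pmin(pmax(values, 0), 1)   # argument order keeps the dims
  dimnames(values) <- dimnames(mu)
  structure(list(values = values, labels = labels, map = map),
            class = "methylation_set")
}

#' Simulate immune-style gene signatures
#'
#' Draws disjoint random signatures from the genome's protein-coding
#' genes (stand-ins for immune cell-population marker sets).
#'
#' @param genome a `genome_spec`.
#' @param n_signatures number of signatures.
#' @param genes_per_signature genes per signature.
#' @param seed integer seed.
#' @return named list of character vectors (GMT-writable).
#' @export
simulate_signatures <- function(genome, n_signatures = 5,
                                genes_per_signature = 10, seed = 1) {
  validate_genome(genome)
  pool <- genome$genes$gene_id[genome$genes$biotype == "protein_coding"]
  need <- n_signatures * genes_per_signature
  if (length(pool) < need) {
    stop("not enough protein-coding genes for ", n_signatures,
         " disjoint signatures of ", genes_per_signature)
  }
  set.seed(as.integer(seed))
  picked <- sample(pool, need)
  sigs <- split(picked, rep(seq_len(n_signatures), each = genes_per_signature))
  names(sigs) <- sprintf("SIG_%02d", seq_len(n_signatures))
  sigs
}
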