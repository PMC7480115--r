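# Rank-based single-sample signature scores and amplification contrasts.

#' Single-sample signature enrichment score
#'
#' Weighted Kolmogorov-Smirnov running-sum (ssGSEA-style) area
#' statistic. Genes are ranked by expression (midranks for ties) and
#' walked in descending order; the running sum gains
#' `rank^alpha / sum(rank^alpha over hits)` at signature genes and loses
#' `1 / #misses` at the rest. The score is the sum of the running-sum
#' values divided by the number of genes. Being rank-based, the score is
#' invariant to any monotone transform of the sample's expression.
#'
#' @param expr named numeric vector of one sample's expression.
#' @param signature character vector of gene ids; must hit at least one
#'   and not all of the genes.
#' @param alpha rank-weight exponent (default 0.25).
#' @return numeric score.
#' @export
ss_enrichment <- function(expr, signature, alpha = 0.25) {
  stopifnot(!is.null(names(expr)), length(expr) >= 2)
  hit <- names(expr) %in% signature
  if (!any(hit) || all(hit)) {
    stop("signature must cover >= 1 and < all genes of the sample")
  }
  r <- rank(expr, ties.method = "average")
  ord <- order(expr, decreasing = TRUE)   # stable: ties keep input order
  hit_o <- hit[ord]
  r_o <- r[ord]
  inc <- numeric(length(expr))
  inc[hit_o] <- r_o[hit_o]^alpha / sum(r_o[hit_o]^alpha)
  inc[!hit_o] <- -1 / sum(!hit_o)
  sum(cumsum(inc)) / length(expr)
}

#' Score signatures across all samples
#'
#' @param expression a `labeled_matrix` (or any list with `values`).
#' @param signatures named list of gene-id vectors.
#' @param alpha rank-weight exponent.
#' @param min_frac minimum fraction of a signature's genes that must be
#'   present in the matrix (default 0.5); absent genes are dropped with
#'   a warning.
#' @return A `signature_scores` object: list with `scores`
#'   (signatures x samples matrix), `alpha`, and the sample `labels`
#'   when present.
#' @export
score_signatures <- function(expression, signatures, alpha = 0.25,
                             min_frac = 0.5) {
  v <- expression$values
  scores <- matrix(NA_real_, length(signatures), ncol(v),
                   dimnames = list(names(signatures), colnames(v)))
  for (sn in names(signatures)) {
    sig <- signatures[[sn]]
    present <- intersect(sig, rownames(v))
    if (length(present) < length(sig)) {
      warning("signature ", sn, ": ", length(sig) - length(present),
              " member(s) absent from the matrix, dropped")
    }
    if (length(present) < min_frac * length(sig)) {
      stop("signature ", sn, ": fewer than ", round(100 * min_frac),
           "% of members present")
    }
    for (j in seq_len(ncol(v))) {
      scores[sn, j] <- ss_enrichment(v[, j], present, alpha)
    }
  }
  structure(list(scores = scores, alpha = alpha,
                 labels = expression$labels),
            class = "signature_scores")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided unpaired test. When the pooled size is at most 20 the p
#' value is exact, by enumeration of all group assignments on the pooled
#' midranks (so ties are handled exactly); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   `NULL` (default) picks exact when the pooled size is at most 20.
#' @return list `W` (rank sum of `x`), `p_value`, `method`
#'   (`"exact"`/`"approx"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y), ties.method = "average")
  W <- sum(r[seq_len(m)])
  if (is.null(exact)) exact <- N <= 20
  if (exact) {
    if (N > 22) stop("exact enumeration limited to pooled size <= 22")
    combs <- combn(N, m)
    Ws <- colSums(matrix(r[combs], nrow = m))
    tol <- 1e-9
    p_le <- mean(Ws <= W + tol)
    p_ge <- mean(Ws >= W - tol)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(W = W, p_value = p, method = "exact"))
  }
  mu <- m * (N + 1) / 2
  ties <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(W = W, p_value = 1, method = "approx"))
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  list(W = W, p_value = min(1, 2 * pnorm(-abs(z))), method = "approx")
}

#' Signature-score contrast by amplification status
#'
#' Per signature: Wilcoxon rank-sum test of scores between amplified and
#' non-amplified samples, with the median difference signed so that a
#' positive value means higher in the amplified group. BH q across
#' signatures.
#'
#' @param scores a `signature_scores` object (or matrix signatures x
#'   samples).
#' @param amplified_ids sample ids with the amplification.
#' @return data frame `signature`, `median_diff`, `W`, `p_value`,
#'   `q_value`, `n_amplified`, `n_other`.
#' @export
infiltration_contrast <- function(scores, amplified_ids) {
  m <- if (inherits(scores, "signature_scores")) scores$scores else scores
  amplified_ids <- intersect(amplified_ids, colnames(m))
  other <- setdiff(colnames(m), amplified_ids)
  if (!length(amplified_ids)) stop("no amplified samples among the scores")
  if (!length(other)) stop("all samples amplified: empty complement")
  rows <- lapply(rownames(m), function(sn) {
    a <- m[sn, amplified_ids]; b <- m[sn, other]
    wt <- wilcoxon_rank_sum(a, b)
    data.frame(signature = sn, median_diff = median(a) - median(b),
               W = wt$W, p_value = wt$p_value,
               n_amplified = length(a), n_other = length(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
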