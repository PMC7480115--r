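# Recurrence scoring of somatic copy-number alterations.
#
# The genome is binned into fixed-size markers. Per direction
# (amplification / deletion) every marker gets: the fraction of tumors
# altered there (|log2 ratio| beyond amp_threshold with the right sign),
# the mean |log2| amplitude over those altered tumors, and the G-score,
# their product. Significance comes from an empirical null built by
# circularly shifting each tumor's marker profile within each chromosome,
# with BH q-values over markers.

#' Marker grid for a genome
#'
#' @param chromosomes data frame with `name` and `length` (as in a
#'   `genome_spec`), or a `genome_spec`.
#' @param bin_size marker bin size in bp.
#' @return data frame `chromosome`, `start`, `end` (0-based half-open).
#' @export
marker_grid <- function(chromosomes, bin_size = 10e3) {
  if (inherits(chromosomes, "genome_spec")) chromosomes <- chromosomes$chromosomes
  stopifnot(bin_size >= 1)
  rows <- lapply(seq_len(nrow(chromosomes)), function(i) {
    L <- chromosomes$length[i]
    start <- seq(0, L - 1, by = bin_size)
    data.frame(chromosome = chromosomes$name[i], start = start,
               end = pmin(start + bin_size, L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# markers x tumor-samples matrix of width-weighted mean log2 ratios
#' @keywords internal
marker_value_matrix <- function(segments, bins) {
  tumors <- names(segments$labels)[segments$labels == "tumor"]
  if (!length(tumors)) stop("no tumor samples in the segment set")
  seg <- segments$segments[segments$segments$sample %in% tumors, ]
  mat <- matrix(0, nrow(bins), length(tumors),
                dimnames = list(NULL, tumors))
  for (chrom in unique(bins$chromosome)) {
    bi <- which(bins$chromosome == chrom)
    si <- which(seg$chromosome == chrom)
    if (!length(si)) next
    br <- IRanges::IRanges(bins$start[bi] + 1, bins$end[bi])
    sr <- IRanges::IRanges(seg$start[si] + 1, seg$end[si])
    ov <- IRanges::findOverlaps(br, sr)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(br[S4Vectors::queryHits(ov)],
                                            sr[S4Vectors::subjectHits(ov)]))
    val <- seg$log2_ratio[si[S4Vectors::subjectHits(ov)]]
    smp <- match(seg$sample[si[S4Vectors::subjectHits(ov)]], tumors)
    bin <- bi[S4Vectors::queryHits(ov)]
    idx <- bin + (smp - 1) * nrow(bins)
    wsum <- rowsum(w * val, idx)
    wtot <- rowsum(w, idx)
    mat[as.integer(rownames(wsum))] <- wsum[, 1] / wtot[, 1]
  }
  mat
}

# frequency / amplitude / G from a marker value matrix
#' @keywords internal
score_markers <- function(values, direction, amp_threshold, n_tumor) {
  altered <- if (direction == "amplification") {
    values > amp_threshold
  } else {
    values < -amp_threshold
  }
  n_alt <- rowSums(altered)
  frequency <- n_alt / n_tumor
  amp_sum <- rowSums(abs(values) * altered)
  amplitude <- ifelse(n_alt > 0, amp_sum / n_alt, 0)
  list(frequency = frequency, amplitude = amplitude,
       g_score = frequency * amplitude)
}

#' Build a per-marker recurrence track
#'
#' Bins the genome at `bin_size`, projects each tumor's segments onto the
#' bins (width-weighted mean log2 ratio), and scores every marker for one
#' direction: frequency of altered tumors, mean |log2| amplitude over the
#' altered tumors, and G-score = frequency x amplitude. A tumor is
#' "altered" at a marker when its value exceeds `amp_threshold`
#' (amplification) or falls below `-amp_threshold` (deletion).
#'
#' @param segments a `segment_set` with at least one tumor sample.
#' @param bin_size marker size in bp.
#' @param direction `"amplification"` or `"deletion"`.
#' @param amp_threshold |log2 ratio| beyond which a sample is altered.
#' @param chromosomes optional chromosome table (`name`, `length`);
#'   inferred from segment extents when missing.
#' @return A `marker_track` data frame (`chromosome`, `start`, `end`,
#'   `frequency`, `amplitude`, `g_score`, `p_value`, `q_value`; p/q are
#'   `NA` until [empirical_q()]), with the per-tumor marker matrix and
#'   parameters kept in attributes.
#' @export
build_marker_track <- function(segments, bin_size = 10e3,
                               direction = c("amplification", "deletion"),
                               amp_threshold = 0.1, chromosomes = NULL) {
  direction <- match.arg(direction)
  stopifnot(bin_size >= 1, amp_threshold > 0)
  if (is.null(chromosomes)) {
    s <- segments$segments
    chromosomes <- aggregate(end ~ chromosome, data = s, FUN = max)
    names(chromosomes) <- c("name", "length")
  }
  bins <- marker_grid(chromosomes, bin_size)
  values <- marker_value_matrix(segments, bins)
  n_tumor <- ncol(values)
  sc <- score_markers(values, direction, amp_threshold, n_tumor)
  track <- data.frame(bins, frequency = sc$frequency,
                      amplitude = sc$amplitude, g_score = sc$g_score,
                      p_value = NA_real_, q_value = NA_real_)
  attr(track, "direction") <- direction
  attr(track, "amp_threshold") <- amp_threshold
  attr(track, "bin_size") <- bin_size
  attr(track, "n_tumor") <- n_tumor
  attr(track, "marker_values") <- values
  class(track) <- c("marker_track", "data.frame")
  track
}

#' Permutation null distribution of G-scores
#'
#' For each permutation, each tumor's per-marker value vector is
#' circularly shifted by an independent uniform offset within each
#' chromosome, and the track is rescored; the pooled G-scores over
#' markers x permutations form the null. Within-sample segment structure
#' (autocorrelation, amplitude spectrum) is preserved; only cross-sample
#' alignment is destroyed.
#'
#' @param segments the `segment_set` the track was built from (kept for
#'   interface symmetry; values are taken from the track's cached marker
#'   matrix).
#' @param track a `marker_track` from [build_marker_track()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; the null is deterministic for a fixed seed.
#' @return numeric vector of pooled null G-scores (class `g_null`), with
#'   `n_perm` as an attribute.
#' @export
permutation_null <- function(segments, track, n_perm = 1000, seed = 1) {
  stopifnot(inherits(track, "marker_track"), n_perm >= 100)
  set.seed(as.integer(seed))
  values <- attr(track, "marker_values")
  direction <- attr(track, "direction")
  thr <- attr(track, "amp_threshold")
  n_tumor <- ncol(values)
  chrom <- track$chromosome
  chrom_idx <- split(seq_len(nrow(track)), chrom)

  # altered indicator and its amplitude contribution; circular shifts
  # commute with these per-element transforms, so shift the summaries
  altered <- if (direction == "amplification") values > thr else values < -thr
  contrib <- abs(values) * altered

  null <- lapply(chrom_idx, function(idx) {
    m <- length(idx)
    # offsets drawn in R so all randomness flows through set.seed
    offsets <- matrix(sample.int(m, n_perm * n_tumor, replace = TRUE) - 1L,
                      n_perm, n_tumor)
    perm_null_chrom(matrix(as.integer(altered[idx, , drop = FALSE]),
                           m, n_tumor),
                    contrib[idx, , drop = FALSE], offsets, n_tumor)
  })
  structure(unlist(null, use.names = FALSE), n_perm = n_perm,
            class = "g_null")
}

#' Empirical p and BH q-values for a marker track
#'
#' `p(marker) = (1 + #\{null >= G\}) / (1 + #null)`; q by
#' Benjamini-Hochberg step-up over all markers of the track's direction.
#'
#' @param track a `marker_track`.
#' @param null a `g_null` from [permutation_null()].
#' @return the track with `p_value` and `q_value` filled; the sorted null
#'   is cached in an attribute for downstream peel-off rescoring.
#' @export
empirical_q <- function(track, null) {
  if (!length(null)) stop("empty null distribution")
  ns <- sort(as.numeric(null))
  n_null <- length(ns)
  # #{null >= g} = n_null - #{null < g}
  p <- (1 + n_null - findInterval(track$g_score, ns, left.open = TRUE)) /
    (1 + n_null)
  track$p_value <- p
  track$q_value <- p.adjust(p, method = "BH")
  attr(track, "null_sorted") <- ns
  track
}

# largest G-score that still fails significance, from the original BH cut
#' @keywords internal
g_significance_cut <- function(track) {
  ns <- attr(track, "null_sorted")
  if (is.null(ns)) stop("track has no null; run empirical_q() first")
  q_threshold <- attr(track, "q_threshold")
  sig <- track$q_value < q_threshold
  if (!any(sig)) return(Inf)
  p_cut <- max(track$p_value[sig])
  # smallest G with empirical p <= p_cut
  n_null <- length(ns)
  k <- ceiling(p_cut * (1 + n_null)) - 1          # max allowed #{null >= g}
  if (k <= 0) return(ns[n_null] + .Machine$double.eps)
  ns[n_null - k + 1]                              # g >= this => p <= p_cut
}

# map an empirical p back to a q via the original BH step-up curve
#' @keywords internal
q_of_p <- function(track, p) {
  o <- order(track$p_value)
  ps <- track$p_value[o]
  qs <- track$q_value[o]
  i <- findInterval(p, ps)
  ifelse(i == 0, qs[1], qs[pmax(1, i)])
}

#' Call significant recurrent alterations (peaks)
#'
#' A *region* is a maximal run of contiguous markers with
#' `q < q_threshold` on one chromosome. Within a region the *focal peak*
#' is the widest run of markers tied at the maximal G-score, and the
#' *enlarged peak* is the contiguous superset of the focal run keeping
#' `G >= (1 - enlarged_epsilon) * peak G`. After a peak is recorded, its
#' supporting tumors (altered at any focal marker) are peeled off across
#' the region, the region is rescored, and further independent peaks are
#' searched until nothing remains significant against the existing null
#' or `max_peaks_per_region` is reached. Peaks are ranked by G-score.
#'
#' @param track a `marker_track` with q-values ([empirical_q()]).
#' @param q_threshold significance threshold on q (default 0.25).
#' @param enlarged_epsilon relative G tolerance for the enlarged peak.
#' @param max_peaks_per_region cap on peel-off iterations per region.
#' @return An `scna_peaks` data frame: one row per peak with `direction`,
#'   `chromosome`, nested `region_*`, `enlarged_*`, `focal_*` intervals
#'   (focal within enlarged within region), `g_score`, `q_value`,
#'   `n_support`, `supporting` (list column of sample ids) and `rank`.
#' @export
call_alterations <- function(track, q_threshold = 0.25,
                             enlarged_epsilon = 0.05,
                             max_peaks_per_region = 5) {
  stopifnot(q_threshold > 0, q_threshold < 1)
  if (anyNA(track$q_value)) stop("track has no q-values; run empirical_q()")
  attr(track, "q_threshold") <- q_threshold
  direction <- attr(track, "direction")
  thr <- attr(track, "amp_threshold")
  values <- attr(track, "marker_values")
  n_tumor <- attr(track, "n_tumor")
  g_cut <- g_significance_cut(track)

  empty <- data.frame(direction = character(), chromosome = character(),
                      region_start = numeric(), region_end = numeric(),
                      enlarged_start = numeric(), enlarged_end = numeric(),
                      focal_start = numeric(), focal_end = numeric(),
                      g_score = numeric(), q_value = numeric(),
                      n_support = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
  empty$supporting <- list()
  sig <- track$q_value < q_threshold
  if (!any(sig)) {
    class(empty) <- c("scna_peaks", "data.frame")
    return(empty)
  }

  # maximal contiguous significant runs per chromosome
  runs <- list()
  for (chrom in unique(track$chromosome[sig])) {
    idx <- which(track$chromosome == chrom)
    s <- sig[idx]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      runs[[length(runs) + 1L]] <- idx[starts[j]:ends[j]]
    }
  }

  peaks <- list()
  for (region in runs) {
    vals <- values[region, , drop = FALSE]
    for (iter in seq_len(max_peaks_per_region)) {
      sc <- score_markers(vals, direction, thr, n_tumor)
      g <- sc$g_score
      if (max(g) < g_cut || max(g) == 0) break
      # focal: widest contiguous run tied at the max G
      tied <- abs(g - max(g)) <= 1e-12
      r <- rle(tied)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      cand <- which(r$values)
      widest <- cand[which.max(r$lengths[cand])]
      f1 <- starts[widest]; f2 <- ends[widest]
      # enlarged: grow while G stays within (1 - eps) of the peak
      keep <- g >= (1 - enlarged_epsilon) * max(g)
      e1 <- f1; e2 <- f2
      while (e1 > 1 && keep[e1 - 1]) e1 <- e1 - 1
      while (e2 < length(g) && keep[e2 + 1]) e2 <- e2 + 1
      focal_idx <- region[f1:f2]
      altered <- if (direction == "amplification") {
        vals[f1:f2, , drop = FALSE] > thr
      } else {
        vals[f1:f2, , drop = FALSE] < -thr
      }
      support <- colnames(vals)[colSums(altered) > 0]
      q_peak <- if (iter == 1L) {
        min(track$q_value[focal_idx])
      } else {
        ns <- attr(track, "null_sorted")
        p_peak <- (1 + length(ns) -
                     findInterval(max(g), ns, left.open = TRUE)) /
          (1 + length(ns))
        q_of_p(track, p_peak)
      }
      peaks[[length(peaks) + 1L]] <- data.frame(
        direction = direction,
        chromosome = track$chromosome[region[1]],
        region_start = track$start[region[1]],
        region_end = track$end[region[length(region)]],
        enlarged_start = track$start[region[e1]],
        enlarged_end = track$end[region[e2]],
        focal_start = track$start[region[f1]],
        focal_end = track$end[region[f2]],
        g_score = max(g), q_value = q_peak,
        n_support = length(support),
        supporting = I(list(support)),
        stringsAsFactors = FALSE)
      if (!length(support)) break
      vals[, support] <- 0    # peel off supporting samples across region
    }
  }
  if (!length(peaks)) {
    class(empty) <- c("scna_peaks", "data.frame")
    return(empty)
  }
  out <- do.call(rbind, peaks)
  out <- out[order(-out$g_score), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("scna_peaks", "data.frame")
  out
}

#' Peel a peak's supporting samples out of a track
#'
#' Removes the contribution of every tumor whose marker values at the
#' peak's focal interval are altered (beyond the track's threshold, in
#' the track's direction) across the enclosing region, rescores the
#' region, and refreshes p/q for the region's markers against the
#' existing null. G-scores never increase.
#'
#' @param track a `marker_track` with q-values and cached null.
#' @param segments the originating `segment_set` (interface symmetry).
#' @param peak one-row `scna_peaks` data frame (or a list with
#'   `chromosome`, `region_start`, `region_end`, `focal_start`,
#'   `focal_end`).
#' @return the residual `marker_track`.
#' @export
peel_off <- function(track, segments, peak) {
  direction <- attr(track, "direction")
  thr <- attr(track, "amp_threshold")
  values <- attr(track, "marker_values")
  n_tumor <- attr(track, "n_tumor")
  region <- which(track$chromosome == peak$chromosome &
                    track$start >= peak$region_start &
                    track$end <= peak$region_end)
  focal <- which(track$chromosome == peak$chromosome &
                   track$start >= peak$focal_start &
                   track$end <= peak$focal_end)
  fv <- values[focal, , drop = FALSE]
  altered <- if (direction == "amplification") fv > thr else fv < -thr
  support <- colnames(values)[colSums(altered) > 0]
  values[region, support] <- 0
  sc <- score_markers(values[region, , drop = FALSE], direction, thr, n_tumor)
  track$frequency[region] <- sc$frequency
  track$amplitude[region] <- sc$amplitude
  track$g_score[region] <- sc$g_score
  ns <- attr(track, "null_sorted")
  if (!is.null(ns)) {
    p <- (1 + length(ns) -
            findInterval(track$g_score[region], ns, left.open = TRUE)) /
      (1 + length(ns))
    q <- q_of_p(track, p)   # map through the original BH curve
    track$p_value[region] <- p
    track$q_value[region] <- q
  }
  attr(track, "marker_values") <- values
  track
}
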