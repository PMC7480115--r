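# Independent oracles, kept deliberately naive: each recomputes the
# quantity by brute force / textbook formula, without touching the
# implementation path it checks.

# Benjamini-Hochberg step-up, written from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# hypergeometric upper tail by exhaustive draw enumeration:
# universe of N promoters, the first K bound; draw all subsets of size n
hyper_upper_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Welch test from the textbook formulas
welch_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / m + vy / n
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / m)^2 / (m - 1) + (vy / n)^2 / (n - 1))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# exact two-sided Wilcoxon by enumerating every assignment of the pooled
# midranks to the first group
wilcoxon_oracle <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y), ties.method = "average")
  W_obs <- sum(r[seq_len(m)])
  sets <- combn(length(r), m)
  Ws <- apply(sets, 2, function(ix) sum(r[ix]))
  tol <- 1e-9
  min(1, 2 * min(mean(Ws <= W_obs + tol), mean(Ws >= W_obs - tol)))
}

# weighted-KS running-sum area, step by step
ss_oracle <- function(expr, signature, alpha) {
  r <- rank(expr, ties.method = "average")
  ord <- order(expr, decreasing = TRUE)
  walk <- 0
  total <- 0
  hits <- names(expr) %in% signature
  denom_hit <- sum(r[hits]^alpha)
  n_miss <- sum(!hits)
  for (i in ord) {
    walk <- walk + if (hits[i]) r[i]^alpha / denom_hit else -1 / n_miss
    total <- total + walk
  }
  unname(total / length(expr))
}
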