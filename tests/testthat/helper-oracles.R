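# Independent oracle implementations used to validate the package's
# statistical primitives. These are deliberately naive (enumeration,
# hand formulas, O(n^3) search) and share no code with the implementation.

# Benjamini-Hochberg by the literal step-up formula with cumulative minimum.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  pmin(adj, 1)[order(o)]
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration:
# sum the probabilities of all tables (with the same margins) no more
# probable than the observed one.
oracle_fisher_two_sided <- function(k, n_set, K, N) {
  xs <- max(0, n_set + K - N):min(n_set, K)
  d <- stats::dhyper(xs, K, N - K, n_set)
  obs <- stats::dhyper(k, K, N - K, n_set)
  sum(d[d <= obs * (1 + 1e-7)])
}

# Brute-force complete-linkage agglomeration on a distance matrix:
# at every step merge the pair of clusters with the smallest maximal
# inter-point distance. Returns the partition at k clusters.
oracle_complete_linkage <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  assign <- integer(n)
  for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
  assign
}

# Ordinary per-feature two-group t-test via the closed formula.
oracle_two_group_t <- function(y, g) {
  y1 <- y[g == levels(g)[2]]; y2 <- y[g == levels(g)[1]]
  n1 <- length(y1); n2 <- length(y2)
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / (n1 + n2 - 2)
  est <- mean(y1) - mean(y2)
  t <- est / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(estimate = est, statistic = t, df = n1 + n2 - 2,
    p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# Two partitions describe the same clustering (up to label permutation)?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Small deterministic ExpressionMatrix for IO / pipeline tests.
toy_expression_matrix <- function(n_features = 6, plexes = 2,
                                  days = c(0, 3), seed = 1) {
  set.seed(seed)
  design <- expand.grid(plex = seq_len(plexes), timepoint_days = days)
  design$sample <- sprintf("p%d_d%d", design$plex, design$timepoint_days)
  design$channel <- match(design$timepoint_days, days)
  vals <- matrix(rnorm(n_features * nrow(design), 20, 1),
                 n_features, nrow(design),
                 dimnames = list(sprintf("f%02d", seq_len(n_features)),
                                 design$sample))
  expression_matrix(vals, design)
}
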