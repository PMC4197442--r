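# Independent oracles, deliberately implemented by different means than the
# package code paths they check.

# Rank of each element of v by exhaustive pairwise comparison:
# 1 + (# strictly smaller) + (# equal, excluding self)/2. Missing values get
# the neutral mid-rank (n+1)/2 of the full sample count.
oracle_rank_row <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) { out[i] <- (n + 1) / 2; next }
    smaller <- sum(v < v[i], na.rm = TRUE)
    equal <- sum(v == v[i], na.rm = TRUE) - 1
    out[i] <- 1 + smaller + equal / 2
  }
  out
}

# Brute-force rank-sum ordering: pairwise-counted ranks per gene, summed per
# sample, samples sorted by score with input order breaking ties.
oracle_order <- function(values, genes = rownames(values)) {
  ranks <- t(apply(values[genes, , drop = FALSE], 1, oracle_rank_row))
  scores <- colSums(ranks)
  idx <- order(scores, seq_along(scores))
  list(sample_ids = colnames(values)[idx], scores = unname(scores[idx]))
}

# Upper tail of a chi-square with 6 df in closed form (Erlang survival):
# P(X > x) = exp(-x/2) * (1 + x/2 + x^2/8).
oracle_chisq6_tail <- function(x) exp(-x / 2) * (1 + x / 2 + x^2 / 8)

# O(n^3) brute-force average-linkage agglomeration over a distance matrix.
# Returns the merge heights in order and the partition after each merge
# (list of integer membership vectors), for comparison against hclust via
# cutree.
oracle_agglomerate_average <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  membership <- seq_len(n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(dmat[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_d)
    membership <- vapply(seq_len(n), function(s)
      which(vapply(clusters, function(cl) s %in% cl, logical(1))),
      integer(1))
    partitions <- c(partitions, list(membership))
  }
  list(heights = heights, partitions = partitions)
}

# Two partitions describe the same grouping (labels may differ).
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Random expression matrix with dimnames.
random_matrix <- function(n_genes, n_samples, values = NULL) {
  v <- if (is.null(values)) stats::rnorm(n_genes * n_samples) else
    sample(values, n_genes * n_samples, replace = TRUE)
  expr_matrix(matrix(as.numeric(v), n_genes, n_samples,
                     dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                     sprintf("s%02d", seq_len(n_samples)))))
}

full_signature <- function(matrix)
  gene_signature(rownames(matrix), min_present = 1L)

expect_same_ordering <- function(ord, oracle) {
  expect_identical(ord$sample_ids, oracle$sample_ids)
  expect_equal(ord$scores, oracle$scores, tolerance = 1e-12)
}

# Orderings agree up to permutation within blocks of tied total scores
# (rank-sum ties are resolved by input order, so tie-block internals are
# not comparable across negation or column permutation).
expect_same_up_to_score_ties <- function(ids_a, scores_a, ids_b, scores_b) {
  expect_equal(scores_a, scores_b)
  blocks_a <- split(ids_a, factor(scores_a, levels = unique(scores_a)))
  blocks_b <- split(ids_b, factor(scores_b, levels = unique(scores_b)))
  for (i in seq_along(blocks_a))
    expect_setequal(blocks_a[[i]], blocks_b[[i]])
}
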