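# Shared fixtures and independent brute-force oracles. Oracles are written
# as naive loops so they stay independent of the vectorized implementations
# they check.

# small deterministic CountMatrix built in code
toy_count_matrix <- function(n_genes = 5, n_cells = 4, seed = 11,
                             gene_ids = sprintf("G%02d", seq_len(n_genes)),
                             max_count = 9) {
  set.seed(seed)
  m <- matrix(sample(0:max_count, n_genes * n_cells, replace = TRUE),
              n_genes, n_cells)
  count_matrix(m, gene_ids, sprintf("c%02d", seq_len(n_cells)))
}

tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("tiny", seed = 5)
    cache
  }
})

cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("cohort", seed = 3)
    cache
  }
})

# ---- oracles -------------------------------------------------------------

# mean(set) - mean(all non-set genes): the 1-bin, exhaustive-control case
# of the module score
bf_module_score_1bin <- function(values, set_genes) {
  out <- numeric(ncol(values))
  for (ci in seq_len(ncol(values))) {
    s <- 0; n_s <- 0; c0 <- 0; n_c <- 0
    for (g in rownames(values)) {
      if (g %in% set_genes) { s <- s + values[g, ci]; n_s <- n_s + 1 }
      else { c0 <- c0 + values[g, ci]; n_c <- n_c + 1 }
    }
    out[ci] <- s / n_s - c0 / n_c
  }
  out
}

# naive weighted-ECDF-difference sum for one cell
bf_ssgsea_cell <- function(x, is_set, exponent) {
  r <- rank(x, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  n <- length(x); m <- sum(is_set)
  wsum <- 0
  for (i in ord) if (is_set[i]) wsum <- wsum + r[i]^exponent
  score <- 0; cum_in <- 0; cum_out <- 0
  for (i in ord) {
    if (is_set[i]) cum_in <- cum_in + r[i]^exponent / wsum
    else cum_out <- cum_out + 1 / (n - m)
    score <- score + (cum_in - cum_out)
  }
  unname(score)
}

# naive KS walk max-magnitude deviation for one cell (weight 1); the walk
# is observed only when a whole tie group has been consumed
bf_gsva_walk_cell <- function(x, is_set) {
  r <- rank(x, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  n <- length(x); m <- sum(is_set)
  run <- 0; best <- 0
  for (k in seq_along(ord)) {
    i <- ord[k]
    run <- run + if (is_set[i]) 1 / m else -1 / (n - m)
    group_done <- k == n || r[ord[k + 1]] != r[i]
    if (group_done && abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# naive weighted running-sum enrichment score (weight exponent 1) over an
# already-sorted ranking
bf_gsea_es <- function(weights_sorted, is_set_sorted) {
  n <- length(weights_sorted); m <- sum(is_set_sorted)
  wsum <- sum(abs(weights_sorted)[is_set_sorted])
  p_hit <- 0; p_miss <- 0; best <- 0
  for (i in seq_len(n)) {
    if (is_set_sorted[i]) p_hit <- p_hit + abs(weights_sorted[i]) / wsum
    else p_miss <- p_miss + 1 / (n - m)
    if (abs(p_hit - p_miss) > abs(best)) best <- p_hit - p_miss
  }
  unname(best)
}

# step-up Benjamini-Hochberg, literal definition
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, n * p[ord[k]] / k)
    adj[ord[k]] <- val
    prev <- val
  }
  adj
}

# rank-sum W statistic (Mann-Whitney U of group x), literal definition
bf_ranksum_W <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# pairwise Pearson correlation by the textbook formula
bf_pearson <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}
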