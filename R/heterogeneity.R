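# Transcriptome heterogeneity via pairwise cell-cell correlations,
# summarized within and between patient groups. Lower mean pairwise
# correlation = greater heterogeneity.

#' Pairwise cell-cell correlation matrix
#'
#' Correlations between cell expression profiles over a gene universe
#' (default: all genes in the matrix, i.e. whatever survived QC). Cells
#' with zero variance over the universe yield undefined entries, reported
#' as \code{NA} with a logged count.
#'
#' @param em an \code{ExpressionMatrix} with at least 2 cells.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param gene_subset optional gene symbols restricting the universe (at
#'   least 2 must match).
#' @return A \code{CorrelationMatrix}: cell x cell numeric matrix with
#'   attributes \code{method} and \code{gene_universe}.
#' @export
pairwise_correlation <- function(em, method = c("pearson", "spearman"),
                                 gene_subset = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  method <- match.arg(method)
  if (ncol(em$values) < 2L) {
    degenerate_input_error("need at least 2 cells for pairwise correlation")
  }
  v <- em$values
  if (!is.null(gene_subset)) {
    g <- match_set(gene_subset, em$gene_ids, set_name = "gene_subset")
    if (length(g) < 2L) {
      degenerate_input_error("gene_subset matches fewer than 2 genes")
    }
    v <- v[g, , drop = FALSE]
  }
  zero_var <- apply(v, 2L, stats::sd) == 0
  if (any(zero_var)) {
    message(sprintf("pairwise_correlation: %d cell(s) with zero variance; entries set to NA",
                    sum(zero_var)))
  }
  cc <- suppressWarnings(stats::cor(v, method = method))
  diag(cc) <- 1
  structure(cc, method = method,
            gene_universe = rownames(v),
            class = c("CorrelationMatrix", class(cc)))
}

#' Intra- versus inter-group heterogeneity summary
#'
#' Partitions all unordered cell pairs (diagonal excluded) into same-group
#' (intra) and cross-group (inter) pairs, reports per-group and overall
#' mean coefficients, and compares the two coefficient sets with a
#' two-sided Wilcoxon rank-sum test. The test treats pairs as independent
#' observations, reproducing the conventional procedure; an optional
#' cell-level permutation p-value is available as a robustness check via
#' \code{n_cell_perm}.
#'
#' @param corr a \code{CorrelationMatrix}.
#' @param groups named character vector or factor mapping every cell
#'   (by id) to a group (e.g. patient).
#' @param n_cell_perm if > 0, additionally compute a permutation p-value
#'   by shuffling group labels over cells (default 0 = off).
#' @param seed seed for the optional permutation.
#' @return List (\code{HeterogeneitySummary}): \code{intra_mean} (named,
#'   per group), \code{intra_mean_overall}, \code{inter_mean},
#'   \code{n_intra_pairs}, \code{n_inter_pairs}, \code{wilcoxon_stat},
#'   \code{p_value}, and optionally \code{p_cell_perm}. With a single
#'   group, inter statistics are \code{NA} and flagged via
#'   \code{single_group = TRUE}.
#' @export
heterogeneity_summary <- function(corr, groups, n_cell_perm = 0, seed = 0) {
  cells <- colnames(corr)
  if (is.null(names(groups))) {
    if (length(groups) != length(cells)) {
      validation_error("groups must be named by cell id or match cell count")
    }
    names(groups) <- cells
  }
  g <- as.character(groups[cells])
  if (anyNA(g)) validation_error("every cell must be mapped to a group")

  pair_stats <- function(g) {
    same <- outer(g, g, "==")
    ut <- upper.tri(same)
    vals <- corr[ut]
    list(intra = vals[same[ut]], inter = vals[!same[ut]])
  }
  ps <- pair_stats(g)
  per_group <- vapply(unique(g), function(grp) {
    idx <- which(g == grp)
    if (length(idx) < 2L) return(NA_real_)
    sub <- corr[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }, numeric(1))

  single <- length(unique(g)) < 2L
  if (!single && length(ps$intra) > 0) {
    wt <- suppressWarnings(stats::wilcox.test(ps$intra, ps$inter,
                                              exact = FALSE, correct = TRUE))
    wstat <- unname(wt$statistic)
    pval <- wt$p.value
  } else {
    wstat <- NA_real_
    pval <- NA_real_
  }

  out <- list(intra_mean = per_group,
              intra_mean_overall = mean(ps$intra, na.rm = TRUE),
              inter_mean = if (single) NA_real_ else mean(ps$inter, na.rm = TRUE),
              n_intra_pairs = length(ps$intra),
              n_inter_pairs = length(ps$inter),
              wilcoxon_stat = wstat,
              p_value = pval,
              single_group = single,
              note = "lower mean correlation = greater heterogeneity")
  if (n_cell_perm > 0 && !single) {
    obs_gap <- out$intra_mean_overall - out$inter_mean
    perm_gap <- with_seed(seed, vapply(seq_len(n_cell_perm), function(b) {
      gp <- sample(g)
      pp <- pair_stats(gp)
      mean(pp$intra, na.rm = TRUE) - mean(pp$inter, na.rm = TRUE)
    }, numeric(1)))
    out$p_cell_perm <- (1 + sum(abs(perm_gap) >= abs(obs_gap))) / (1 + n_cell_perm)
  }
  class(out) <- "HeterogeneitySummary"
  out
}

#' @export
print.HeterogeneitySummary <- function(x, ...) {
  cat(sprintf("HeterogeneitySummary: intra mean %.4f (%d pairs), inter mean %s (%d pairs)\n",
              x$intra_mean_overall, x$n_intra_pairs,
              ifelse(is.na(x$inter_mean), "NA", sprintf("%.4f", x$inter_mean)),
              x$n_inter_pairs))
  if (!is.na(x$p_value)) {
    cat(sprintf("  rank-sum W = %.1f, p = %.3g\n", x$wilcoxon_stat, x$p_value))
  }
  invisible(x)
}
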