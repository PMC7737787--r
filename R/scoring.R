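# Gene-set scoring: expression-matched-control module scores, single-sample
# rank enrichment (ssGSEA-style), GSVA-style set-variation scores, and
# preranked GSEA with permutation FDR. These constructions are pinned here
# so results are reproducible independent of any external package.

# Evaluate expr under a fixed RNG state (Mersenne-Twister), restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Module score with expression-matched controls
#'
#' Per-cell mean expression of a gene set minus the mean expression of
#' control genes. All genes are binned into \code{n_bins} quantile bins of
#' their dataset-mean expression; for each set gene, \code{n_ctrl} control
#' genes are drawn from the same bin (excluding set genes), without
#' replacement when the bin is large enough and with replacement otherwise.
#' A positive score means the set is expressed above expression-matched
#' background in that cell.
#'
#' @param em an \code{ExpressionMatrix} (see \code{\link{log_normalize}}).
#' @param set character vector of gene symbols.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl controls drawn per set gene (default 100).
#' @param seed integer seed for the control draw.
#' @return Named numeric vector, one score per cell.
#' @export
module_score <- function(em, set, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"), n_bins >= 1, n_ctrl >= 1)
  matched <- match_set(set, em$gene_ids, quiet = FALSE)
  if (!length(matched)) {
    missing_genes_error(sprintf(
      "none of the %d set gene(s) are present in the matrix: %s",
      length(set), paste(utils::head(set, 10), collapse = ", ")))
  }
  v <- em$values
  n_genes <- nrow(v)
  avg <- rowMeans(v)
  # quantile bins on dataset-mean expression; ties broken by position so the
  # binning is deterministic
  bins <- ceiling(rank(avg, ties.method = "first") * n_bins / n_genes)
  bins[bins < 1L] <- 1L
  set_idx <- match(matched, em$gene_ids)
  is_set <- logical(n_genes)
  is_set[set_idx] <- TRUE
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(set_idx, function(g) {
      cand <- which(bins == bins[g] & !is_set)
      if (!length(cand)) cand <- which(!is_set)
      if (!length(cand)) return(integer())
      if (length(cand) >= n_ctrl) sample(cand, n_ctrl)
      else sample(cand, n_ctrl, replace = TRUE)
    }))
  })
  set_mean <- colMeans(v[set_idx, , drop = FALSE])
  ctrl_mean <- if (length(ctrl_idx)) {
    colMeans(v[ctrl_idx, , drop = FALSE])
  } else {
    rep(0, ncol(v))
  }
  stats::setNames(set_mean - ctrl_mean, em$cell_ids)
}

#' Cell-cycle phase scores
#'
#' Module scores for the G1/S and G2/M phase gene lists, computed with a
#' shared expression binning (the binning depends only on the matrix, so
#' two \code{\link{module_score}} calls share it by construction).
#'
#' @param em an \code{ExpressionMatrix}.
#' @param g1s_genes,g2m_genes phase gene lists; defaults are the bundled
#'   canonical 43/54-gene lists (\code{\link{default_cycle_genes}}).
#' @param n_bins,n_ctrl see \code{\link{module_score}}.
#' @param seed integer seed.
#' @return List with numeric vectors \code{g1s} and \code{g2m} plus the
#'   \code{parameters} used.
#' @export
cycle_scores <- function(em, g1s_genes = NULL, g2m_genes = NULL,
                         n_bins = 24, n_ctrl = 100, seed = 0) {
  if (is.null(g1s_genes) || is.null(g2m_genes)) {
    cc <- default_cycle_genes()
    if (is.null(g1s_genes)) g1s_genes <- cc$G1S
    if (is.null(g2m_genes)) g2m_genes <- cc$G2M
  }
  list(g1s = module_score(em, g1s_genes, n_bins, n_ctrl, seed = seed),
       g2m = module_score(em, g2m_genes, n_bins, n_ctrl, seed = seed + 1L),
       parameters = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed))
}

#' Single-sample rank-enrichment score (ssGSEA-style)
#'
#' Per cell, genes are ranked by expression (average ranks on ties) and the
#' score is the sum over the ranked list of the difference between the
#' exponent-weighted in-set empirical CDF and the unweighted out-of-set
#' CDF. The score depends on within-cell ranks only and is monotone in the
#' set genes' ranks.
#'
#' @param em an \code{ExpressionMatrix}.
#' @param set character vector of gene symbols.
#' @param exponent non-negative rank weight exponent (default 0.25).
#' @return Named numeric vector, one score per cell.
#' @export
ssgsea_score <- function(em, set, exponent = 0.25) {
  stopifnot(inherits(em, "ExpressionMatrix"), exponent >= 0)
  matched <- match_set(set, em$gene_ids)
  if (!length(matched)) {
    missing_genes_error("no gene of the set is present in the matrix")
  }
  is_set <- em$gene_ids %in% matched
  n <- nrow(em$values)
  m <- sum(is_set)
  if (m >= n) {
    degenerate_input_error("set covers the entire gene universe")
  }
  scores <- apply(em$values, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    inset <- is_set[ord]
    w <- (r[ord]^exponent) * inset
    ecdf_in <- cumsum(w) / sum(w)
    ecdf_out <- cumsum(!inset) / (n - m)
    sum(ecdf_in - ecdf_out)
  })
  stats::setNames(scores, em$cell_ids)
}

#' Single-sample immune score
#'
#' Convenience wrapper: \code{\link{ssgsea_score}} of the bundled immune
#' signature (or a user-supplied one). Immune cells score high; tumor
#' cells score low.
#'
#' @param em an \code{ExpressionMatrix}.
#' @param signature immune signature gene list; default the bundled
#'   package-curated signature.
#' @param exponent see \code{\link{ssgsea_score}}.
#' @return Named numeric vector of per-cell immune scores.
#' @export
immune_score <- function(em, signature = NULL, exponent = 0.25) {
  if (is.null(signature)) {
    signature <- default_immune_signature()$immune_signature
  }
  ssgsea_score(em, signature, exponent = exponent)
}

#' GSVA-style set-variation scores
#'
#' Per set and cell: genes are ranked within the cell (average ranks on
#' ties, descending order), a Kolmogorov-Smirnov random walk steps up by
#' 1/m at in-set genes and down by 1/(n - m) otherwise, and the raw score
#' is the signed maximum-magnitude deviation of the walk, observed at
#' tie-group boundaries (tied genes arrive simultaneously, so the block of
#' undetected genes in a sparse cell cannot bias the score). Each set's raw
#' scores are then min-max rescaled across the cells of the analysis to
#' [0, 1] so that an absolute 0.5 cutoff is meaningful; this rescaling is
#' an analysis-level convention (cells enter relative to the cohort they
#' are scored with). A set whose raw scores are constant across cells maps
#' to 0.5 everywhere.
#'
#' @param em an \code{ExpressionMatrix} with at least 2 cells.
#' @param sets a \code{GeneSetLibrary} or named list of gene vectors.
#' @param rescale if \code{FALSE}, return the raw signed walk scores.
#' @return A \code{ScoreMatrix}: set x cell numeric matrix with attributes
#'   \code{score_kind} and \code{parameters}.
#' @export
gsva_like_score <- function(em, sets, rescale = TRUE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 2L && rescale) {
    degenerate_input_error("min-max rescaling needs at least 2 cells")
  }
  n <- nrow(em$values)
  ranks <- apply(em$values, 2L, rank, ties.method = "average")
  ords <- apply(ranks, 2L, order, decreasing = TRUE)
  raw <- matrix(NA_real_, length(sets), ncol(em$values),
                dimnames = list(names(sets), em$cell_ids))
  for (s in names(sets)) {
    matched <- match_set(sets[[s]], em$gene_ids, set_name = s)
    if (!length(matched)) {
      missing_genes_error(sprintf("set '%s' has no gene in the matrix", s))
    }
    is_set <- em$gene_ids %in% matched
    m <- sum(is_set)
    if (m >= n) degenerate_input_error(sprintf("set '%s' covers the whole universe", s))
    for (ci in seq_len(ncol(em$values))) {
      ord <- ords[, ci]
      inset <- is_set[ord]
      walk <- cumsum(ifelse(inset, 1 / m, -1 / (n - m)))
      # tied genes arrive simultaneously: the walk is observed only at
      # tie-group boundaries, so within-tie gene order cannot bias the score
      rv <- ranks[ord, ci]
      at <- c(which(rv[-n] != rv[-1L]), n)
      dev <- walk[at]
      raw[s, ci] <- dev[which.max(abs(dev))]
    }
  }
  out <- raw
  if (rescale) {
    for (s in rownames(out)) {
      rng <- range(out[s, ])
      out[s, ] <- if (rng[2] > rng[1]) (out[s, ] - rng[1]) / (rng[2] - rng[1]) else 0.5
    }
  }
  structure(out,
            score_kind = if (rescale) "gsva" else "gsva_raw",
            parameters = list(rescale = rescale),
            class = c("ScoreMatrix", class(out)))
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent 1)
#' over a preranked gene list, with gene-label permutations for nominal p,
#' sign-matched normalization for NES, and a permutation-based FDR over all
#' tested sets.
#'
#' @param ranking named numeric vector: names are unique gene symbols,
#'   values are ranking weights (e.g. signed log2 fold changes). Sorted
#'   internally by decreasing weight.
#' @param sets a \code{GeneSetLibrary} or named list of gene vectors; sets
#'   with no gene in the ranking are skipped with a warning.
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame with one row per tested set: \code{set}, \code{size},
#'   \code{ES}, \code{NES}, \code{p_nominal}, \code{fdr_q},
#'   \code{leading_edge} (comma-separated genes).
#' @export
preranked_gsea <- function(ranking, sets, n_perm = 1000, seed = 0) {
  stopifnot(is.numeric(ranking), !is.null(names(ranking)), n_perm >= 1)
  if (anyDuplicated(names(ranking))) {
    validation_error("ranking contains duplicate genes")
  }
  ord <- order(ranking, decreasing = TRUE)
  genes <- names(ranking)[ord]
  absw <- unname(abs(ranking[ord]))
  n <- length(genes)

  es_stat <- function(inset) {
    m <- sum(inset)
    wsum <- sum(absw[inset])
    p_hit <- if (wsum > 0) cumsum(absw * inset) / wsum else cumsum(inset) / m
    p_miss <- cumsum(!inset) / (n - m)
    dev <- p_hit - p_miss
    i <- which.max(abs(dev))
    c(es = dev[i], peak = i)
  }

  keep <- vapply(names(sets), function(s) {
    ok <- length(intersect(sets[[s]], genes)) > 0
    if (!ok) warning(sprintf("set '%s' shares no gene with the ranking; skipped", s))
    ok
  }, logical(1))
  sets <- sets[keep]
  if (!length(sets)) return(data.frame())

  res <- lapply(names(sets), function(s) {
    inset <- genes %in% sets[[s]]
    st <- es_stat(inset)
    m <- sum(inset)
    perm <- with_seed(seed + which(names(sets) == s) - 1L, {
      vapply(seq_len(n_perm), function(b) {
        ins <- logical(n)
        ins[sample.int(n, m)] <- TRUE
        es_stat(ins)[["es"]]
      }, numeric(1))
    })
    es <- st[["es"]]
    peak <- st[["peak"]]
    if (es >= 0) {
      pos <- perm[perm >= 0]
      p <- (1 + sum(pos >= es)) / (1 + length(pos))
      nes <- if (length(pos)) es / mean(pos) else NA_real_
      perm_nes <- if (length(pos) && mean(pos) > 0) perm / mean(pos) else rep(NA_real_, n_perm)
      le <- genes[seq_len(peak)][inset[seq_len(peak)]]
    } else {
      neg <- perm[perm < 0]
      p <- (1 + sum(neg <= es)) / (1 + length(neg))
      nes <- if (length(neg)) -es / mean(neg) else NA_real_
      perm_nes <- if (length(neg) && mean(neg) < 0) -perm / mean(neg) else rep(NA_real_, n_perm)
      le <- genes[peak:n][inset[peak:n]]
    }
    list(set = s, size = m, ES = es, NES = nes, p_nominal = p,
         perm_nes = perm_nes, leading_edge = paste(le, collapse = ","))
  })

  obs_nes <- vapply(res, `[[`, numeric(1), "NES")
  all_perm <- unlist(lapply(res, `[[`, "perm_nes"))
  all_perm <- all_perm[is.finite(all_perm)]
  fdr <- vapply(seq_along(res), function(i) {
    nes <- obs_nes[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(all_perm >= nes)
      den <- mean(obs_nes[is.finite(obs_nes)] >= nes)
    } else {
      num <- mean(all_perm <= nes)
      den <- mean(obs_nes[is.finite(obs_nes)] <= nes)
    }
    if (den == 0) return(0)
    min(1, max(0, num / den))
  }, numeric(1))

  data.frame(set = vapply(res, `[[`, character(1), "set"),
             size = vapply(res, `[[`, numeric(1), "size"),
             ES = vapply(res, `[[`, numeric(1), "ES"),
             NES = obs_nes,
             p_nominal = vapply(res, `[[`, numeric(1), "p_nominal"),
             fdr_q = fdr,
             leading_edge = vapply(res, `[[`, character(1), "leading_edge"),
             stringsAsFactors = FALSE)
}
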