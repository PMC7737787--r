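# Two-group differential expression with Benjamini-Hochberg FDR,
# one-vs-rest patient signatures, stage-biased genes, and diagnostic panel
# selection.

#' Two-group differential expression
#'
#' Per gene, compares two disjoint cell groups with either a two-sided
#' Wilcoxon rank-sum test on log-normalized expression (tie-corrected
#' normal approximation with continuity correction; exact when the smaller
#' group has fewer than 8 cells and the data are tie-free) or a simplified
#' negative-binomial Wald test (method-of-moments dispersion on
#' library-size-scaled counts). P-values are Benjamini-Hochberg adjusted
#' over all tested genes. Group means are counts-per-10,000 means and the
#' fold change is \code{log2((mean_a + epsilon) / (mean_b + epsilon))}.
#'
#' @param cm a QC-filtered \code{CountMatrix}.
#' @param group_a,group_b disjoint cell-id sets, each with at least 3 cells.
#' @param method \code{"ranksum"} (default) or \code{"nb_wald"}.
#' @param epsilon pseudocount on CP10K means for the fold change (default 1).
#' @param scale_factor normalization scale (default 1e4).
#' @return data.frame with one row per gene: \code{gene_id}, \code{mean_a},
#'   \code{mean_b}, \code{detect_frac_a}, \code{detect_frac_b},
#'   \code{log2_fc}, \code{p_raw}, \code{p_adj}; attribute \code{method}
#'   records the test used.
#' @export
de_two_group <- function(cm, group_a, group_b,
                         method = c("ranksum", "nb_wald"), epsilon = 1.0,
                         scale_factor = 1e4) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "CountMatrix"))
  if (length(intersect(group_a, group_b))) {
    validation_error("group_a and group_b overlap")
  }
  ia <- match(group_a, cm$cell_ids)
  ib <- match(group_b, cm$cell_ids)
  if (anyNA(ia) || anyNA(ib)) validation_error("unknown cell id in group")
  if (length(ia) < 3L || length(ib) < 3L) {
    degenerate_input_error("each group needs at least 3 cells")
  }

  totals <- Matrix::colSums(cm$counts)
  divisor <- ifelse(totals > 0, totals, 1)
  cp10k <- sweep(as.matrix(cm$counts), 2L, scale_factor / divisor, "*")
  loga <- log1p(cp10k)

  mean_a <- rowMeans(cp10k[, ia, drop = FALSE])
  mean_b <- rowMeans(cp10k[, ib, drop = FALSE])
  det_a <- Matrix::rowMeans(cm$counts[, ia, drop = FALSE] > 0)
  det_b <- Matrix::rowMeans(cm$counts[, ib, drop = FALSE] > 0)
  log2_fc <- log2((mean_a + epsilon) / (mean_b + epsilon))

  n_min <- min(length(ia), length(ib))
  p_raw <- if (method == "ranksum") {
    apply_ranksum(loga, ia, ib, exact = n_min < 8L)
  } else {
    nb_wald_p(cp10k, ia, ib, epsilon)
  }
  p_raw <- pmin(pmax(p_raw, .Machine$double.xmin), 1)
  res <- data.frame(gene_id = cm$gene_ids,
                    mean_a = mean_a, mean_b = mean_b,
                    detect_frac_a = as.numeric(det_a),
                    detect_frac_b = as.numeric(det_b),
                    log2_fc = log2_fc,
                    p_raw = p_raw,
                    p_adj = stats::p.adjust(p_raw, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(res, "method") <- method
  res
}

apply_ranksum <- function(vals, ia, ib, exact) {
  vapply(seq_len(nrow(vals)), function(g) {
    x <- vals[g, ia]
    y <- vals[g, ib]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                        correct = TRUE)$p.value)
  }, numeric(1))
}

# Simplified NB Wald: delta-method z test on log group means with a
# method-of-moments common dispersion per gene.
nb_wald_p <- function(cp10k, ia, ib, epsilon) {
  vapply(seq_len(nrow(cp10k)), function(g) {
    xa <- cp10k[g, ia]
    xb <- cp10k[g, ib]
    ma <- mean(xa); mb <- mean(xb)
    va <- stats::var(xa); vb <- stats::var(xb)
    pooled_mu <- mean(c(xa, xb))
    pooled_var <- stats::var(c(xa, xb))
    excess <- pooled_var - pooled_mu
    theta <- if (excess > 0) pooled_mu^2 / excess else Inf
    var_mu <- function(mu, n) (mu + mu^2 / theta) / n
    se <- sqrt(var_mu(ma, length(xa)) / (ma + epsilon)^2 +
                 var_mu(mb, length(xb)) / (mb + epsilon)^2)
    if (!is.finite(se) || se == 0) return(1)
    z <- (log(ma + epsilon) - log(mb + epsilon)) / se
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
}

#' Per-patient one-vs-rest signatures
#'
#' For each patient, differential expression of that patient's cells
#' against all other patients' cells; signature genes pass a raw p-value
#' cutoff (as conventionally reported for this analysis) and a
#' fold-change cutoff, in the patient's favor.
#'
#' @param cm a \code{CountMatrix}.
#' @param patient_labels named character vector (cell id -> patient);
#'   default taken from the cell metadata.
#' @param p_cutoff raw p threshold (default .05).
#' @param fc_cutoff linear fold-change threshold (default 1.5).
#' @param method passed to \code{\link{de_two_group}}.
#' @return Named list of per-patient signature gene vectors, with a
#'   \code{membership} attribute (data.frame gene x patient logical).
#' @export
patient_signatures <- function(cm, patient_labels = NULL, p_cutoff = 0.05,
                               fc_cutoff = 1.5, method = "ranksum") {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(patient_labels)) {
    patient_labels <- stats::setNames(cm$cell_meta$patient_id, cm$cell_ids)
  }
  pts <- unique(as.character(patient_labels[cm$cell_ids]))
  if (length(pts) < 2L) validation_error("need at least 2 patients")
  sigs <- list()
  for (p in pts) {
    ga <- cm$cell_ids[patient_labels[cm$cell_ids] == p]
    gb <- setdiff(cm$cell_ids, ga)
    de <- de_two_group(cm, ga, gb, method = method)
    hit <- de$p_raw < p_cutoff & de$log2_fc > log2(fc_cutoff)
    sigs[[p]] <- de$gene_id[hit]
  }
  union_genes <- sort(unique(unlist(sigs)))
  membership <- as.data.frame(lapply(pts, function(p) union_genes %in% sigs[[p]]))
  names(membership) <- pts
  if (length(union_genes)) rownames(membership) <- union_genes
  attr(sigs, "membership") <- membership
  sigs
}

#' Stage-biased genes between two disease stages
#'
#' Differential expression between early- and late-stage cells at the
#' adjusted-p and fold-change-2 cutoffs, returning signed lists.
#'
#' @param cm a \code{CountMatrix}.
#' @param stage_labels named vector (cell id -> \code{"early"}/\code{"late"}).
#' @param p_adj_cutoff adjusted p threshold (default .05).
#' @param fc_cutoff linear fold-change threshold (default 2).
#' @param method passed to \code{\link{de_two_group}}.
#' @return List with character vectors \code{up_late}, \code{up_early} and
#'   the full \code{table}.
#' @export
stage_biased_genes <- function(cm, stage_labels, p_adj_cutoff = 0.05,
                               fc_cutoff = 2, method = "ranksum") {
  stopifnot(inherits(cm, "CountMatrix"))
  lab <- as.character(stage_labels[cm$cell_ids])
  if (!all(stats::na.omit(unique(lab)) %in% c("early", "late"))) {
    validation_error("stage labels must be 'early' or 'late'")
  }
  ga <- cm$cell_ids[!is.na(lab) & lab == "late"]
  gb <- cm$cell_ids[!is.na(lab) & lab == "early"]
  de <- de_two_group(cm, ga, gb, method = method)
  sig <- de$p_adj < p_adj_cutoff & abs(de$log2_fc) > log2(fc_cutoff)
  list(up_late = de$gene_id[sig & de$log2_fc > 0],
       up_early = de$gene_id[sig & de$log2_fc < 0],
       table = de)
}

#' Diagnostic panel selection
#'
#' Ranks genes that pass all four criteria — detected in at least
#' \code{min_detect_frac_ctc} of tumor cells, in at most
#' \code{max_detect_frac_normal} of normal cells, with
#' \code{log2_fc >= min_log2_fc} and \code{p_adj < max_p_adj} — by
#' decreasing detection gap (\code{detect_frac_a - detect_frac_b}), ties
#' by decreasing \code{log2_fc} then lexicographic gene id, truncated to
#' \code{panel_size}.
#'
#' @param de DE table from \code{\link{de_two_group}} with the tumor group
#'   as group A and the normal group as group B.
#' @param criteria list with \code{min_detect_frac_ctc},
#'   \code{max_detect_frac_normal}, \code{min_log2_fc}, \code{max_p_adj},
#'   \code{panel_size}; see \code{\link{default_panel_criteria}}.
#' @return data.frame of the selected genes in rank order (possibly empty,
#'   with a warning when nothing passes).
#' @export
select_panel <- function(de, criteria = default_panel_criteria()) {
  needed <- c("min_detect_frac_ctc", "max_detect_frac_normal",
              "min_log2_fc", "max_p_adj", "panel_size")
  if (!all(needed %in% names(criteria))) {
    validation_error(sprintf("criteria must contain: %s",
                             paste(needed, collapse = ", ")))
  }
  if (criteria$panel_size < 1) validation_error("panel_size must be >= 1")
  pass <- de$detect_frac_a >= criteria$min_detect_frac_ctc &
    de$detect_frac_b <= criteria$max_detect_frac_normal &
    de$log2_fc >= criteria$min_log2_fc &
    de$p_adj < criteria$max_p_adj
  hits <- de[pass, , drop = FALSE]
  if (!nrow(hits)) {
    warning("no gene passes the panel criteria; returning an empty panel")
    return(hits)
  }
  gap <- hits$detect_frac_a - hits$detect_frac_b
  ord <- order(-gap, -hits$log2_fc, hits$gene_id)
  hits <- hits[ord, , drop = FALSE]
  hits$detection_gap <- gap[ord]
  utils::head(hits, criteria$panel_size)
}

#' Default diagnostic panel criteria
#'
#' Detected in at least half of tumor cells, in at most 5% of normal
#' cells, at least 2-fold up with adjusted p < .05, 20-gene panel.
#'
#' @return Named list of criteria.
#' @export
default_panel_criteria <- function() {
  list(min_detect_frac_ctc = 0.5, max_detect_frac_normal = 0.05,
       min_log2_fc = 1, max_p_adj = 0.05, panel_size = 20L)
}
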