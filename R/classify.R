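# Per-cell identity and state assignment: marker-panel typing, cell-cycle
# state, partial EMT, cancer-stem-cell marker positivity, and
# cancer-testis-antigen burden.

immune_panel_names <- c("T", "B", "monocyte")
tumor_panel_names <- c("lung", "epithelial", "proliferation")

#' Assign cell types from marker panels
#'
#' Replaces heatmap inspection with an explicit, configurable positivity
#' rule: a panel is positive in a cell if at least \code{min_detected} of
#' its genes are detected (raw count > 0) or its module score exceeds
#' \code{score_threshold}. A cell is immune if the pan-leukocyte panel or
#' any immune panel is positive (immune positivity takes priority over
#' tumor panels), and is then typed by its highest-scoring immune panel;
#' otherwise it is a CTC if the epithelial or lung panel is positive;
#' otherwise unassigned.
#'
#' @param em an \code{ExpressionMatrix}.
#' @param cm the matching \code{CountMatrix} (raw counts drive the
#'   detection part of the rule).
#' @param panels marker panels (default \code{\link{default_marker_panels}}).
#' @param min_detected detected-gene threshold per panel (default 2).
#' @param score_threshold module-score threshold per panel (default 0.1).
#' @param n_bins,n_ctrl,seed passed to \code{\link{module_score}}.
#' @return Character vector per cell: \code{"T"}, \code{"B"},
#'   \code{"monocyte"}, \code{"CTC"} or \code{"unassigned"}.
#' @export
assign_cell_type <- function(em, cm, panels = default_marker_panels(),
                             min_detected = 2, score_threshold = 0.1,
                             n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(cm, "CountMatrix"))
  if (!identical(em$cell_ids, cm$cell_ids)) {
    validation_error("expression and count matrices cover different cells")
  }
  present <- vapply(panels, function(g) any(g %in% em$gene_ids), logical(1))
  if (!any(present[intersect(names(panels), tumor_panel_names)])) {
    missing_genes_error("no tumor panel gene is present in the matrix")
  }
  if (!any(present)) missing_genes_error("no panel gene is present in the matrix")

  detected <- vapply(names(panels), function(p) {
    g <- intersect(panels[[p]], cm$gene_ids)
    if (!length(g)) return(rep(0L, ncol(cm$counts)))
    as.integer(Matrix::colSums(cm$counts[g, , drop = FALSE] > 0))
  }, integer(ncol(cm$counts)))
  if (ncol(cm$counts) == 1L) detected <- matrix(detected, nrow = 1L,
                                                dimnames = list(NULL, names(panels)))

  scores <- vapply(seq_along(panels), function(i) {
    if (!present[i]) return(rep(-Inf, ncol(em$values)))
    module_score(em, panels[[i]], n_bins = n_bins, n_ctrl = n_ctrl,
                 seed = seed + i)
  }, numeric(ncol(em$values)))
  if (ncol(em$values) == 1L) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- names(panels)

  # detection threshold capped at panel size so one-gene panels (the
  # pan-leukocyte PTPRC panel) can be detection-positive
  cap <- pmin(min_detected, vapply(panels, length, integer(1)))
  positive <- sweep(detected, 2L, cap, ">=") | scores > score_threshold

  imm_cols <- intersect(c(immune_panel_names, "leukocyte"), names(panels))
  imm_score_cols <- intersect(immune_panel_names, names(panels))
  tum_cols <- intersect(c("epithelial", "lung"), names(panels))

  vapply(seq_len(ncol(em$values)), function(ci) {
    if (length(imm_cols) && any(positive[ci, imm_cols])) {
      if (!length(imm_score_cols)) return("unassigned")
      # subtype by the highest-scoring immune panel: panels are compared
      # on detected marker genes first, module score as tie-break, so a
      # cell detecting one T marker is T even when sparse detection makes
      # the control-subtracted score negative
      d <- detected[ci, imm_score_cols]
      best <- which(d == max(d))
      imm_score_cols[best[which.max(scores[ci, imm_score_cols][best])]]
    } else if (length(tum_cols) && any(positive[ci, tum_cols])) {
      "CTC"
    } else {
      "unassigned"
    }
  }, character(1))
}

#' Assign cell-cycle state from phase scores
#'
#' Cycling iff \code{max(g1s, g2m) > 0.2} (strict); intermediate iff
#' \code{0 < max <= 0.2}; non-cycling otherwise (\code{max <= 0}).
#'
#' @param g1s,g2m numeric vectors of G1/S and G2/M scores (finite).
#' @return Character vector: \code{"cycling"}, \code{"intermediate"} or
#'   \code{"non_cycling"}.
#' @export
assign_cycle_state <- function(g1s, g2m) {
  if (length(g1s) != length(g2m)) {
    validation_error("g1s and g2m must have equal length")
  }
  if (anyNA(g1s) || anyNA(g2m) || any(!is.finite(g1s)) || any(!is.finite(g2m))) {
    validation_error("cycle scores must be finite and non-missing")
  }
  mx <- pmax(g1s, g2m)
  ifelse(mx > 0.2, "cycling", ifelse(mx > 0, "intermediate", "non_cycling"))
}

#' Partial-EMT call
#'
#' A cell is in partial EMT iff both its epithelial score and its
#' mesenchymal/CSC score strictly exceed the threshold (default 0.5, on
#' the [0, 1] rescaled GSVA-style scores).
#'
#' @param epi_score,mes_csc_score numeric vectors in [0, 1].
#' @param threshold strict threshold (default 0.5).
#' @return Logical vector.
#' @export
classify_partial_emt <- function(epi_score, mes_csc_score, threshold = 0.5) {
  if (length(epi_score) != length(mes_csc_score)) {
    validation_error("score vectors must have equal length")
  }
  epi_score > threshold & mes_csc_score > threshold
}

#' Cancer-stem-cell marker positivity
#'
#' Positivity = raw count > 0 for each CSC candidate marker, plus the
#' CD44+ALDH1A1+ dual flag and the stem-like flag (PROM1+ or CD44+).
#' Markers absent from the matrix yield all-FALSE flags.
#'
#' @param cm a \code{CountMatrix}.
#' @param markers marker symbols (default \code{\link{csc_markers}}).
#' @return data.frame with one row per cell: \code{cell_id}, one logical
#'   column per marker (\code{<marker>_pos}), \code{cd44_aldh1a1_dual},
#'   \code{stem_like}.
#' @export
csc_positivity <- function(cm, markers = csc_markers()) {
  stopifnot(inherits(cm, "CountMatrix"))
  flags <- vapply(markers, function(g) {
    if (g %in% cm$gene_ids) as.vector(cm$counts[g, ] > 0)
    else rep(FALSE, ncol(cm$counts))
  }, logical(ncol(cm$counts)))
  if (ncol(cm$counts) == 1L) flags <- matrix(flags, nrow = 1L,
                                             dimnames = list(NULL, markers))
  out <- data.frame(cell_id = cm$cell_ids, stringsAsFactors = FALSE)
  for (g in markers) out[[paste0(g, "_pos")]] <- flags[, g]
  out$cd44_aldh1a1_dual <- flag_or_false(flags, "CD44") & flag_or_false(flags, "ALDH1A1")
  out$stem_like <- flag_or_false(flags, "PROM1") | flag_or_false(flags, "CD44")
  out
}

flag_or_false <- function(flags, g) {
  if (g %in% colnames(flags)) flags[, g] else rep(FALSE, nrow(flags))
}

#' Cancer-testis-antigen burden
#'
#' Number of catalogue CTA genes detected (raw count > 0) per cell.
#'
#' @param cm a \code{CountMatrix}.
#' @param cta_list CTA gene symbols (default the bundled 276-symbol
#'   curated catalogue, \code{\link{default_cta_catalog}}).
#' @return Named integer vector, one count per cell.
#' @export
cta_burden <- function(cm, cta_list = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(cta_list)) cta_list <- default_cta_catalog()$CTA
  g <- intersect(cta_list, cm$gene_ids)
  burden <- if (length(g)) {
    as.integer(Matrix::colSums(cm$counts[g, , drop = FALSE] > 0))
  } else {
    rep(0L, ncol(cm$counts))
  }
  stats::setNames(burden, cm$cell_ids)
}

#' Per-sample panel detection fractions
#'
#' For each sample and marker panel, the fraction of cells detecting at
#' least one panel gene — the evidence-of-origin profile used to reason
#' about panel absence (e.g. a tumor with no lung-marker expression).
#' Panels entirely absent from the gene universe are reported as
#' \code{NA} (absent-from-universe), not as zero detection.
#'
#' @param cm a \code{CountMatrix}.
#' @param panels marker panels (default \code{\link{default_marker_panels}}).
#' @return data.frame: \code{sample_id}, \code{panel}, \code{n_cells},
#'   \code{n_detecting}, \code{fraction}.
#' @export
panel_absence_profile <- function(cm, panels = default_marker_panels()) {
  stopifnot(inherits(cm, "CountMatrix"))
  samples <- unique(cm$cell_meta$sample_id)
  rows <- list()
  for (s in samples) {
    cells <- which(cm$cell_meta$sample_id == s)
    for (p in names(panels)) {
      g <- intersect(panels[[p]], cm$gene_ids)
      if (!length(g)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, panel = p, n_cells = length(cells),
          n_detecting = NA_integer_, fraction = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      det <- sum(Matrix::colSums(cm$counts[g, cells, drop = FALSE] > 0) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, panel = p, n_cells = length(cells),
        n_detecting = as.integer(det),
        fraction = det / length(cells), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Full per-cell annotation
#'
#' Runs typing, cycle scoring/state, GSVA-style EMT scoring, partial-EMT
#' calling, CSC positivity and CTA burden, returning one row per cell.
#'
#' @param cm a QC-passing \code{CountMatrix}.
#' @param em matching \code{ExpressionMatrix} (computed if omitted).
#' @param panels,emt_sets,cycle_genes,cta_list gene sets; bundled defaults
#'   when \code{NULL}.
#' @param min_detected,score_threshold typing rule knobs
#'   (\code{\link{assign_cell_type}}).
#' @param emt_threshold partial-EMT threshold (default 0.5).
#' @param seed integer seed for stochastic scoring.
#' @return data.frame (\code{CellAnnotation}): cell_id, sample_id,
#'   patient_id, cell_type, g1s_score, g2m_score, cycle_state, epi_score,
#'   mes_csc_score, ecm_score, partial_emt, CSC flags, cta_count.
#' @export
annotate_cells <- function(cm, em = log_normalize(cm), panels = NULL,
                           emt_sets = NULL, cycle_genes = NULL,
                           cta_list = NULL, min_detected = 2,
                           score_threshold = 0.1, emt_threshold = 0.5,
                           seed = 0) {
  if (is.null(panels)) panels <- default_marker_panels()
  if (is.null(emt_sets)) emt_sets <- default_emt_sets()
  if (is.null(cycle_genes)) cycle_genes <- default_cycle_genes()
  if (is.null(cta_list)) cta_list <- default_cta_catalog()$CTA

  cell_type <- assign_cell_type(em, cm, panels, min_detected = min_detected,
                                score_threshold = score_threshold, seed = seed)
  cyc <- cycle_scores(em, cycle_genes$G1S, cycle_genes$G2M, seed = seed + 100L)
  cycle_state <- assign_cycle_state(cyc$g1s, cyc$g2m)
  gsva <- gsva_like_score(em, emt_sets)
  emt <- classify_partial_emt(gsva["epithelial", ], gsva["mes_csc", ],
                              threshold = emt_threshold)
  csc <- csc_positivity(cm)
  burden <- cta_burden(cm, cta_list)

  ann <- data.frame(cell_id = cm$cell_ids,
                    sample_id = cm$cell_meta$sample_id,
                    patient_id = cm$cell_meta$patient_id,
                    cell_type = cell_type,
                    g1s_score = as.numeric(cyc$g1s),
                    g2m_score = as.numeric(cyc$g2m),
                    cycle_state = cycle_state,
                    epi_score = as.numeric(gsva["epithelial", ]),
                    mes_csc_score = as.numeric(gsva["mes_csc", ]),
                    ecm_score = as.numeric(gsva["ecm", ]),
                    partial_emt = as.logical(emt),
                    cta_count = as.integer(burden),
                    stringsAsFactors = FALSE)
  cbind(ann, csc[, setdiff(names(csc), "cell_id"), drop = FALSE])
}
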