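# Cohort summaries and pipeline orchestration. Every reported percentage
# carries its integer numerator and denominator and is reproducible via
# report_proportion().

#' Fixed-precision proportion reporting
#'
#' \code{100 * numerator / denominator} rounded half-up to one decimal
#' (half-up, not banker's rounding: 0.05 at the reporting precision always
#' rounds away from zero, matching the conventional reporting of ratios
#' like 142/157 = 90.4\%).
#'
#' @param numerator,denominator non-negative integers with
#'   \code{numerator <= denominator} and \code{denominator > 0}.
#' @return Percentage as a number with one decimal.
#' @export
report_proportion <- function(numerator, denominator) {
  if (any(denominator == 0)) validation_error("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator)) {
    validation_error("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, 1L)
}

round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Cohort summary tables
#'
#' Tabulates per-sample cell-type counts (sequenced-equivalent input,
#' class counts summing to the annotated total), per-patient cycle-state
#' proportions, marker-positive fractions, partial-EMT fractions and CTA
#' burden quartiles. Every percentage is emitted with its numerator and
#' denominator; across-patient means of per-patient percentages are
#' unweighted ("on average" convention).
#'
#' @param annotations a \code{CellAnnotation} data.frame from
#'   \code{\link{annotate_cells}}.
#' @param qc optional \code{QCMetrics} on the same cells (consistency
#'   checked when given).
#' @return List of class \code{CohortSummary}: \code{by_sample},
#'   \code{by_patient}, \code{cycling_mean_pct}, \code{partial_emt_mean_pct}.
#' @export
summarize_cohort <- function(annotations, qc = NULL) {
  need <- c("cell_id", "sample_id", "patient_id", "cell_type", "cycle_state",
            "partial_emt", "cta_count")
  if (!all(need %in% names(annotations))) {
    validation_error(sprintf("annotations must contain columns: %s",
                             paste(need, collapse = ", ")))
  }
  if (!is.null(qc)) {
    if (!setequal(qc$cell$cell_id, annotations$cell_id)) {
      validation_error("annotations and QC metrics cover different cell sets")
    }
  }
  types <- c("T", "B", "monocyte", "CTC", "unassigned")
  by_sample <- do.call(rbind, lapply(split(annotations, annotations$sample_id),
    function(a) {
      counts <- table(factor(a$cell_type, levels = types))
      data.frame(sample_id = a$sample_id[1], n_cells = nrow(a),
                 t(as.matrix(counts)), check.names = FALSE,
                 stringsAsFactors = FALSE)
    }))
  rownames(by_sample) <- NULL

  by_patient <- do.call(rbind, lapply(split(annotations, annotations$patient_id),
    function(a) {
      ctc <- a[a$cell_type == "CTC", , drop = FALSE]
      n_ctc <- nrow(ctc)
      pct <- function(num, den) if (den > 0) report_proportion(num, den) else NA_real_
      data.frame(
        patient_id = a$patient_id[1],
        n_cells = nrow(a), n_ctc = n_ctc,
        cycling_n = sum(ctc$cycle_state == "cycling"),
        cycling_pct = pct(sum(ctc$cycle_state == "cycling"), n_ctc),
        intermediate_n = sum(ctc$cycle_state == "intermediate"),
        intermediate_pct = pct(sum(ctc$cycle_state == "intermediate"), n_ctc),
        non_cycling_n = sum(ctc$cycle_state == "non_cycling"),
        non_cycling_pct = pct(sum(ctc$cycle_state == "non_cycling"), n_ctc),
        partial_emt_n = sum(ctc$partial_emt),
        partial_emt_pct = pct(sum(ctc$partial_emt), n_ctc),
        cd44_pos_n = if ("CD44_pos" %in% names(ctc)) sum(ctc$CD44_pos) else NA_integer_,
        cd44_pos_pct = if ("CD44_pos" %in% names(ctc)) pct(sum(ctc$CD44_pos), n_ctc) else NA_real_,
        cta_q1 = if (n_ctc) as.numeric(stats::quantile(ctc$cta_count, 0.25)) else NA_real_,
        cta_median = if (n_ctc) as.numeric(stats::median(ctc$cta_count)) else NA_real_,
        cta_q3 = if (n_ctc) as.numeric(stats::quantile(ctc$cta_count, 0.75)) else NA_real_,
        stringsAsFactors = FALSE)
    }))
  rownames(by_patient) <- NULL

  structure(list(
    by_sample = by_sample,
    by_patient = by_patient,
    cycling_mean_pct = across_patient_mean(by_patient$cycling_pct),
    partial_emt_mean_pct = across_patient_mean(by_patient$partial_emt_pct)
  ), class = "CohortSummary")
}

# unweighted across-patient mean of per-patient percentages, half-up 1 dp
across_patient_mean <- function(pcts) {
  pcts <- pcts[!is.na(pcts)]
  if (!length(pcts)) return(NA_real_)
  round_half_up(mean(pcts), 1L)
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat("CohortSummary\n  per-sample cell-type counts:\n")
  print(x$by_sample)
  cat(sprintf("  across-patient mean cycling: %s%%\n", x$cycling_mean_pct))
  invisible(x)
}

#' Convenience 2-D embedding
#'
#' Principal-component coordinates of the cells (first two PCs of the
#' centered expression matrix) — visualization plumbing only, no
#' quantitative claims are made from it. Deterministic; the seed argument
#' exists for interface stability with stochastic embeddings.
#'
#' @param em an \code{ExpressionMatrix} with at least 3 cells.
#' @param seed unused by the PCA embedding (kept for interface parity).
#' @return data.frame: \code{cell_id}, \code{dim1}, \code{dim2}.
#' @export
embed_cells <- function(em, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 3L) {
    degenerate_input_error("need at least 3 cells to embed")
  }
  keep <- apply(em$values, 1L, stats::sd) > 0
  pc <- stats::prcomp(t(em$values[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE, rank. = 2L)
  data.frame(cell_id = em$cell_ids, dim1 = pc$x[, 1], dim2 = pc$x[, 2],
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Orchestrates simulate/load -> QC -> normalization -> annotation
#' (typing, cycle, EMT, CSC, CTA) -> heterogeneity -> differential
#' expression (CTC vs immune when both are present) -> cohort summary,
#' writing TSV tables and a JSON run summary (full config echo included)
#' into the output directory. Re-running with an identical config and
#' seed reproduces all outputs.
#'
#' @param config either a path to a YAML file or a named list. Recognized
#'   keys: \code{counts_dir}, \code{counts_format} (\code{"mtx"}/
#'   \code{"tsv"}), or \code{simulate} (a list of
#'   \code{\link{synthetic_config}} arguments); \code{out_dir}
#'   (required); \code{seed}; QC thresholds \code{min_cells},
#'   \code{min_genes}, \code{max_mito}; typing knobs \code{min_detected},
#'   \code{score_threshold}; \code{emt_threshold}; \code{scale_factor};
#'   \code{de_method}. Unknown keys are rejected.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("counts_dir", "counts_format", "simulate", "out_dir", "seed",
             "min_cells", "min_genes", "max_mito", "min_detected",
             "score_threshold", "emt_threshold", "scale_factor", "de_method")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    validation_error(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  if (is.null(config$out_dir)) validation_error("config needs out_dir")
  defaults <- list(seed = 0L, min_cells = 10, min_genes = 600,
                   max_mito = 0.20, min_detected = 2, score_threshold = 0.1,
                   emt_threshold = 0.5, scale_factor = 1e4,
                   de_method = "ranksum", counts_format = "mtx")
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]

  log_msg <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_msg(name, "done in %.2fs", as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()

  cm_raw <- stage("input", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      sim <- do.call(synthetic_config, sim_args)
      gen <- generate_synthetic(sim)
      utils::write.table(gen$truth$cell, file.path(out_dir, "truth_cells.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      gen$counts
    } else {
      if (is.null(config$counts_dir) || !dir.exists(config$counts_dir)) {
        io_error(sprintf("counts_dir missing or not found: %s",
                         if (is.null(config$counts_dir)) "<unset>" else config$counts_dir))
      }
      load_counts(config$counts_dir, format = config$counts_format)
    }
  })

  cm <- stage("qc", {
    qc0 <- compute_qc(cm_raw)
    write_result_table(qc0$cell, file.path(out_dir, "qc_cells.tsv"))
    apply_qc(cm_raw, min_cells = config$min_cells,
             min_genes = config$min_genes, max_mito = config$max_mito)
  })
  if (ncol(cm$counts) < 3L) {
    degenerate_input_error("fewer than 3 cells survive QC")
  }
  em <- stage("normalize", log_normalize(cm, scale_factor = config$scale_factor))

  ann <- stage("annotate", {
    a <- annotate_cells(cm, em, min_detected = config$min_detected,
                        score_threshold = config$score_threshold,
                        emt_threshold = config$emt_threshold,
                        seed = config$seed)
    write_result_table(a, file.path(out_dir, "cell_annotations.tsv"))
    a
  })

  het <- stage("heterogeneity", {
    if (ncol(em$values) >= 2L) {
      corr <- pairwise_correlation(em)
      groups <- stats::setNames(cm$cell_meta$patient_id, cm$cell_ids)
      h <- heterogeneity_summary(corr, groups)
      utils::write.table(as.data.frame(as.matrix(corr)),
                         file.path(out_dir, "pairwise_correlation.tsv"),
                         sep = "\t", quote = FALSE)
      h
    } else NULL
  })

  de <- stage("diffexpr", {
    ctc <- ann$cell_id[ann$cell_type == "CTC"]
    imm <- ann$cell_id[ann$cell_type %in% c("T", "B", "monocyte")]
    if (length(ctc) >= 3L && length(imm) >= 3L) {
      d <- de_two_group(cm, ctc, imm, method = config$de_method)
      write_result_table(d, file.path(out_dir, "de_ctc_vs_immune.tsv"))
      panel <- select_panel(d)
      if (nrow(panel)) {
        write_result_table(panel, file.path(out_dir, "diagnostic_panel.tsv"))
      }
      d
    } else NULL
  })

  summary <- stage("summarize", summarize_cohort(ann))
  write_result_table(summary$by_sample, file.path(out_dir, "summary_by_sample.tsv"))
  write_result_table(summary$by_patient, file.path(out_dir, "summary_by_patient.tsv"))

  emb <- stage("embed", embed_cells(em, seed = config$seed))
  write_result_table(emb, file.path(out_dir, "embedding.tsv"))

  run_summary <- list(
    config = config[order(names(config))],
    n_genes_input = nrow(cm_raw$counts), n_cells_input = ncol(cm_raw$counts),
    n_genes_qc = nrow(cm$counts), n_cells_qc = ncol(cm$counts),
    cell_type_counts = as.list(table(ann$cell_type)),
    cycling_mean_pct = summary$cycling_mean_pct,
    partial_emt_mean_pct = summary$partial_emt_mean_pct,
    heterogeneity = if (!is.null(het)) {
      list(intra_mean_overall = het$intra_mean_overall,
           inter_mean = het$inter_mean, p_value = het$p_value)
    } else NULL,
    n_de_significant = if (!is.null(de)) {
      sum(de$p_adj < 0.05 & abs(de$log2_fc) > 1)
    } else NULL
  )
  jsonlite::write_json(run_summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
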