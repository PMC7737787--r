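#' Per-cell and per-gene quality-control metrics
#'
#' Computed on raw counts: per cell, the number of genes with a nonzero
#' count (\code{genes_detected}), the library size (\code{total_counts})
#' and the fraction of counts attributed to mitochondrial genes
#' (\code{mito_fraction}); per gene, the number of cells with a nonzero
#' count (\code{cells_expressing}). The mitochondrial fraction is computed
#' over counted reads, the only information a count matrix carries.
#'
#' @param cm a \code{CountMatrix}.
#' @param mito_genes gene symbols treated as mitochondrial; default every
#'   gene whose symbol starts with \code{"MT-"}.
#' @return A list of class \code{QCMetrics} with data.frames \code{cell}
#'   (\code{cell_id}, \code{genes_detected}, \code{total_counts},
#'   \code{mito_fraction}) and \code{gene} (\code{gene_id},
#'   \code{cells_expressing}).
#' @export
compute_qc <- function(cm, mito_genes = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(mito_genes)) {
    mito_genes <- grep("^MT-", cm$gene_ids, value = TRUE)
  }
  nz <- cm$counts > 0
  genes_detected <- Matrix::colSums(nz)
  total_counts <- Matrix::colSums(cm$counts)
  mito_idx <- cm$gene_ids %in% mito_genes
  mito_counts <- if (any(mito_idx)) {
    Matrix::colSums(cm$counts[mito_idx, , drop = FALSE])
  } else {
    rep(0, ncol(cm$counts))
  }
  mito_fraction <- ifelse(total_counts > 0, mito_counts / total_counts, 0)
  structure(list(
    cell = data.frame(cell_id = cm$cell_ids,
                      genes_detected = as.integer(genes_detected),
                      total_counts = as.integer(round(total_counts)),
                      mito_fraction = as.numeric(mito_fraction),
                      stringsAsFactors = FALSE),
    gene = data.frame(gene_id = cm$gene_ids,
                      cells_expressing = as.integer(Matrix::rowSums(nz)),
                      stringsAsFactors = FALSE)
  ), class = "QCMetrics")
}

#' Filter lowly-detected genes
#'
#' Retains exactly the genes detected (count > 0) in at least
#' \code{min_cells} cells; "less than 10 cells" is a strict bound, so a
#' gene seen in exactly 10 cells survives the default. The cell set is
#' unchanged and the operation is idempotent.
#'
#' @param cm a \code{CountMatrix}.
#' @param min_cells minimum number of expressing cells (default 10).
#' @return Filtered \code{CountMatrix}.
#' @export
filter_genes <- function(cm, min_cells = 10) {
  stopifnot(inherits(cm, "CountMatrix"), min_cells >= 0)
  keep <- Matrix::rowSums(cm$counts > 0) >= min_cells
  subset_counts(cm, genes = which(keep))
}

#' Filter low-quality cells
#'
#' Removes a cell iff it has fewer than \code{min_genes} detected genes OR
#' a mitochondrial fraction strictly above \code{max_mito}. Boundaries
#' follow the QC rule literally: "fewer than 600" and "over 20%" are both
#' strict, so a cell at exactly 600 genes and exactly 20% mitochondrial
#' reads is retained. The gene set is unchanged; idempotent.
#'
#' @param cm a \code{CountMatrix}.
#' @param qc \code{QCMetrics} computed on \code{cm} (recomputed if omitted).
#' @param min_genes minimum detected genes (default 600).
#' @param max_mito maximum tolerated mitochondrial fraction (default 0.20).
#' @return Filtered \code{CountMatrix}.
#' @export
filter_cells <- function(cm, qc = compute_qc(cm), min_genes = 600,
                         max_mito = 0.20) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(qc, "QCMetrics"))
  qcc <- qc$cell[match(cm$cell_ids, qc$cell$cell_id), , drop = FALSE]
  if (anyNA(qcc$cell_id)) validation_error("qc metrics do not cover all cells")
  remove <- qcc$genes_detected < min_genes | qcc$mito_fraction > max_mito
  subset_counts(cm, cells = which(!remove))
}

#' Subset to high-coverage cells
#'
#' Retains cells with at least \code{min_genes} detected genes (inclusive
#' boundary: "more than or equal to"), the stricter coverage cut applied
#' to tumor cells before transcriptome characterization.
#'
#' @inheritParams filter_cells
#' @param min_genes minimum detected genes, inclusive (default 1000).
#' @return Filtered \code{CountMatrix}.
#' @export
subset_high_coverage <- function(cm, qc = compute_qc(cm), min_genes = 1000) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(qc, "QCMetrics"))
  qcc <- qc$cell[match(cm$cell_ids, qc$cell$cell_id), , drop = FALSE]
  if (anyNA(qcc$cell_id)) validation_error("qc metrics do not cover all cells")
  subset_counts(cm, cells = which(qcc$genes_detected >= min_genes))
}

#' Standard QC pipeline
#'
#' Gene filter first, then cell filter (the pipeline's default order).
#'
#' @inheritParams filter_cells
#' @param min_cells gene filter threshold (default 10).
#' @param mito_genes see \code{\link{compute_qc}}.
#' @return Filtered \code{CountMatrix}.
#' @export
apply_qc <- function(cm, min_cells = 10, min_genes = 600, max_mito = 0.20,
                     mito_genes = NULL) {
  cm <- filter_genes(cm, min_cells = min_cells)
  qc <- compute_qc(cm, mito_genes = mito_genes)
  filter_cells(cm, qc, min_genes = min_genes, max_mito = max_mito)
}
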