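#' Construct a CountMatrix
#'
#' The pipeline's sole primary input: a gene x cell matrix of non-negative
#' integer read counts with per-cell metadata. Genes are rows, cells are
#' columns, everywhere in the package. Gene identifiers are HGNC symbols as
#' plain strings; matching against gene sets is exact and case-sensitive.
#'
#' @param counts gene x cell matrix (base matrix or \pkg{Matrix} sparse
#'   matrix) of non-negative integers.
#' @param gene_ids character vector of unique gene symbols (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param cell_meta data.frame with one row per cell and columns
#'   \code{cell_id}, \code{sample_id}, \code{patient_id} and optionally
#'   \code{population_label}. If \code{NULL}, a single-sample placeholder
#'   metadata table is created.
#' @return An object of class \code{CountMatrix}: a list with elements
#'   \code{counts} (a \code{dgCMatrix}), \code{gene_ids}, \code{cell_ids}
#'   and \code{cell_meta}.
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 0L, 0L, 1L), nrow = 2)
#' cm <- count_matrix(m, c("A", "B"), c("c1", "c2", "c3"))
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_ids, cell_ids, cell_meta = NULL) {
  if (!methods::is(counts, "Matrix")) {
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    validation_error(sprintf(
      "counts is %d x %d but %d gene_ids and %d cell_ids were given",
      nrow(counts), ncol(counts), length(gene_ids), length(cell_ids)))
  }
  if (anyDuplicated(gene_ids)) {
    validation_error(sprintf("duplicate gene_ids: %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(cell_ids)) {
    validation_error(sprintf("duplicate cell_ids: %s",
      paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", ")))
  }
  x <- counts@x
  if (length(x)) {
    bad <- which(x < 0 | x != round(x))
    if (length(bad)) {
      ij <- sparse_coords(counts, bad[1L])
      validation_error(sprintf(
        "count for gene '%s', cell '%s' is %s (must be a non-negative integer)",
        gene_ids[ij[1L]], cell_ids[ij[2L]], format(x[bad[1L]])),
        gene = gene_ids[ij[1L]], cell = cell_ids[ij[2L]])
    }
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cell_ids,
                            sample_id = rep("S1", length(cell_ids)),
                            patient_id = rep("P1", length(cell_ids)),
                            population_label = rep(NA_character_,
                                                   length(cell_ids)),
                            stringsAsFactors = FALSE)
  }
  cell_meta <- validate_cell_meta(cell_meta, cell_ids)
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_ids
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "CountMatrix")
}

# row/col of the k-th stored entry of a CsparseMatrix (1-based)
sparse_coords <- function(m, k) {
  j <- findInterval(k - 1L, m@p[-1L]) + 1L
  c(m@i[k] + 1L, j)
}

validate_cell_meta <- function(cell_meta, cell_ids) {
  need <- c("cell_id", "sample_id", "patient_id")
  missing_cols <- setdiff(need, names(cell_meta))
  if (length(missing_cols)) {
    validation_error(sprintf("cell_meta lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  if (!"population_label" %in% names(cell_meta)) {
    cell_meta$population_label <- NA_character_
  }
  cell_meta <- cell_meta[, c(need, "population_label")]
  cell_meta$cell_id <- as.character(cell_meta$cell_id)
  if (!setequal(cell_meta$cell_id, cell_ids) ||
      nrow(cell_meta) != length(cell_ids)) {
    validation_error("cell_meta must contain exactly one record per cell_id")
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  cell_meta
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%d samples, %d patients)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              length(unique(x$cell_meta$patient_id))))
  invisible(x)
}

#' Subset a CountMatrix by genes and/or cells
#'
#' @param cm a \code{CountMatrix}.
#' @param genes character or logical/integer index of genes to keep
#'   (default all).
#' @param cells character or logical/integer index of cells to keep
#'   (default all).
#' @return A \code{CountMatrix} with the selected rows/columns and the
#'   matching metadata rows, in the requested order.
#' @export
subset_counts <- function(cm, genes = NULL, cells = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  gi <- if (is.null(genes)) seq_along(cm$gene_ids) else resolve_index(genes, cm$gene_ids, "gene")
  ci <- if (is.null(cells)) seq_along(cm$cell_ids) else resolve_index(cells, cm$cell_ids, "cell")
  count_matrix(cm$counts[gi, ci, drop = FALSE],
               cm$gene_ids[gi], cm$cell_ids[ci],
               cm$cell_meta[ci, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) {
      validation_error(sprintf("unknown %s id(s): %s", what,
                               paste(idx[is.na(pos)], collapse = ", ")))
    }
    pos
  } else if (is.logical(idx)) {
    which(idx)
  } else {
    as.integer(idx)
  }
}

#' Log-normalize a CountMatrix
#'
#' Library-size normalization followed by a natural log1p transform:
#' \code{value[g, c] = ln(1 + scale_factor * count[g, c] / total[c])}, the
#' de-facto scRNA-seq convention (counts per 10,000 by default). Cells with
#' zero total counts receive all-zero values (they are removed at QC, not
#' here: the loader validates format, QC enforces biology).
#'
#' @param cm a \code{CountMatrix}.
#' @param scale_factor positive scale applied after library-size division
#'   (default \code{1e4}).
#' @return An \code{ExpressionMatrix}: list with \code{values} (dense gene x
#'   cell matrix of log-normalized expression), \code{source_total} (per-cell
#'   library sizes used) and \code{scale_factor}.
#' @export
log_normalize <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (scale_factor <= 0) validation_error("scale_factor must be positive")
  totals <- Matrix::colSums(cm$counts)
  divisor <- ifelse(totals > 0, totals, 1)
  values <- log1p(sweep(as.matrix(cm$counts), 2L, scale_factor / divisor, "*"))
  dimnames(values) <- list(cm$gene_ids, cm$cell_ids)
  structure(list(values = values, source_total = stats::setNames(totals, cm$cell_ids),
                 scale_factor = scale_factor,
                 gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
                 cell_meta = cm$cell_meta),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (scale_factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

# Match a gene set against a matrix universe; drops unmatched symbols with a
# logged count (message), per the package's exact case-sensitive matching rule.
match_set <- function(set, universe, set_name = "gene set", quiet = FALSE) {
  hit <- intersect(set, universe)
  n_drop <- length(set) - length(hit)
  if (n_drop > 0 && !quiet) {
    message(sprintf("%s: dropped %d/%d symbol(s) absent from the matrix",
                    set_name, n_drop, length(set)))
  }
  hit
}
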