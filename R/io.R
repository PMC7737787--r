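#' Load a count matrix from disk
#'
#' Reads a gene x cell integer count matrix either from a Matrix Market
#' triplet directory (\code{matrix.mtx} with \code{genes.tsv} and
#' \code{barcodes.tsv} sidecars, optional \code{metadata.tsv}) or from a
#' dense TSV directory (\code{counts.tsv} with gene rows and a header of
#' cell IDs, optional \code{metadata.tsv}). MTX triplets are 1-based on
#' disk, standard Matrix Market semantics.
#'
#' @param path directory containing the files above.
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @return A validated \code{\link{count_matrix}}.
#' @export
load_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (!dir.exists(path)) io_error(sprintf("no such directory: %s", path))
  if (format == "mtx") {
    mtx_path <- file.path(path, "matrix.mtx")
    genes_path <- file.path(path, "genes.tsv")
    cells_path <- file.path(path, "barcodes.tsv")
    for (p in c(mtx_path, genes_path, cells_path)) {
      if (!file.exists(p)) {
        format_error(sprintf("missing MTX sidecar or matrix file: %s", p))
      }
    }
    m <- Matrix::readMM(mtx_path)
    gene_ids <- read_id_sidecar(genes_path)
    cell_ids <- read_id_sidecar(cells_path)
  } else {
    tsv_path <- file.path(path, "counts.tsv")
    if (!file.exists(tsv_path)) format_error(sprintf("missing %s", tsv_path))
    tab <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                             check.names = FALSE, row.names = 1L,
                             colClasses = "character")
    gene_ids <- rownames(tab)
    cell_ids <- colnames(tab)
    num <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
    if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L)
    if (length(num) == 0L) num <- matrix(0, nrow(tab), ncol(tab))
    bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      validation_error(sprintf(
        "counts.tsv entry for gene '%s', cell '%s' is '%s' (must be a non-negative integer)",
        gene_ids[bad[1L, 1L]], cell_ids[bad[1L, 2L]],
        tab[bad[1L, 1L], bad[1L, 2L]]))
    }
    m <- num
    dim(m) <- c(length(gene_ids), length(cell_ids))
  }
  meta_path <- file.path(path, "metadata.tsv")
  meta <- if (file.exists(meta_path)) load_cell_meta(meta_path) else NULL
  count_matrix(m, gene_ids, cell_ids, meta)
}

# first tab-separated field of each sidecar line; empty files allowed
read_id_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(character())
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Load per-cell metadata
#'
#' Metadata TSV with header columns \code{cell_id}, \code{sample_id},
#' \code{patient_id} and optional \code{population_label}.
#'
#' @param path TSV file path.
#' @return data.frame of cell metadata.
#' @export
load_cell_meta <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "sample_id", "patient_id")
  if (!all(need %in% names(meta))) {
    format_error(sprintf("metadata must have columns %s",
                         paste(need, collapse = ", ")))
  }
  meta
}

#' Write a count matrix to disk
#'
#' Inverse of \code{\link{load_counts}}: writes the MTX triplet (or dense
#' TSV) plus sidecars and a metadata TSV into \code{path} so that
#' \code{load_counts(path, format)} reproduces the matrix entrywise with
#' identical ID order.
#'
#' @param cm a \code{CountMatrix}.
#' @param path output directory (created if needed).
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
write_counts <- function(cm, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(cm, "CountMatrix"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, mode = 2L) != 0L) {
    io_error(sprintf("cannot write to directory: %s", path))
  }
  if (format == "mtx") {
    Matrix::writeMM(cm$counts, file.path(path, "matrix.mtx"))
    writeLines(cm$gene_ids, file.path(path, "genes.tsv"))
    writeLines(cm$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    tab <- as.data.frame(as.matrix(cm$counts))
    colnames(tab) <- cm$cell_ids
    utils::write.table(cbind(gene_id = cm$gene_ids, tab),
                       file.path(path, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cm$cell_meta, file.path(path, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a gene-set library from a GMT file
#'
#' One set per line: \code{set_name TAB description TAB gene1 TAB gene2 ...}.
#' The description field is stored as per-set provenance. Duplicate genes
#' within a line are collapsed with a warning.
#'
#' @param path GMT file path.
#' @return A \code{GeneSetLibrary}: named list of character vectors with a
#'   \code{provenance} attribute (named character vector of descriptions).
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  prov <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      format_error(sprintf("GMT line %d has %d field(s); need set name, description and at least one gene",
                           i, length(fields)))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): collapsed %d duplicate gene(s)",
                      i, fields[1L], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (!length(genes)) {
      format_error(sprintf("GMT line %d ('%s') has no genes", i, fields[1L]))
    }
    sets[[fields[1L]]] <- genes
    prov[fields[1L]] <- fields[2L]
  }
  gene_set_library(sets, prov)
}

#' Construct a GeneSetLibrary in code
#'
#' @param sets named list of non-empty character vectors (no duplicates
#'   within a set).
#' @param provenance optional named character vector of free-text
#'   descriptions, one per set.
#' @return A \code{GeneSetLibrary}.
#' @export
gene_set_library <- function(sets, provenance = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    validation_error("every gene set must be named")
  }
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) validation_error(sprintf("set '%s' is empty", nm))
    if (anyDuplicated(sets[[nm]])) {
      validation_error(sprintf("set '%s' contains duplicate genes", nm))
    }
  }
  if (is.null(provenance)) {
    provenance <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, provenance = provenance[names(sets)],
            class = c("GeneSetLibrary", "list"))
}

#' Write a gene-set library to GMT
#'
#' @param gsl a \code{GeneSetLibrary}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(gsl, path) {
  prov <- attr(gsl, "provenance")
  if (is.null(prov)) prov <- stats::setNames(rep("", length(gsl)), names(gsl))
  lines <- vapply(names(gsl), function(nm) {
    paste(c(nm, prov[[nm]], gsl[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Reals are written at full precision (at least 6 significant digits);
#' row count and column order survive a write/read round trip.
#'
#' @param df data.frame.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_result_table <- function(df, path) {
  if (anyDuplicated(names(df))) validation_error("duplicate column names")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
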