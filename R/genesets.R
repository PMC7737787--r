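#' Bundled gene-set libraries
#'
#' Accessors for the gene-set files shipped with the package, all
#' user-overridable by supplying your own GMT via \code{\link{load_gmt}}:
#' \itemize{
#'   \item \code{default_marker_panels()}: the cell-typing marker panels —
#'     immune (T, B, monocyte, pan-leukocyte \emph{PTPRC}) and tumor
#'     (lung/LUAD origin, epithelial, proliferation).
#'   \item \code{default_emt_sets()}: the 7-gene epithelial program, the
#'     3-gene mesenchymal/cancer-stem-cell program (\emph{FN1}, \emph{VIM},
#'     \emph{CD44}) and the 7-gene ECM-receptor core set used for
#'     partial-EMT calling.
#'   \item \code{default_cycle_genes()}: canonical G1/S (43 genes) and G2/M
#'     (54 genes) phase lists for cell-cycle scoring.
#'   \item \code{default_immune_signature()}: a package-curated ~50-gene
#'     immune signature (T/NK/monocyte/B/MHC-II markers) for the
#'     single-sample immune score.
#'   \item \code{default_cta_catalog()}: a 276-symbol curated synthetic
#'     stand-in for a cancer-testis-antigen catalogue, assembled from
#'     canonical CTA gene families.
#' }
#'
#' @return A \code{GeneSetLibrary} (see \code{\link{load_gmt}}).
#' @name bundled_gene_sets
NULL

extdata_gmt <- function(file) {
  load_gmt(system.file("extdata", file, package = "ctcprofiler",
                       mustWork = TRUE))
}

#' @rdname bundled_gene_sets
#' @export
default_marker_panels <- function() extdata_gmt("marker_panels.gmt")

#' @rdname bundled_gene_sets
#' @export
default_emt_sets <- function() extdata_gmt("emt_sets.gmt")

#' @rdname bundled_gene_sets
#' @export
default_cycle_genes <- function() extdata_gmt("cell_cycle.gmt")

#' @rdname bundled_gene_sets
#' @export
default_immune_signature <- function() extdata_gmt("immune_signature.gmt")

#' @rdname bundled_gene_sets
#' @export
default_cta_catalog <- function() extdata_gmt("cta_catalog_synthetic.gmt")

#' Cancer-stem-cell candidate markers
#'
#' The six lung CSC candidate biomarkers examined per cell for positivity.
#'
#' @return Character vector of gene symbols.
#' @export
csc_markers <- function() {
  c("PROM1", "CD44", "ALDH1A1", "ALDH1A3", "ALDH3A1", "ABCG2")
}
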