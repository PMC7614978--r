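#' Build a cell-by-gene expression container
#'
#' Wraps a sparse gene x cell UMI count matrix and its metadata in a
#' [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]. Raw
#' counts live in the `"counts"` assay; transformed layers (e.g. `"lognorm"`)
#' are added by [normalize_lognorm()]. Cell-level fields used downstream
#' (`sample_id`, `donor_id`, `lane_id`, `age_pcw`, `facs_gate`, `pct_mito`,
#' `doublet_score`, `cluster_id`) are stored in `colData`.
#'
#' @param counts sparse (or dense) nonnegative integer matrix, genes in rows,
#'   cells in columns; dimnames required.
#' @param cell_meta `data.frame` of per-cell metadata, one row per column of
#'   `counts` (optional columns listed above).
#' @param gene_meta optional `data.frame` of per-gene metadata.
#' @return A `SingleCellExperiment` with a `"counts"` assay.
#' @examples
#' m <- Matrix::rsparsematrix(20, 10, density = 0.3,
#'   rand.x = function(n) rpois(n, 4) + 1)
#' dimnames(m) <- list(paste0("g", 1:20), paste0("c", 1:10))
#' sce <- rna_experiment(m, data.frame(pct_mito = runif(10, 0, 0.1)))
#' @export
rna_experiment <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  counts <- as_sparse_counts(counts, "counts")
  if (is.null(cell_meta)) cell_meta <- data.frame(row.names = colnames(counts))
  if (is.null(gene_meta)) gene_meta <- data.frame(row.names = rownames(counts))
  stopifnot(nrow(cell_meta) == ncol(counts), nrow(gene_meta) == nrow(counts))
  rownames(cell_meta) <- colnames(counts)
  rownames(gene_meta) <- rownames(counts)
  gene_meta$n_cells_expressing <- Matrix::rowSums(counts > 0)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_meta),
    rowData = S4Vectors::DataFrame(gene_meta)
  )
}

#' Build a droplet-by-protein assay container
#'
#' Antibody (ADT) counts for *all* droplets of a CITE-seq lane, cells and
#' ambient/empty droplets alike, as a `SingleCellExperiment` with proteins in
#' rows. `colData` carries `total_rna_umi` (total RNA UMIs of the matched
#' barcode, used for empty-droplet detection) and, once classified, `class`
#' (`"cell"`, `"empty"` or `"unknown"`) and `bg_score`.
#'
#' @param counts nonnegative integer matrix, proteins in rows, droplets in
#'   columns; dimnames required.
#' @param droplet_meta `data.frame` with at least `total_rna_umi`.
#' @return A `SingleCellExperiment` with a `"counts"` assay and droplet
#'   metadata; `class` is initialized to `"unknown"` if absent.
#' @export
protein_experiment <- function(counts, droplet_meta) {
  counts <- as_sparse_counts(counts, "counts")
  stopifnot(is.data.frame(droplet_meta), nrow(droplet_meta) == ncol(counts))
  if (is.null(droplet_meta$total_rna_umi))
    stop("droplet_meta must contain 'total_rna_umi'")
  if (is.null(droplet_meta$class)) droplet_meta$class <- "unknown"
  rownames(droplet_meta) <- colnames(counts)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(droplet_meta)
  )
}

# Coerce to dgCMatrix and check count-ness; gives uniform errors across ops.
as_sparse_counts <- function(m, what) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " matrix must have row and column names")
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (any(m@x < 0)) stop(what, " must be nonnegative")
  if (any(m@x != round(m@x))) stop(what, " must be integer-valued")
  m
}

# Fetch a named layer (assay), with a readable error naming the missing stage.
get_layer <- function(x, layer, needed_by) {
  if (!layer %in% SummarizedExperiment::assayNames(x))
    stop(needed_by, " requires the '", layer, "' layer; run the upstream step first")
  SummarizedExperiment::assay(x, layer)
}

cell_meta_col <- function(x, col, needed_by) {
  cd <- SummarizedExperiment::colData(x)
  if (!col %in% colnames(cd))
    stop(needed_by, " requires cell metadata column '", col, "'")
  cd[[col]]
}
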