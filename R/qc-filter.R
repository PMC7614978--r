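#' Filter low-quality cells and rarely expressed genes
#'
#' Removes cells with fewer than `min_counts` total UMIs, fewer than
#' `min_genes` detected genes, or more than `max_mito` mitochondrial
#' fraction; then removes genes expressed in fewer than `min_cells_per_gene`
#' of the remaining cells. All inequalities are strict, so a cell sitting
#' exactly on a threshold is retained, and the order is fixed: cells first,
#' then genes (no iteration).
#'
#' @param m a `SingleCellExperiment` from [rna_experiment()] with raw counts
#'   and a `pct_mito` cell metadata column (fraction in `[0, 1]`).
#' @param min_counts,min_genes,max_mito,min_cells_per_gene thresholds.
#' @return A list with `matrix` (the filtered object) and `report` (a
#'   `"qc_report"`: totals in/out and marginal per-filter removal counts;
#'   marginal counts can overlap, their union is `n_cells_in - n_cells_out`).
#' @export
filter_cells_and_genes <- function(m, min_counts = 2000, min_genes = 200,
                                   max_mito = 0.20, min_cells_per_gene = 3) {
  counts <- get_layer(m, "counts", "filter_cells_and_genes")
  pct_mito <- cell_meta_col(m, "pct_mito", "filter_cells_and_genes")
  totals <- Matrix::colSums(counts)
  n_genes_det <- Matrix::colSums(counts > 0)
  fail_counts <- totals < min_counts
  fail_genes <- n_genes_det < min_genes
  fail_mito <- pct_mito > max_mito
  keep_cell <- !(fail_counts | fail_genes | fail_mito)
  m2 <- m[, keep_cell]
  n_expr <- Matrix::rowSums(SummarizedExperiment::assay(m2, "counts") > 0)
  keep_gene <- n_expr >= min_cells_per_gene
  m2 <- m2[keep_gene, ]
  SummarizedExperiment::rowData(m2)$n_cells_expressing <- n_expr[keep_gene]
  report <- structure(list(
    n_cells_in = ncol(m), n_cells_out = ncol(m2),
    n_genes_in = nrow(m), n_genes_out = nrow(m2),
    removed = c(low_counts = sum(fail_counts), low_genes = sum(fail_genes),
                high_mito = sum(fail_mito),
                rare_genes = sum(!keep_gene)),
    thresholds = c(min_counts = min_counts, min_genes = min_genes,
                   max_mito = max_mito, min_cells_per_gene = min_cells_per_gene)
  ), class = "qc_report")
  list(matrix = m2, report = report)
}

#' Remove doublet-enriched clusters per sequencing lane
#'
#' Within each lane, computes the median doublet-detection score of every
#' cluster and removes clusters whose median lies strictly above
#' `median + 1.48 * MAD` of the lane's cluster medians, where MAD is the raw
#' (unscaled) median absolute deviation. A lane containing a single cluster
#' is never touched; such lanes are flagged in the report. When all cluster
#' medians in a lane coincide the MAD is zero and nothing strictly exceeds
#' the threshold, so nothing is removed.
#'
#' @param m a `SingleCellExperiment`; lane, cluster and score default to the
#'   `lane_id`, `cluster_id` and `doublet_score` metadata columns.
#' @param clusters,scores,lanes optional overrides (one value per cell).
#' @return A list with `matrix` (doublet clusters dropped) and `report`
#'   (per-lane threshold, cluster medians, removed cluster ids, and
#'   single-cluster flags).
#' @examples
#' # cluster medians {0.05, 0.06, 0.50}: threshold 0.06 + 1.48*0.01 = 0.0748
#' @export
remove_doublet_clusters <- function(m, clusters = NULL, scores = NULL,
                                    lanes = NULL) {
  if (is.null(clusters)) clusters <- cell_meta_col(m, "cluster_id", "remove_doublet_clusters")
  if (is.null(scores)) scores <- cell_meta_col(m, "doublet_score", "remove_doublet_clusters")
  if (is.null(lanes)) lanes <- cell_meta_col(m, "lane_id", "remove_doublet_clusters")
  stopifnot(length(clusters) == ncol(m), length(scores) == ncol(m),
            length(lanes) == ncol(m))
  if (anyNA(scores)) stop("every cell needs a doublet score")
  clusters <- as.character(clusters)
  lanes <- as.character(lanes)
  drop <- rep(FALSE, ncol(m))
  lane_info <- list()
  for (ln in unique(lanes)) {
    in_lane <- lanes == ln
    med <- vapply(split(scores[in_lane], clusters[in_lane]), median, numeric(1))
    single <- length(med) == 1L
    thr <- median(med) + 1.48 * median(abs(med - median(med)))
    removed <- if (single) character(0) else names(med)[med > thr]
    drop <- drop | (in_lane & clusters %in% removed)
    lane_info[[ln]] <- list(cluster_medians = med, threshold = thr,
                            removed_clusters = removed,
                            single_cluster = single)
  }
  m2 <- m[, !drop]
  report <- structure(list(
    n_cells_in = ncol(m), n_cells_out = ncol(m2),
    n_genes_in = nrow(m), n_genes_out = nrow(m),
    removed = c(doublet_cluster_cells = sum(drop)),
    lanes = lane_info
  ), class = "qc_report")
  list(matrix = m2, report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("qc_report: cells", x$n_cells_in, "->", x$n_cells_out,
      "| genes", x$n_genes_in, "->", x$n_genes_out, "\n")
  cat("  removed:", paste(names(x$removed), x$removed, sep = "=",
                          collapse = ", "), "\n")
  if (!is.null(x$lanes)) {
    for (ln in names(x$lanes)) {
      li <- x$lanes[[ln]]
      cat("  lane", ln, ": threshold", format(li$threshold, digits = 4),
          if (li$single_cluster) "(single cluster, rule not applied)" else "",
          "removed: [", paste(li$removed_clusters, collapse = ", "), "]\n")
    }
  }
  invisible(x)
}

# Serialize a qc_report (or any report list) to JSON.
#' Write a QC report as JSON
#' @param report a `"qc_report"` (or plain list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
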