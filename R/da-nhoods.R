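#' Symmetric k-nearest-neighbor graph from coordinates
#'
#' Convenience builder for the KNN graph consumed by
#' [build_neighborhoods()]: brute-force Euclidean k nearest neighbors,
#' symmetrized by union, stored as a sparse adjacency matrix whose entries
#' are the pairwise distances. Embedding computation itself is upstream of
#' this package; any cells x dims coordinate matrix works.
#'
#' @param coords numeric matrix, cells in rows.
#' @param k neighbors per cell (>= 10 recommended for neighborhood testing).
#' @param block rows per distance block (memory/speed trade-off).
#' @return Sparse symmetric `dgCMatrix` adjacency with distances as values.
#' @export
knn_graph <- function(coords, k = 30, block = 500L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(k >= 1, k < n)
  sq <- rowSums(coords^2)
  ii <- jj <- matrix(0L, n, k)
  xx <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    d2 <- outer(sq[rows], sq, `+`) -
      2 * tcrossprod(coords[rows, , drop = FALSE], coords)
    d2[cbind(seq_along(rows), rows)] <- Inf
    for (r in seq_along(rows)) {
      nb <- order(d2[r, ])[seq_len(k)]
      ii[rows[r], ] <- rows[r]
      jj[rows[r], ] <- nb
      xx[rows[r], ] <- sqrt(pmax(0, d2[r, nb]))
    }
  }
  g <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(xx), dims = c(n, n))
  m <- pmax(g, Matrix::t(g))   # union, keeping distances
  rownames(m) <- colnames(m) <- rownames(coords)
  m
}

#' Sample index cells and build KNN neighborhoods
#'
#' Samples `round(prop * n)` index cells without replacement and forms one
#' neighborhood per index cell: the index cell plus its graph neighbors.
#' Per-sample cell counts are tabulated for differential-abundance testing;
#' the index cell's k-distance (distance to its farthest neighborhood
#' member) is kept for distance-weighted FDR control.
#'
#' @param graph sparse symmetric adjacency with distances as values, e.g.
#'   from [knn_graph()].
#' @param samples per-cell (pseudo-)sample ids; counts are tabulated over
#'   these columns.
#' @param prop fraction of cells to sample as index cells, in (0, 1].
#' @param seed RNG seed for index-cell sampling.
#' @param cell_groups optional per-cell stratum (e.g. FACS gate). When cells
#'   are counted into per-(sample, gate) pseudo-samples, a neighborhood made
#'   of one gate's cells can never appear in the other gate's columns; the
#'   groups observed among each neighborhood's members are recorded so
#'   [test_differential_abundance()] can drop those structural-zero columns.
#' @return A `"neighborhood_set"`: `index_cells`, `members` (list),
#'   `counts` (neighborhoods x samples), `kdist`, `sample_sizes` (cells per
#'   sample, for offsets), `groups` (per-neighborhood member groups, if
#'   given) and `n_cells`.
#' @examples
#' # 1000 cells at prop = 0.05 give 50 neighborhoods
#' @export
build_neighborhoods <- function(graph, samples, prop = 0.05, seed = 0,
                                cell_groups = NULL) {
  n <- nrow(graph)
  stopifnot(ncol(graph) == n, length(samples) == n)
  if (prop <= 0 || prop > 1) stop("prop must lie in (0, 1]")
  samples <- factor(samples)
  if (!is.null(cell_groups)) stopifnot(length(cell_groups) == n)
  n_index <- max(1L, round(prop * n))
  set.seed(seed)
  index <- sort(sample.int(n, n_index))
  gT <- methods::as(graph, "CsparseMatrix")
  members <- vector("list", n_index)
  kdist <- numeric(n_index)
  counts <- matrix(0L, n_index, nlevels(samples),
                   dimnames = list(NULL, levels(samples)))
  for (i in seq_len(n_index)) {
    col <- index[i]
    ptr <- if (gT@p[col + 1L] > gT@p[col]) (gT@p[col] + 1L):gT@p[col + 1L]
           else integer(0)
    nb <- gT@i[ptr] + 1L
    kdist[i] <- if (length(ptr)) max(gT@x[ptr]) else NA_real_
    mem <- union(col, nb)
    members[[i]] <- mem
    tab <- table(samples[mem])
    counts[i, names(tab)] <- as.integer(tab)
  }
  groups <- if (is.null(cell_groups)) NULL else
    lapply(members, function(mem) unique(as.character(cell_groups[mem])))
  structure(list(index_cells = index, members = members, counts = counts,
                 kdist = kdist,
                 sample_sizes = as.integer(table(samples)),
                 groups = groups,
                 n_cells = n),
            class = "neighborhood_set")
}

#' @exportS3Method base::print
print.neighborhood_set <- function(x, ...) {
  cat("neighborhood_set:", length(x$index_cells), "neighborhoods over",
      x$n_cells, "cells,", ncol(x$counts), "samples; median size",
      median(lengths(x$members)), "\n")
  invisible(x)
}

#' Majority-vote neighborhood labels
#'
#' A neighborhood inherits its modal cell label when that label's frequency
#' strictly exceeds 50%; otherwise it is `"Mixed"`.
#'
#' @param nhoods a `"neighborhood_set"`.
#' @param labels per-cell labels (length `n_cells`).
#' @return Character vector, one label per neighborhood.
#' @export
label_neighborhoods <- function(nhoods, labels) {
  stopifnot(length(labels) == nhoods$n_cells)
  labels <- as.character(labels)
  vapply(nhoods$members, function(mem) {
    if (!length(mem)) stop("empty neighborhood")
    tab <- table(labels[mem])
    if (max(tab) / length(mem) > 0.5) names(tab)[which.max(tab)] else "Mixed"
  }, character(1))
}
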