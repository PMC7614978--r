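#' Score a gene module against expression-matched control genes
#'
#' Bins all genes into `n_bins` equal-frequency bins of mean log-normalized
#' expression (ties broken by stable gene order), samples up to `ctrl_size`
#' control genes from each module gene's bin (module genes themselves are
#' excluded from the control pool; sampling is seeded and without
#' replacement), and scores each cell as mean expression of the module genes
#' minus mean expression of the pooled control set. Cells with score > 0 are
#' flagged enriched. Adding a constant to every gene's expression leaves the
#' score unchanged. For a singleton module the per-cell eligibility mask is
#' `expression > 0` for that gene (used by
#' [enriched_proportion_series()]); multi-gene modules mark every cell
#' eligible.
#'
#' If a module gene's bin holds no other genes, the module genes themselves
#' serve as controls for that bin (degenerate self-control, score
#' contribution 0).
#'
#' @param m a `SingleCellExperiment` with a `"lognorm"` layer.
#' @param genes module gene ids; ids absent from `m` are dropped with a
#'   warning.
#' @param ctrl_size control genes sampled per module gene's bin.
#' @param n_bins number of equal-frequency expression bins.
#' @param seed RNG seed for control sampling.
#' @return A `"module_score"`: `genes`, `control_genes`, per-cell `score`,
#'   `enriched`, `eligible`, and the control configuration.
#' @export
score_gene_module <- function(m, genes, ctrl_size = 200, n_bins = 50,
                              seed = 0) {
  lognorm <- get_layer(m, "lognorm", "score_gene_module")
  missing <- setdiff(genes, rownames(lognorm))
  if (length(missing)) {
    warning("dropping ", length(missing), " module gene(s) absent from the data")
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) stop("module is empty after dropping missing genes")
  mu <- Matrix::rowMeans(lognorm)
  bin <- cut(rank(mu, ties.method = "first"),
             breaks = round(seq(0, length(mu), length.out = n_bins + 1L)),
             labels = FALSE, include.lowest = TRUE)
  names(bin) <- rownames(lognorm)
  set.seed(seed)
  ctrl <- character(0)
  for (g in genes) {
    pool <- setdiff(rownames(lognorm)[bin == bin[g]], genes)
    if (!length(pool)) pool <- intersect(rownames(lognorm)[bin == bin[g]], genes)
    pool <- sort(pool)   # row-order invariance of the seeded draw
    ctrl <- c(ctrl, sample(pool, min(ctrl_size, length(pool))))
  }
  ctrl <- unique(ctrl)
  mod_mean <- Matrix::colMeans(lognorm[genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(lognorm[ctrl, , drop = FALSE])
  score <- mod_mean - ctrl_mean
  eligible <- if (length(genes) == 1L)
    as.vector(lognorm[genes, ] > 0) else rep(TRUE, ncol(lognorm))
  structure(list(genes = genes, control_genes = ctrl, score = score,
                 enriched = score > 0, eligible = eligible,
                 ctrl_size = ctrl_size, n_bins = n_bins, seed = seed),
            class = "module_score")
}

#' @exportS3Method base::print
print.module_score <- function(x, ...) {
  cat("module_score:", length(x$genes), "gene(s),", length(x$control_genes),
      "controls;", sum(x$enriched), "/", length(x$score),
      "cells enriched\n")
  invisible(x)
}

#' Enriched-cell proportion across age bins
#'
#' Within a population of interest, computes per age bin the proportion of
#' eligible cells whose module score is enriched (> 0). Eligibility combines
#' the score's own mask (for single-gene tracking, expression > 0) with the
#' caller's population mask. Bins with no eligible cells yield `NA`.
#' Per-bin enriched counts are carried for display sizing; `min_count` is a
#' display option only (a `below_min_count` flag), never a data filter.
#'
#' @param scores a `"module_score"`.
#' @param age per-cell ages (post-conception weeks).
#' @param mask logical population mask (default: all cells).
#' @param min_count display threshold for the `below_min_count` flag.
#' @return `data.frame` ordered by age: `age`, `n_eligible`, `n_enriched`,
#'   `proportion`, `below_min_count`.
#' @export
enriched_proportion_series <- function(scores, age, mask = NULL,
                                       min_count = 500) {
  n <- length(scores$score)
  stopifnot(length(age) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  eligible <- scores$eligible & mask
  bins <- sort(unique(age))
  rows <- lapply(bins, function(a) {
    idx <- eligible & age == a
    n_el <- sum(idx)
    n_en <- sum(scores$enriched[idx])
    data.frame(age = a, n_eligible = n_el, n_enriched = n_en,
               proportion = if (n_el > 0) n_en / n_el else NA_real_,
               below_min_count = n_en < min_count)
  })
  do.call(rbind, rows)
}

#' Robust median/MAD standardization
#'
#' `(x - median) / MAD` with the raw (unscaled) median absolute deviation.
#' Affine-equivariant: `robust_standardize(a*x + b)` equals
#' `sign(a) * robust_standardize(x)`.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return Standardized vector.
#' @examples
#' robust_standardize(c(1, 2, 3, 4, 100))  # median 3, MAD 1; 100 -> 97
#' @export
robust_standardize <- function(values) {
  if (length(unique(values)) < 2)
    stop("robust_standardize needs at least 2 distinct values")
  med <- median(values)
  m <- median(abs(values - med))
  if (m == 0)
    stop("MAD is zero for this input (more than half the values equal ",
         format(med), "); cannot standardize")
  (values - med) / m
}
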