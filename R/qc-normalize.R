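#' Total-count normalization and log transform
#'
#' Scales each cell to `target_sum` total counts, applies `log(1 + x)`
#' (natural log), and stores the result as the `"lognorm"` layer; the raw
#' counts are untouched.
#'
#' @param m a `SingleCellExperiment` with raw counts.
#' @param target_sum per-cell total after scaling (counts-per-10k default).
#' @return `m` with an added `"lognorm"` assay.
#' @examples
#' # counts c(1, 1, 2) at target 1e4 scale to c(2500, 2500, 5000) and
#' # log1p to approximately c(7.8244, 7.8244, 8.5174)
#' @export
normalize_lognorm <- function(m, target_sum = 1e4) {
  counts <- get_layer(m, "counts", "normalize_lognorm")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts present; filter them first")
  scaled <- counts %*% Matrix::Diagonal(x = target_sum / totals)
  lognorm <- scaled
  lognorm@x <- log1p(lognorm@x)
  dimnames(lognorm) <- dimnames(counts)
  SummarizedExperiment::assay(m, "lognorm") <- lognorm
  m
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Dispersion-based selection in the droplet-field convention: per gene,
#' compute mean and dispersion (variance/mean) of the un-logged normalized
#' expression (`expm1` of the `"lognorm"` layer), then work with
#' `log1p(mean)` and `log(dispersion)`; bin genes into `n_bins`
#' equal-frequency bins of the mean metric, z-score the log dispersion
#' within each bin, and return the `n_top` genes with the largest normalized
#' dispersion among genes whose mean metric lies strictly inside
#' `(min_mean, max_mean)`. Constant genes have zero dispersion and are never
#' selected while any variable gene remains.
#'
#' @param m a `SingleCellExperiment` with a `"lognorm"` layer.
#' @param n_top number of genes to return.
#' @param min_mean,max_mean exclusive eligibility bounds on `log1p` of the
#'   mean un-logged expression.
#' @param n_bins number of equal-frequency mean bins.
#' @return Character vector of gene ids, ordered by decreasing normalized
#'   dispersion. If fewer than `n_top` genes are eligible, all eligible genes
#'   are returned with a warning.
#' @export
select_hvgs <- function(m, n_top, min_mean = 0.001, max_mean = 10,
                        n_bins = 20) {
  lognorm <- get_layer(m, "lognorm", "select_hvgs")
  expd <- lognorm
  expd@x <- expm1(expd@x)
  mu <- Matrix::rowMeans(expd)
  n <- ncol(expd)
  ex2 <- Matrix::rowMeans(expd^2)
  v <- pmax(0, (ex2 - mu^2) * n / max(1, n - 1))
  disp <- log(ifelse(mu > 0, v / mu, 0))  # -Inf for constant/absent genes
  mean_metric <- log1p(mu)
  bin <- cut(rank(mean_metric, ties.method = "first"),
             breaks = round(seq(0, length(mu), length.out = n_bins + 1L)),
             labels = FALSE, include.lowest = TRUE)
  z <- disp
  for (b in unique(bin)) {
    i <- bin == b
    fin <- i & is.finite(disp)
    s <- sd(disp[fin])
    z[i] <- if (sum(fin) < 2 || is.na(s) || s == 0)
      ifelse(is.finite(disp[i]), 0, -Inf)
    else (disp[i] - mean(disp[fin])) / s
  }
  eligible <- which(mean_metric > min_mean & mean_metric < max_mean)
  ord <- eligible[order(z[eligible], decreasing = TRUE)]
  if (length(ord) < n_top) {
    warning("only ", length(ord), " genes eligible; returning all of them")
    n_top <- length(ord)
  }
  rownames(m)[head(ord, n_top)]
}
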