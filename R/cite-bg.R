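#' Per-cell background scores from the mixture background means
#'
#' For each cell c, the raw score is the aggregate over proteins p of
#' `exp(mu_bg[p] - x[c, p])` with x the dsb expression, i.e. the ratio of
#' e^background-mean to e^expression; high expression relative to background
#' gives a small score. Raw scores are min-max scaled over cells to `[0, 1]`
#' and stored as `bg_score` droplet metadata (NA for empty droplets).
#'
#' @param assay a `SingleCellExperiment` with `"dsb"` layer and `class`.
#' @param model a `"background_model"` supplying per-protein `mu_bg`.
#' @param aggregate how per-protein ratios combine into one per-cell score.
#' @return `assay` with `bg_score` filled in.
#' @examples
#' # with a single protein and x = mu_bg the raw ratio is exp(0) = 1
#' @export
compute_bg_scores <- function(assay, model, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  dsb <- get_layer(assay, "dsb", "compute_bg_scores")
  cls <- cell_meta_col(assay, "class", "compute_bg_scores")
  mu_bg <- model$mu_bg[rownames(assay)]
  if (anyNA(mu_bg)) stop("model lacks mu_bg for some proteins")
  cells <- which(cls == "cell")
  ratios <- exp(mu_bg - dsb[, cells, drop = FALSE])
  raw <- if (aggregate == "mean") colMeans(ratios) else
    apply(ratios, 2L, median)
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("all raw background scores identical; bg_score set to 0")
    scaled <- rep(0, length(raw))
  } else {
    scaled <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  bg <- rep(NA_real_, ncol(assay))
  bg[cells] <- scaled
  SummarizedExperiment::colData(assay)$bg_score <- bg
  assay
}

#' Regress the background component out of DSB values
#'
#' Per protein, fits an ordinary Gaussian linear model of the dsb value on
#' the per-cell background score across cell droplets and stores
#' `fitted intercept + residuals` as the `"corrected"` layer: the
#' background-score-associated component is removed while the protein's
#' location is preserved. By least squares the corrected values have zero
#' sample covariance with the background score. A constant background score
#' leaves the protein uncorrected (with a warning). Empty droplets keep
#' their dsb values in the corrected layer.
#'
#' @param assay a `SingleCellExperiment` with `"dsb"` layer, `class` and
#'   `bg_score` (from [compute_bg_scores()]).
#' @return `assay` with a `"corrected"` layer.
#' @export
regress_background <- function(assay) {
  dsb <- get_layer(assay, "dsb", "regress_background")
  cls <- cell_meta_col(assay, "class", "regress_background")
  bg <- cell_meta_col(assay, "bg_score", "regress_background")
  cells <- which(cls == "cell")
  corrected <- dsb
  if (sd(bg[cells]) == 0) {
    warning("background score is constant; corrected layer equals dsb")
  } else {
    b <- bg[cells]
    for (p in seq_len(nrow(dsb))) {
      fit <- lm(dsb[p, cells] ~ b)
      corrected[p, cells] <- coef(fit)[1] + residuals(fit)
    }
  }
  SummarizedExperiment::assay(assay, "corrected") <- corrected
  assay
}
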