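#' Neighborhood differential abundance across age
#'
#' Models each neighborhood's per-sample cell counts as a negative-binomial
#' GLM on age (continuous, in post-conception weeks) with offset
#' `log(sample cells) - fs` (fs = 0 without FACS correction). A single
#' common NB dispersion is estimated by the method of moments on Poisson
#' residuals pooled across neighborhoods, then each neighborhood's age
#' coefficient is tested (two-sided Wald by default, likelihood-ratio
#' optionally). Multiplicity is controlled by the spatial FDR: weighted
#' Benjamini-Hochberg with weights 1/k-distance of each neighborhood's index
#' cell ([weighted_bh()]), which reduces exactly to classical BH when all
#' weights are equal.
#'
#' @param nhoods a `"neighborhood_set"` whose count columns are samples (or
#'   sample|gate pseudo-samples when correcting for sorting).
#' @param design `data.frame` with `sample` matching
#'   `colnames(nhoods$counts)` and numeric `age`.
#' @param correction optional `"facs_correction"`; rows are matched to count
#'   columns by `pseudo_sample` (falling back to `sample_id`).
#' @param cell_labels optional per-cell labels; adds a >50% majority label
#'   per neighborhood (else `"Mixed"`).
#' @param test `"wald"` or `"lrt"`.
#' @param fdr_weights `"kdist"` (1/k-distance) or `"equal"`.
#' @return A `"da_result"` `data.frame`: per neighborhood `index_cell`,
#'   `size`, `logFC` (age slope, natural log per week), `p`, `spatial_fdr`,
#'   `label`; the common dispersion is in `attr(, "dispersion")`.
#'   Non-convergent neighborhoods carry `NA` p-values.
#' @export
test_differential_abundance <- function(nhoods, design, correction = NULL,
                                        cell_labels = NULL,
                                        test = c("wald", "lrt"),
                                        fdr_weights = c("kdist", "equal")) {
  test <- match.arg(test)
  fdr_weights <- match.arg(fdr_weights)
  counts <- nhoods$counts
  cols <- colnames(counts)
  if (ncol(counts) < 3) stop("need at least 3 samples")
  m <- match(cols, design$sample)
  if (anyNA(m)) stop("design lacks rows for: ",
                     paste(cols[is.na(m)], collapse = ", "))
  age <- design$age[m]
  if (length(unique(age)) < 2) stop("age covariate does not vary")

  col_groups <- NULL
  if (!is.null(correction)) {
    key <- if (!is.null(correction$pseudo_sample)) correction$pseudo_sample
           else correction$sample_id
    mc <- match(cols, key)
    if (anyNA(mc)) stop("correction lacks rows for: ",
                        paste(cols[is.na(mc)], collapse = ", "))
    ## exposure of a sorted fraction: log(S) - fs = log(Si / pi), which
    ## converts within-gate cell shares back to whole-tissue abundances
    off <- log(correction$S[mc]) - correction$fs[mc]
    if (!is.null(correction$gate)) col_groups <- as.character(correction$gate[mc])
  } else {
    off <- log(nhoods$sample_sizes)
  }

  ## columns a neighborhood can populate: when counts are per (sample, gate)
  ## pseudo-samples, columns of gates absent from the neighborhood's members
  ## are structural zeros and are dropped from its model
  n_nh <- nrow(counts)
  use_cols <- lapply(seq_len(n_nh), function(i) {
    if (is.null(col_groups) || is.null(nhoods$groups)) seq_along(cols)
    else which(col_groups %in% nhoods$groups[[i]])
  })

  ## common dispersion by moments on Poisson fits: Var = mu (1 + phi mu)
  num <- den <- 0
  for (i in seq_len(n_nh)) {
    j <- use_cols[[i]]
    if (length(j) < 3 || length(unique(age[j])) < 2) next
    fit <- tryCatch(
      suppressWarnings(glm(counts[i, j] ~ age[j] + offset(off[j]),
                           family = poisson())),
      error = function(e) NULL)
    if (is.null(fit)) next
    mu <- fitted(fit)
    num <- num + sum((counts[i, j] - mu)^2 - mu)
    den <- den + sum(mu^2)
  }
  phi <- if (den > 0) num / den else 0
  theta <- if (phi > 1e-8) 1 / phi else 1e8

  logfc <- p <- rep(NA_real_, n_nh)
  for (i in seq_len(n_nh)) {
    j <- use_cols[[i]]
    if (length(j) < 3 || length(unique(age[j])) < 2) next
    y <- counts[i, j]
    aj <- age[j]
    oj <- off[j]
    res <- tryCatch({
      fit <- suppressWarnings(glm(y ~ aj + offset(oj),
                                  family = MASS::negative.binomial(theta)))
      if (!fit$converged) stop("IRLS did not converge")
      sm <- summary(fit, dispersion = 1)$coefficients
      if (test == "wald") {
        c(sm["aj", "Estimate"], 2 * pnorm(-abs(sm["aj", "z value"])))
      } else {
        fit0 <- suppressWarnings(glm(y ~ 1 + offset(oj),
                                     family = MASS::negative.binomial(theta)))
        c(sm["aj", "Estimate"],
          stats::pchisq(fit0$deviance - fit$deviance, 1, lower.tail = FALSE))
      }
    }, error = function(e) c(NA_real_, NA_real_))
    logfc[i] <- res[1]
    p[i] <- res[2]
  }

  w <- if (fdr_weights == "kdist") {
    kd <- nhoods$kdist
    kd[!is.finite(kd) | kd <= 0] <- min(kd[kd > 0], na.rm = TRUE)
    1 / kd
  } else rep(1, n_nh)
  sfdr <- weighted_bh(p, w)

  label <- if (is.null(cell_labels)) rep(NA_character_, n_nh) else
    label_neighborhoods(nhoods, cell_labels)
  out <- data.frame(nhood = seq_len(n_nh), index_cell = nhoods$index_cells,
                    size = lengths(nhoods$members), logFC = logfc, p = p,
                    spatial_fdr = sfdr, label = label)
  attr(out, "dispersion") <- phi
  attr(out, "theta") <- theta
  class(out) <- c("da_result", "data.frame")
  out
}

#' Weighted Benjamini-Hochberg adjustment
#'
#' Step-up FDR control with per-hypothesis weights: order p-values
#' increasingly, form `sum(w) * p_(i) / cumsum(w)_(i)`, enforce monotonicity
#' from the largest p down, and cap at 1. With equal weights this is exactly
#' the classical Benjamini-Hochberg adjustment. `NA` p-values are ignored
#' and returned as `NA`.
#'
#' @param p p-values.
#' @param weights positive weights, e.g. reciprocal index-cell k-distances.
#' @return Adjusted values, same length/order as `p`.
#' @export
weighted_bh <- function(p, weights = rep(1, length(p))) {
  stopifnot(length(weights) == length(p), all(weights[!is.na(p)] > 0))
  adj <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(adj)
  o <- ok[order(p[ok])]
  a <- sum(weights[o]) * p[o] / cumsum(weights[o])
  adj[o] <- pmin(rev(cummin(rev(a))), 1)
  adj
}
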