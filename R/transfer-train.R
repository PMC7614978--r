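#' Train a probabilistic elastic-net label-transfer model
#'
#' Fits a multinomial elastic-net logistic regression of reference labels on
#' the `"lognorm"` expression of `features`, tuning the mixing parameter
#' (`l1_ratio`, 0 = ridge to 1 = lasso) and `alpha` -- the *inverse*
#' regularization strength, honored literally: larger alpha means a weaker
#' penalty, mapped to the glmnet penalty scale as `lambda = 1/(alpha * n)` --
#' over a 6 x 5 grid with 5 stratified train/test splits repeated 3 times
#' (fold seeds advance deterministically from `seed_base`). Each held-out
#' fold is scored by the class-frequency-weighted mean squared error between
#' one-hot labels and predicted probabilities; the grid point with the
#' minimal unweighted mean over the 15 fold scores (ties: first in grid
#' order) is refit on all data.
#'
#' @param ref a `SingleCellExperiment` with a `"lognorm"` layer, or a
#'   cells x features numeric matrix.
#' @param labels per-cell reference labels (>= 2 classes, each with >= 10
#'   cells).
#' @param features character vector of feature (gene) names; typically from
#'   [select_hvgs()]. Ignored (all columns used) when `ref` is a matrix.
#' @param l1_ratios,alphas the CV grid.
#' @param n_folds,n_repeats stratified splits and repeats.
#' @param decision_threshold minimal class probability for assignment in
#'   [predict_cells()].
#' @param seed_base first fold seed; repeats use `seed_base + 0, 1, 2, ...`.
#' @return A `"transfer_model"`: `classes`, `features`, `coefficients`
#'   (class x feature), `intercepts`, `cv` (per grid point x fold scores),
#'   `selected` (`l1_ratio`, `alpha`, `lambda`), `fold_assignments`
#'   (cells x repeats), `decision_threshold`.
#' @export
train_transfer_model <- function(ref, labels, features = NULL,
                                 l1_ratios = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                 alphas = c(0.2, 0.4, 0.6, 0.8, 1),
                                 n_folds = 5, n_repeats = 3,
                                 decision_threshold = 0.9,
                                 seed_base = 0) {
  x <- transfer_feature_matrix(ref, features)
  y <- factor(labels)
  stopifnot(nrow(x) == length(y))
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 10)) stop("every class needs at least 10 cells; smallest has ",
                          min(tab))
  if (any(tab < n_folds))
    stop("class '", names(tab)[which.min(tab)], "' has fewer cells (",
         min(tab), ") than folds (", n_folds, "); stratification impossible")

  folds <- stratified_folds(y, n_folds, n_repeats, seed_base)
  n <- nrow(x)
  lam_of_alpha <- 1 / (alphas * n)

  cv <- expand.grid(l1_ratio = l1_ratios, alpha = alphas,
                    rep = seq_len(n_repeats), fold = seq_len(n_folds),
                    KEEP.OUT.ATTRS = FALSE)
  cv$mse <- NA_real_
  for (r in seq_len(n_repeats)) for (f in seq_len(n_folds)) {
    test <- folds[, r] == f
    for (l1 in l1_ratios) {
      fit <- glmnet_multinomial(x[!test, , drop = FALSE], y[!test],
                                alpha = l1, lambda = lam_of_alpha)
      for (a in seq_along(alphas)) {
        p <- predict(fit, x[test, , drop = FALSE], s = lam_of_alpha[a],
                     type = "response", exact = FALSE)[, , 1]
        p <- p[, levels(y), drop = FALSE]
        row <- cv$l1_ratio == l1 & cv$alpha == alphas[a] &
          cv$rep == r & cv$fold == f
        cv$mse[row] <- weighted_onehot_mse(y[test], p)
      }
    }
  }

  grid <- aggregate(mse ~ l1_ratio + alpha, data = cv, FUN = mean)
  ## restore grid order (l1_ratio fastest) and take the first minimum
  grid <- grid[order(match(grid$alpha, alphas), match(grid$l1_ratio, l1_ratios)), ]
  grid <- grid[order(match(grid$l1_ratio, l1_ratios), match(grid$alpha, alphas)), ]
  best <- grid[which.min(grid$mse), ]

  lam_best <- 1 / (best$alpha * n)
  final <- glmnet_multinomial(x, y, alpha = best$l1_ratio,
                              lambda = sort(unique(c(lam_of_alpha, lam_best)),
                                            decreasing = TRUE))
  cf <- coef(final, s = lam_best, exact = FALSE)
  coefs <- t(vapply(levels(y), function(cl) as.numeric(cf[[cl]])[-1],
                    numeric(ncol(x))))
  dimnames(coefs) <- list(levels(y), colnames(x))
  intercepts <- vapply(levels(y), function(cl) as.numeric(cf[[cl]])[1],
                       numeric(1))

  structure(list(
    classes = levels(y), features = colnames(x),
    coefficients = coefs, intercepts = intercepts,
    cv = cv, cv_grid = grid,
    selected = list(l1_ratio = best$l1_ratio, alpha = best$alpha,
                    lambda = lam_best, cv_mse = best$mse),
    fold_assignments = folds,
    decision_threshold = decision_threshold
  ), class = "transfer_model")
}

#' @exportS3Method base::print
print.transfer_model <- function(x, ...) {
  cat("transfer_model:", length(x$classes), "classes,",
      length(x$features), "features; selected l1_ratio =",
      x$selected$l1_ratio, ", alpha =", x$selected$alpha,
      sprintf("(CV-MSE %.4g);", x$selected$cv_mse),
      "decision threshold", x$decision_threshold, "\n")
  invisible(x)
}

## cells x features matrix from an SCE (lognorm layer) or a plain matrix,
## e.g. a caller-supplied low-dimensional representation.
transfer_feature_matrix <- function(ref, features) {
  if (methods::is(ref, "SingleCellExperiment")) {
    lognorm <- get_layer(ref, "lognorm", "label transfer")
    if (is.null(features)) stop("features must be given for expression input")
    missing <- setdiff(features, rownames(lognorm))
    if (length(missing)) stop("features absent from reference: ",
                              paste(head(missing, 5), collapse = ", "))
    t(as.matrix(lognorm[features, , drop = FALSE]))
  } else {
    x <- as.matrix(ref)
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    x
  }
}

## Stratified fold ids: cells x repeats matrix; repeat r is drawn under seed
## seed_base + r - 1, shuffling within each class and dealing folds round-robin.
stratified_folds <- function(y, n_folds, n_repeats, seed_base) {
  folds <- matrix(NA_integer_, length(y), n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed_base + r - 1)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[sample(idx), r] <- rep_len(seq_len(n_folds), length(idx))
    }
  }
  folds
}

## Class-frequency-weighted MSE between one-hot labels and probabilities.
weighted_onehot_mse <- function(y_test, p) {
  onehot <- outer(as.character(y_test), colnames(p), `==`) * 1
  se <- rowSums((onehot - p)^2)
  cls_mse <- tapply(se, y_test, mean)
  w <- table(y_test) / length(y_test)
  sum(w[names(cls_mse)] * cls_mse, na.rm = TRUE)
}

glmnet_multinomial <- function(x, y, alpha, lambda) {
  glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                 lambda = sort(lambda, decreasing = TRUE),
                 standardize = FALSE)
}
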