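#' Predict cell labels from a transfer model
#'
#' Computes softmax class probabilities from the stored coefficients and
#' assigns the argmax class when its probability reaches the model's
#' decision threshold (default 0.9), otherwise `"unassigned"`. Features are
#' aligned by name, so query column order is irrelevant; model features
#' missing from the query are zero-filled with a warning.
#'
#' @param model a `"transfer_model"`.
#' @param query a `SingleCellExperiment` with a `"lognorm"` layer, or a
#'   cells x features matrix.
#' @return `data.frame` with `cell`, `label`, `probability` (of the argmax
#'   class); the full probability matrix is attached as
#'   `attr(, "probabilities")` (rows sum to 1).
#' @examples
#' # probabilities (0.95, 0.03, 0.02) assign class 1; (0.6, 0.3, 0.1) do not
#' @export
predict_cells <- function(model, query) {
  if (methods::is(query, "SingleCellExperiment")) {
    lognorm <- get_layer(query, "lognorm", "predict_cells")
    x <- t(as.matrix(lognorm))
  } else {
    x <- as.matrix(query)
  }
  present <- intersect(model$features, colnames(x))
  if (!length(present)) stop("query shares no features with the model")
  missing <- setdiff(model$features, colnames(x))
  if (length(missing)) {
    warning(length(missing), " model feature(s) missing from query; zero-filled")
    x <- cbind(x, matrix(0, nrow(x), length(missing),
                         dimnames = list(NULL, missing)))
  }
  x <- x[, model$features, drop = FALSE]
  z <- x %*% t(model$coefficients) +
    matrix(model$intercepts, nrow(x), length(model$classes), byrow = TRUE)
  z <- z - apply(z, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- model$classes
  top <- apply(p, 1L, which.max)
  prob <- p[cbind(seq_len(nrow(p)), top)]
  label <- ifelse(prob >= model$decision_threshold,
                  model$classes[top], "unassigned")
  cells <- if (!is.null(rownames(x))) rownames(x) else
    paste0("cell", seq_len(nrow(x)))
  out <- data.frame(cell = cells, label = label, probability = prob)
  attr(out, "probabilities") <- p
  out
}

#' Vote cluster-level labels from per-cell predictions
#'
#' Per cluster, counts cells by projected label (over the label set observed
#' anywhere in the predictions, so absent labels count as zero) and assigns
#' the modal label when its count strictly exceeds `mean + 1 * std` of the
#' cluster's label counts (population standard deviation); otherwise the
#' cluster is `"unresolved"`. A modal `"unassigned"` vote never labels a
#' cluster.
#'
#' @param predictions per-cell labels (e.g. the `label` column from
#'   [predict_cells()]), possibly including `"unassigned"`.
#' @param clusters per-cell cluster ids.
#' @return Named character vector, one label (or `"unresolved"`) per cluster.
#' @examples
#' # counts {A:90, B:5, C:5}: mean 33.33, population sd 40.07 -> labeled A
#' # counts {A:30, B:30}: sd 0, threshold 30, no strict excess -> unresolved
#' @export
assign_cluster_labels <- function(predictions, clusters) {
  stopifnot(length(predictions) == length(clusters))
  predictions <- factor(as.character(predictions))
  out <- vapply(split(predictions, as.character(clusters)), function(lab) {
    if (!length(lab)) stop("empty cluster")
    counts <- table(lab)
    thr <- mean(counts) + sqrt(mean((counts - mean(counts))^2))
    winner <- names(counts)[which.max(counts)]
    if (counts[winner] > thr && winner != "unassigned") winner else "unresolved"
  }, character(1))
  out
}
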