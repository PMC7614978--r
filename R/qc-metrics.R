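#' Partition agreement and homogeneity metrics
#'
#' Returns, for a pair of labelings and an optional embedding, the adjusted
#' mutual information (AMI) and adjusted Rand index (ARI) between
#' `labels_a` and `labels_b`, and the mean silhouette width and
#' within-cluster sum of squared errors (WSS) of `labels_a` on `embedding`.
#' Both adjusted indices are chance-corrected: identical partitions (up to a
#' relabeling) score 1 and random partitions score about 0. Silhouette is
#' undefined for a single-cluster labeling and is returned as `NA`.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param embedding optional numeric matrix (cells x dims) for silhouette
#'   and WSS; rows must match the labels.
#' @return A list with `ami`, `ari`, `silhouette`, `wss`.
#' @export
partition_metrics <- function(labels_a, labels_b, embedding = NULL) {
  stopifnot(length(labels_a) == length(labels_b))
  sil <- wss <- NA_real_
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    stopifnot(nrow(embedding) == length(labels_a))
    f <- as.integer(factor(labels_a))
    if (max(f) > 1L) {
      sw <- cluster::silhouette(f, stats::dist(embedding))
      sil <- mean(sw[, "sil_width"])
    }
    wss <- sum(vapply(split(seq_along(f), f), function(i) {
      sub <- embedding[i, , drop = FALSE]
      sum(sweep(sub, 2L, colMeans(sub))^2)
    }, numeric(1)))
  }
  list(ami = unname(adjusted_mutual_info(labels_a, labels_b)),
       ari = unname(mclust::adjustedRandIndex(labels_a, labels_b)),
       silhouette = sil, wss = wss)
}

#' Evaluate partition metrics across a set of candidate partitions
#'
#' Convenience sweep for benchmarking clusterings obtained at different
#' graph parameters (e.g. neighborhood sizes k = 5..50) against a reference
#' labeling.
#'
#' @param partitions named list of label vectors.
#' @param reference reference label vector.
#' @param embedding optional embedding for silhouette/WSS.
#' @return `data.frame` with one row per partition and columns `partition`,
#'   `ami`, `ari`, `silhouette`, `wss`.
#' @export
partition_sweep <- function(partitions, reference, embedding = NULL) {
  stopifnot(is.list(partitions), length(partitions) > 0)
  if (is.null(names(partitions)))
    names(partitions) <- paste0("partition", seq_along(partitions))
  rows <- lapply(names(partitions), function(nm) {
    met <- partition_metrics(partitions[[nm]], reference, embedding)
    data.frame(partition = nm, ami = met$ami, ari = met$ari,
               silhouette = met$silhouette, wss = met$wss)
  })
  do.call(rbind, rows)
}

# Adjusted mutual information with the hypergeometric expected-MI model and
# arithmetic-mean normalization: AMI = (MI - E[MI]) / (mean(H_a, H_b) - E[MI]).
adjusted_mutual_info <- function(labels_a, labels_b) {
  tab <- table(labels_a, labels_b)
  N <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  ha <- entropy_counts(a, N)
  hb <- entropy_counts(b, N)
  if (ha == 0 && hb == 0) return(1)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / N * log(N * nij / (a[i] * b[j]))
  }
  emi <- expected_mutual_info(a, b, N)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-15) return(1)
  (mi - emi) / denom
}

entropy_counts <- function(n, N) {
  p <- n[n > 0] / N
  -sum(p * log(p))
}

# E[MI] over random contingency tables with fixed margins (hypergeometric).
expected_mutual_info <- function(a, b, N) {
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - N)
    hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    logp <- lchoose(bj, nij) + lchoose(N - bj, ai - nij) - lchoose(N, ai)
    emi <- emi + sum(exp(logp) * nij / N * log(N * nij / (ai * bj)))
  }
  emi
}
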