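#' One-vs-rest Wilcoxon marker genes
#'
#' For every group, tests genes expressed in more than `min_frac` of the
#' group's cells (strictly) with a two-sided Wilcoxon rank-sum test of that
#' group against all other cells on the `"lognorm"` layer. P-values are
#' Benjamini-Hochberg adjusted across the tested genes of each group, and
#' only genes whose log2 fold change passes `|logFC| >= logfc_cutoff` are
#' reported.
#'
#' The fold change is `log2((mean expm1 in group + eps) / (mean expm1 in
#' rest + eps))` with `eps = 1e-9`, the droplet-field convention.
#'
#' @param m a `SingleCellExperiment` with a `"lognorm"` layer.
#' @param groups per-cell group labels (length `ncol(m)`).
#' @param min_frac minimum within-group expression fraction (strict).
#' @param logfc_cutoff absolute log2 fold-change report cut-off.
#' @return `data.frame` with `group`, `gene`, `logFC`, `frac`, `p`, `p_adj`,
#'   ordered by group then increasing adjusted p.
#' @export
rank_marker_genes <- function(m, groups, min_frac = 0.25,
                              logfc_cutoff = 0.25) {
  lognorm <- get_layer(m, "lognorm", "rank_marker_genes")
  stopifnot(length(groups) == ncol(m))
  groups <- as.character(groups)
  if (any(table(groups) < 2)) stop("every group needs at least 2 cells")
  expd <- lognorm
  expd@x <- expm1(expd@x)
  out <- list()
  for (g in sort(unique(groups))) {
    in_g <- groups == g
    frac <- Matrix::rowMeans(lognorm[, in_g, drop = FALSE] > 0)
    tested <- which(frac > min_frac)
    if (!length(tested)) next
    mean_in <- Matrix::rowMeans(expd[tested, in_g, drop = FALSE])
    mean_out <- Matrix::rowMeans(expd[tested, !in_g, drop = FALSE])
    logfc <- log2((mean_in + 1e-9) / (mean_out + 1e-9))
    dense <- as.matrix(lognorm[tested, , drop = FALSE])
    p <- vapply(seq_along(tested), function(i) {
      wilcox.test(dense[i, in_g], dense[i, !in_g], exact = FALSE)$p.value
    }, numeric(1))
    p_adj <- p.adjust(p, method = "BH")
    keep <- abs(logfc) >= logfc_cutoff
    if (!any(keep)) next
    df <- data.frame(group = g, gene = rownames(lognorm)[tested][keep],
                     logFC = logfc[keep], frac = frac[tested][keep],
                     p = p[keep], p_adj = p_adj[keep])
    out[[g]] <- df[order(df$p_adj, df$p), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
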