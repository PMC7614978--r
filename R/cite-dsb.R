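#' DSB-style normalization of antibody counts against the ambient background
#'
#' Log-transforms protein counts (`log1p`) and z-scores each protein against
#' the empty-droplet (ambient) distribution: subtract the protein's mean and
#' divide by its standard deviation over the empty droplets identified by
#' [detect_empty_droplets()]. The transform is applied to every droplet and
#' stored as the `"dsb"` layer, so by construction the empty droplets
#' themselves have per-protein mean 0 and SD 1 afterwards; downstream stages
#' use only the cell droplets. Droplet `class` metadata is set from the
#' partition (`"empty"`/`"cell"`).
#'
#' @param assay a `SingleCellExperiment` from [protein_experiment()].
#' @param partition a `"droplet_partition"` for the same droplets; `NULL`
#'   recomputes it from `total_rna_umi`.
#' @return `assay` with a `"dsb"` layer and updated `class`.
#' @examples
#' # empty mean 2.0 and sd 0.5 map a cell log1p value of 3.0 to dsb = 2.0
#' @export
dsb_normalize <- function(assay, partition = NULL) {
  counts <- get_layer(assay, "counts", "dsb_normalize")
  if (is.null(partition))
    partition <- detect_empty_droplets(cell_meta_col(assay, "total_rna_umi",
                                                     "dsb_normalize"))
  stopifnot(inherits(partition, "droplet_partition"),
            partition$n_droplets == ncol(assay))
  empty <- partition$empty_idx
  if (length(empty) < 50)
    stop("need at least 50 empty droplets for background estimation; got ",
         length(empty))
  lp <- log1p(as.matrix(counts))
  mu_e <- rowMeans(lp[, empty, drop = FALSE])
  sd_e <- apply(lp[, empty, drop = FALSE], 1L, sd)
  if (any(sd_e < 1e-8)) {
    warning("protein(s) with ~zero ambient variance; sd floored at 1e-8: ",
            paste(rownames(assay)[sd_e < 1e-8], collapse = ", "))
    sd_e <- pmax(sd_e, 1e-8)
  }
  dsb <- (lp - mu_e) / sd_e
  SummarizedExperiment::assay(assay, "dsb") <- dsb
  cls <- rep("cell", ncol(assay))
  cls[empty] <- "empty"
  SummarizedExperiment::colData(assay)$class <- cls
  S4Vectors::metadata(assay)$dsb <- list(empty_mean = mu_e, empty_sd = sd_e,
                                         partition = partition)
  assay
}
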