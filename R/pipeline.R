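#' Run the full multiomic pipeline on a simulated dataset
#'
#' End-to-end smoke pipeline: simulate, RNA QC (cell/gene filters,
#' doublet-cluster removal, normalization, HVGs, markers), CITE-seq
#' background correction (empty-droplet detection, DSB, mixture background
#' model, background scores, regression), label transfer (train on one
#' deterministic half of the QC-passed cells using the true states as
#' reference labels, predict the other half, vote cluster labels),
#' FACS-corrected neighborhood differential abundance on the sorted time
#' series, and module tracking of the first state's marker set. When
#' `out_dir` is given every stage report is serialized (JSON/TSV).
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory for stage reports.
#' @param n_hvgs features for the transfer model.
#' @param da_prop neighborhood sampling proportion.
#' @param da_k KNN graph k for differential abundance.
#' @param gmm_k mixture component grid.
#' @return A list of stage outputs (`sim`, `qc`, `doublets`, `hvgs`,
#'   `markers`, `cite`, `transfer`, `da`, `modules`), class
#'   `"multidrop_pipeline"`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         n_hvgs = 200, da_prop = 0.05, da_k = 50,
                         gmm_k = 2:21) {
  t0 <- Sys.time()
  sim <- generate_multiomic_dataset(config)

  ## RNA QC
  qc <- filter_cells_and_genes(sim$rna)
  dbl <- remove_doublet_clusters(qc$matrix)
  norm <- normalize_lognorm(dbl$matrix)
  hvgs <- select_hvgs(norm, n_top = min(n_hvgs, nrow(norm) - 1L))
  markers <- rank_marker_genes(norm,
                               cell_meta_col(norm, "cluster_id", "pipeline"))

  ## CITE-seq background correction
  part <- detect_empty_droplets(cell_meta_col(sim$protein, "total_rna_umi",
                                              "pipeline"))
  adt <- dsb_normalize(sim$protein, part)
  gmm <- fit_background_gmm(adt, k_range = gmm_k)
  adt <- compute_bg_scores(adt, gmm)
  adt <- regress_background(adt)

  ## label transfer: deterministic half split of the QC-passed cells
  truth_states <- sim$truth$cells$state[match(colnames(norm),
                                              sim$truth$cells$cell)]
  half <- seq_len(ncol(norm)) %% 2L == 1L
  model <- train_transfer_model(norm[, half], truth_states[half], hvgs)
  preds <- predict_cells(model, norm[, !half])
  cluster_labels <- assign_cluster_labels(
    preds$label, cell_meta_col(norm, "cluster_id", "pipeline")[!half])

  ## FACS-corrected differential abundance on the sorted time series
  sorted <- generate_sorted_timeseries(config)
  pseudo <- paste(sorted$truth$sorted_cells$sample_id,
                  config$gate_of_state[sorted$truth$sorted_cells$state_idx],
                  sep = "|")
  graph <- knn_graph(sorted$truth$sorted_embedding,
                     k = min(da_k, nrow(sorted$truth$sorted_embedding) - 1L))
  gate <- config$gate_of_state[sorted$truth$sorted_cells$state_idx]
  nh <- build_neighborhoods(graph, pseudo, prop = da_prop, seed = config$seed,
                            cell_groups = gate)
  corr <- facs_correction_factors(sorted$truth$gates)
  design <- data.frame(sample = corr$pseudo_sample, age = corr$age_pcw)
  da <- test_differential_abundance(nh, design, correction = corr,
                                    cell_labels = sorted$truth$sorted_cells$state)

  ## module tracking: first state's planted markers
  mod <- score_gene_module(norm, intersect(sim$truth$markers[[1]],
                                           rownames(norm)))
  series <- enriched_proportion_series(mod,
                                       cell_meta_col(norm, "age_pcw", "pipeline"))

  out <- structure(list(
    sim = sim, qc = qc$report, doublets = dbl$report, matrix = norm,
    hvgs = hvgs, markers = markers,
    cite = list(partition = part, assay = adt, gmm = gmm),
    transfer = list(model = model, predictions = preds,
                    cluster_labels = cluster_labels),
    da = list(neighborhoods = nh, correction = corr, result = da),
    modules = list(score = mod, series = series),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "multidrop_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_qc_report(qc$report, file.path(out_dir, "qc_cells_genes.json"))
    write_qc_report(dbl$report, file.path(out_dir, "qc_doublet_clusters.json"))
    jsonlite::write_json(list(n_bins = part$n_bins, fallback = part$fallback,
                              boundary = part$boundary,
                              n_empty = length(part$empty_idx)),
                         file.path(out_dir, "empty_droplets.json"),
                         auto_unbox = TRUE, digits = NA)
    write_background_model(gmm, file.path(out_dir, "background_model.json"))
    write_meta_tsv(preds, file.path(out_dir, "predictions.tsv"))
    write_meta_tsv(as.data.frame(da), file.path(out_dir, "neighborhoods.tsv"))
    write_meta_tsv(series, file.path(out_dir, "module_series.tsv"))
    jsonlite::write_json(list(hvgs = hvgs, cluster_labels = as.list(cluster_labels),
                              elapsed_sec = out$elapsed),
                         file.path(out_dir, "pipeline.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @exportS3Method base::print
print.multidrop_pipeline <- function(x, ...) {
  cat("multidrop_pipeline run:",
      x$qc$n_cells_in, "cells ->", ncol(x$matrix), "after QC;",
      length(x$cite$partition$empty_idx), "empty droplets; GMM k =",
      x$cite$gmm$k, ";",
      sum(x$transfer$predictions$label != "unassigned"), "/",
      nrow(x$transfer$predictions), "cells assigned;",
      sum(x$da$result$spatial_fdr < 0.1, na.rm = TRUE),
      "DA neighborhoods at spatial FDR < 0.1;",
      sprintf("%.1f s elapsed", x$elapsed), "\n")
  invisible(x)
}
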