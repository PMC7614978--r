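suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

assay_of <- function(x, layer) SummarizedExperiment::assay(x, layer)
cmeta <- function(x) as.data.frame(SummarizedExperiment::colData(x))

# Hand-built QC fixture: 250 genes, 5 cells sitting on and around the
# filter thresholds (see test-rna-qc.R for the expected fates).
make_qc_fixture <- function() {
  g <- sprintf("g%03d", 1:250)
  cells <- c("A", "B", "C", "D", "E")
  m <- matrix(0, 250, 5, dimnames = list(g, cells))
  m[1:220, "A"] <- 9; m[221, "A"] <- 19        # 1999 counts, 221 genes
  m[1:200, "B"] <- 10                          # 2000 counts, 200 genes
  m[1:250, "C"] <- 10                          # 2500 counts, 250 genes
  m[1:250, "D"] <- 10                          # good counts, bad mito
  m[1:210, "E"] <- 10                          # 2100 counts, 210 genes
  rna_experiment(m, data.frame(
    pct_mito = c(0.05, 0.20, 0.05, 0.21, 0.20),
    sample_id = "s1", lane_id = "l1"
  ))
}

# Small generated dataset shared across tests (memoized per session).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(n_cells = 2000, n_genes = 300, empty = 2000,
                       seed = 3) {
  key <- paste(n_cells, n_genes, empty, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(n_cells = n_cells, n_genes = n_genes,
                      empty_droplet_count = empty, seed = seed)
    .sim_cache[[key]] <- generate_multiomic_dataset(cfg)
  }
  .sim_cache[[key]]
}

# dsb fixture with planted background/signal populations in z-score space
make_dsb_fixture <- function(n_cells = 2000, n_prot = 6, n_groups = 2,
                             sep = 4, seed = 42) {
  set.seed(seed)
  grp <- rep_len(seq_len(n_groups), n_cells)
  x <- matrix(rnorm(n_prot * n_cells), n_prot, n_cells)
  for (g in seq_len(n_groups)[-1])
    x[, grp == g] <- x[, grp == g] + sep * (g - 1)
  dimnames(x) <- list(sprintf("P%02d", seq_len(n_prot)),
                      sprintf("c%04d", seq_len(n_cells)))
  list(dsb = x, group = grp)
}

# Wrap a dsb matrix in a protein SCE the gmm/score/regress ops accept.
wrap_dsb <- function(dsb, bg_score = NULL) {
  counts <- matrix(0L, nrow(dsb), ncol(dsb), dimnames = dimnames(dsb))
  assay <- protein_experiment(counts,
                              data.frame(total_rna_umi = rep(1000, ncol(dsb)),
                                         class = "cell"))
  SummarizedExperiment::assay(assay, "dsb") <- dsb
  if (!is.null(bg_score))
    SummarizedExperiment::colData(assay)$bg_score <- bg_score
  assay
}

# Sorted-time-series DA scenario. With constant = TRUE the composition is
# flat across age (null); biased = TRUE ramps the sorted CD45+ fraction from
# unbiased (0.8 = pi) at 3 PCW down to 0.4 at 8 PCW.
da_scenario <- function(n_cells = 8000, constant = TRUE, biased = FALSE,
                        prop = 0.1, k = 60, seed = 1) {
  props <- if (constant) matrix(0.2, 5, 5) else NULL
  ages <- c(3, 3, 4, 4, 5, 5, 7, 7, 8, 8)
  frac <- if (biased) 0.8 - 0.4 * (ages - 3) / 5 else NULL
  cfg <- sim_config(n_cells = n_cells, n_genes = 60, n_markers_per_state = 5,
                    state_proportions_by_age = props,
                    empty_droplet_count = 0, doublet_rate = 0,
                    facs_sorted_fraction = frac, sort_yield = 0.25,
                    seed = seed)
  ts <- generate_sorted_timeseries(cfg)
  tr <- ts$truth
  gate <- cfg$gate_of_state[tr$sorted_cells$state_idx]
  pseudo <- paste(tr$sorted_cells$sample_id, gate, sep = "|")
  graph <- knn_graph(tr$sorted_embedding, k = k)
  corr <- facs_correction_factors(tr$gates)
  list(
    graph = graph, truth = tr, labels = tr$sorted_cells$state,
    gate = gate,
    pseudo = pseudo, sample = tr$sorted_cells$sample_id,
    corr = corr,
    design_pseudo = data.frame(sample = corr$pseudo_sample,
                               age = corr$age_pcw),
    design_sample = data.frame(sample = tr$samples$sample_id,
                               age = tr$samples$age_pcw),
    prop = prop, seed = seed
  )
}
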