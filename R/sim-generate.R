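#' Generate a multiomic droplet dataset with known ground truth
#'
#' Draws a cell-by-gene UMI count matrix, a droplet-by-protein antibody count
#' matrix (cells plus ambient/empty droplets) and a truth object recording
#' every planted parameter. RNA counts follow per-state negative-binomial
#' profiles with `marker_logfc` natural-log enrichment of each state's marker
#' genes; doublets are averages of two random states' expected profiles at
#' doubled library size and carry high doublet-detection scores; protein
#' counts are Poisson draws from log-normal intensities, with a
#' state-specific signal component added on top of the ambient background for
#' each state's proteins; empty droplets draw protein counts from the
#' background alone and have low total RNA UMIs.
#'
#' Singlet doublet-score locations differ mildly between states (0.03-0.11),
#' as doublet detectors show in real data; doublets score around 0.8.
#'
#' @param config a [sim_config()].
#' @return A list with elements `rna` (a `SingleCellExperiment`, genes x
#'   cells), `protein` (a `SingleCellExperiment`, proteins x droplets) and
#'   `truth` (class `"synthetic_truth"`): per-cell `state`, `doublet` flag and
#'   parent states, per-droplet `empty` flag, per-state `markers`, per-protein
#'   `mu_bg_true` (log1p scale) and signal-state map, a latent `embedding`
#'   (cells x dims) and the `config`.
#' @examples
#' sim <- generate_multiomic_dataset(sim_config(n_cells = 200, n_genes = 60,
#'   n_samples = 5, empty_droplet_count = 300, seed = 7))
#' table(sim$truth$cells$state)
#' @export
generate_multiomic_dataset <- function(config) {
  validate_sim_config(config)
  cfg <- config
  K <- cfg$n_states

  samples <- sim_sample_table(cfg)

  ## ---- cell stream: sample/state assignment, doublets, embedding ----
  set.seed(stream_seed(cfg$seed, "cells"))
  sample_of_cell <- rep(seq_len(cfg$n_samples), samples$n_cells)
  state <- integer(cfg$n_cells)
  for (s in seq_len(cfg$n_samples)) {
    idx <- which(sample_of_cell == s)
    p <- cfg$state_proportions_by_age[samples$age_idx[s], ]
    state[idx] <- sample.int(K, length(idx), replace = TRUE, prob = p)
  }
  doublet <- as.logical(rbinom(cfg$n_cells, 1L, cfg$doublet_rate))
  state2 <- rep(NA_integer_, cfg$n_cells)
  if (any(doublet)) {
    for (i in which(doublet)) {
      s <- sample_of_cell[i]
      p <- cfg$state_proportions_by_age[samples$age_idx[s], ]
      state2[i] <- sample.int(K, 1L, prob = p)
    }
  }
  emb <- sim_embedding(state, state2, doublet, K)

  ## ---- gene stream: baseline abundances and marker assignment ----
  set.seed(stream_seed(cfg$seed, "genes"))
  gw <- sim_gene_weights(cfg)

  ## ---- rna stream: library sizes and NB counts ----
  set.seed(stream_seed(cfg$seed, "rna"))
  depth <- 10^rnorm(cfg$n_cells, cfg$depth_log10_mean, cfg$depth_log10_sd)
  depth[doublet] <- depth[doublet] * 2
  mu <- gw$profiles[, state, drop = FALSE]
  if (any(doublet))
    mu[, doublet] <- (gw$profiles[, state[doublet], drop = FALSE] +
                      gw$profiles[, state2[doublet], drop = FALSE]) / 2
  mu <- sweep(mu, 2L, depth, `*`)
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$gene_dispersion),
    nrow = cfg$n_genes
  )
  dimnames(counts) <- list(gw$gene_ids, sprintf("cell%05d", seq_len(cfg$n_cells)))

  ## ---- score stream: mito fractions and doublet scores ----
  set.seed(stream_seed(cfg$seed, "scores"))
  pct_mito <- rbeta(cfg$n_cells, 2, 38)
  doublet_score <- sim_doublet_scores(state, doublet, K)

  cell_meta <- data.frame(
    sample_id = samples$sample_id[sample_of_cell],
    donor_id = samples$sample_id[sample_of_cell],
    lane_id = samples$sample_id[sample_of_cell],
    age_pcw = samples$age_pcw[sample_of_cell],
    facs_gate = cfg$gate_of_state[state],
    pct_mito = pct_mito,
    doublet_score = doublet_score,
    cluster_id = ifelse(doublet, "doublet", paste0("state", state))
  )
  rna <- rna_experiment(counts, cell_meta)

  ## ---- protein stream: ambient background plus state-specific signal ----
  set.seed(stream_seed(cfg$seed, "protein"))
  prot <- sim_protein_assay(cfg, state, counts)

  truth <- structure(list(
    cells = data.frame(
      cell = colnames(counts), sample_id = cell_meta$sample_id,
      age_pcw = cell_meta$age_pcw, state = paste0("state", state),
      state_idx = state, doublet = doublet, state2_idx = state2
    ),
    droplets = data.frame(droplet = colnames(prot$assay),
                          empty = prot$empty_flag),
    markers = gw$markers,
    marker_logfc = cfg$marker_logfc,
    mu_bg_true = prot$mu_bg_true,
    protein_state = prot$protein_state,
    embedding = emb,
    samples = samples,
    config = cfg
  ), class = "synthetic_truth")

  list(rna = rna, protein = prot$assay, truth = truth)
}

#' Generate a FACS-sorted time series of samples
#'
#' Builds the full dataset with [generate_multiomic_dataset()], then passes
#' each sample's cells through a two-gate sorter: of each sample's generated
#' pool, `round(sort_yield * pool)` cells are sorted, of which a fraction
#' `facs_sorted_fraction` (default: the true gate proportion `pi`, i.e.
#' unbiased sorting) come from the first gate. Sorting at a fraction other
#' than `pi` induces a known composition bias; e.g. `pi = 0.8` sorted at
#' `Si/S = 0.4` under-represents the gate's states two-fold in expectation.
#'
#' @param config a [sim_config()].
#' @return A list with `matrices` (one `SingleCellExperiment` per sample,
#'   with `sample_id`, `age_pcw` and `facs_gate` in `colData`) and `truth`,
#'   the full-dataset truth augmented with `gates` (per sample and gate:
#'   `pi`, `Si`, `S`), `sorted_cells` (truth rows for the sorted cells, in
#'   concatenation order) and `sorted_embedding`.
#' @export
generate_sorted_timeseries <- function(config) {
  full <- generate_multiomic_dataset(config)
  cfg <- config
  gates <- unique(cfg$gate_of_state)
  if (length(gates) > 2L) stop("at most two FACS gates are supported")
  g1 <- gates[1L]

  frac <- cfg$facs_sorted_fraction
  if (!is.null(frac)) frac <- rep_len(frac, cfg$n_samples)

  truth <- full$truth
  state_idx <- truth$cells$state_idx
  in_g1 <- cfg$gate_of_state[state_idx] == g1

  set.seed(stream_seed(cfg$seed, "sort"))
  keep <- list()
  gate_rows <- list()
  for (s in seq_len(cfg$n_samples)) {
    pool <- which(truth$cells$sample_id == truth$samples$sample_id[s])
    S <- round(cfg$sort_yield * length(pool))
    p_row <- cfg$state_proportions_by_age[truth$samples$age_idx[s], ]
    pi_s <- sum(p_row[cfg$gate_of_state == g1])
    if (pi_s <= 0 || pi_s >= 1)
      stop("true gate proportion pi must lie in (0, 1); got ", pi_s)
    f_s <- if (is.null(frac)) pi_s else frac[s]
    Si <- round(f_s * S)
    pool1 <- pool[in_g1[pool]]
    pool2 <- pool[!in_g1[pool]]
    if (Si > length(pool1) || (S - Si) > length(pool2))
      stop("sorted count exceeds available gate population in sample ",
           truth$samples$sample_id[s])
    keep[[s]] <- c(sample(pool1, Si), sample(pool2, S - Si))
    gate_rows[[s]] <- data.frame(
      sample_id = truth$samples$sample_id[s],
      age_pcw = truth$samples$age_pcw[s],
      gate = c(g1, setdiff(gates, g1)),
      pi = c(pi_s, 1 - pi_s),
      Si = c(Si, S - Si),
      S = S
    )
  }

  mats <- lapply(seq_len(cfg$n_samples), function(s) full$rna[, keep[[s]]])
  names(mats) <- truth$samples$sample_id
  all_idx <- unlist(keep)
  truth$gates <- do.call(rbind, gate_rows)
  if (length(gates) == 1L) truth$gates <- truth$gates[truth$gates$gate == g1, ]
  truth$sorted_cells <- truth$cells[all_idx, ]
  truth$sorted_embedding <- truth$embedding[all_idx, , drop = FALSE]
  list(matrices = mats, truth = truth)
}

#' @exportS3Method base::print
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$cells), "cells (",
      sum(x$cells$doublet), "doublets ),",
      nrow(x$droplets), "protein droplets (",
      sum(x$droplets$empty), "empty ),",
      length(x$markers), "marker sets\n")
  invisible(x)
}

## ----------------------------- internals -----------------------------

sim_sample_table <- function(cfg) {
  n_per <- diff(round(seq(0, cfg$n_cells, length.out = cfg$n_samples + 1L)))
  age_idx <- ceiling(seq_len(cfg$n_samples) * length(cfg$age_bins) / cfg$n_samples)
  data.frame(
    sample_id = sprintf("S%02d", seq_len(cfg$n_samples)),
    age_idx = age_idx,
    age_pcw = cfg$age_bins[age_idx],
    n_cells = n_per
  )
}

# Baseline gene abundances and per-state expected profiles (columns sum to 1).
# Marker genes get a fixed baseline weight chosen so that their normalized
# expression sits in the log-linear range (about 15-40 counts per 10k), which
# makes the planted mean log-expression gap track marker_logfc closely.
sim_gene_weights <- function(cfg) {
  K <- cfg$n_states
  m <- cfg$n_markers_per_state
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  marker_idx <- if (m > 0) seq_len(m * K) else integer(0)
  w_marker <- min(0.002, 0.5 / max(1, m * K))
  w <- numeric(cfg$n_genes)
  ## mild baseline variation spreads markers across dispersion bins, as in
  ## real data where marker baselines differ
  w[marker_idx] <- w_marker * rlnorm(length(marker_idx), 0, 0.25)
  nm <- setdiff(seq_len(cfg$n_genes), marker_idx)
  u <- rlnorm(length(nm), 0, 0.7)
  w[nm] <- u / sum(u) * (1 - sum(w[marker_idx]))
  profiles <- matrix(w, cfg$n_genes, K)
  markers <- vector("list", K)
  names(markers) <- paste0("state", seq_len(K))
  for (k in seq_len(K)) {
    idx <- if (m > 0) ((k - 1L) * m + 1L):(k * m) else integer(0)
    profiles[idx, k] <- profiles[idx, k] * exp(cfg$marker_logfc)
    markers[[k]] <- gene_ids[idx]
  }
  profiles <- sweep(profiles, 2L, colSums(profiles), `/`)
  list(gene_ids = gene_ids, profiles = profiles, markers = markers)
}

# Latent coordinates: well-separated state centers plus isotropic noise;
# doublets sit midway between their parents' centers.
sim_embedding <- function(state, state2, doublet, K) {
  p <- max(2L, min(K, 8L))
  centers <- matrix(0, K, p)
  for (k in seq_len(K)) centers[k, ((k - 1L) %% p) + 1L] <- 3
  if (K > p) for (k in (p + 1L):K) centers[k, (k %% p) + 1L] <- 1.5
  emb <- centers[state, , drop = FALSE]
  if (any(doublet))
    emb[doublet, ] <- (centers[state[doublet], , drop = FALSE] +
                       centers[state2[doublet], , drop = FALSE]) / 2
  emb <- emb + matrix(rnorm(length(emb), 0, 0.6), nrow(emb))
  colnames(emb) <- paste0("dim", seq_len(p))
  emb
}

sim_doublet_scores <- function(state, doublet, K) {
  loc <- if (K == 1L) 0.07 else 0.03 + 0.08 * (state - 1) / (K - 1)
  conc <- 800
  score <- rbeta(length(state), loc * conc, (1 - loc) * conc)
  if (any(doublet)) {
    nd <- sum(doublet)
    score[doublet] <- rbeta(nd, 0.8 * 50, 0.2 * 50)
  }
  score
}

sim_protein_assay <- function(cfg, state, rna_counts) {
  P <- cfg$n_proteins
  E <- cfg$empty_droplet_count
  n_drop <- cfg$n_cells + E
  s_bg <- calibrate_log1p_intensity(cfg$protein_background_mean,
                                    cfg$protein_background_sd)
  s_sig <- calibrate_log1p_intensity(cfg$protein_signal_mean,
                                     cfg$protein_signal_sd)
  lam <- s_bg * exp(matrix(rnorm(P * n_drop, 0, cfg$protein_background_sd), P))
  counts <- matrix(rpois(length(lam), as.vector(lam)), P)
  protein_state <- ((seq_len(P) - 1L) %% max(1L, cfg$n_states)) + 1L
  if (cfg$n_cells > 0 && P > 0) {
    sig_on <- outer(protein_state, state, `==`)  # P x n_cells
    n_on <- sum(sig_on)
    if (n_on > 0) {
      sig <- rpois(n_on, s_sig * exp(rnorm(n_on, 0, cfg$protein_signal_sd)))
      cell_block <- counts[, seq_len(cfg$n_cells), drop = FALSE]
      cell_block[sig_on] <- cell_block[sig_on] + sig
      counts[, seq_len(cfg$n_cells)] <- cell_block
    }
  }
  empty_umi <- pmax(1, round(10^rnorm(E, cfg$empty_log10umi_mean,
                                      cfg$empty_log10umi_sd)))
  drop_ids <- c(colnames(rna_counts), sprintf("empty%05d", seq_len(E)))
  dimnames(counts) <- list(sprintf("P%02d", seq_len(P)), drop_ids)
  meta <- data.frame(
    barcode = drop_ids,
    total_rna_umi = c(unname(colSums(rna_counts)), empty_umi)
  )
  assay <- protein_experiment(counts, meta)
  list(assay = assay,
       empty_flag = c(rep(FALSE, cfg$n_cells), rep(TRUE, E)),
       mu_bg_true = setNames(rep(cfg$protein_background_mean, P),
                             rownames(counts)),
       protein_state = setNames(paste0("state", protein_state),
                                rownames(counts)))
}

# E[log1p(X)] for X ~ Pois(lambda): exact truncated sum for moderate lambda,
# second-order delta beyond.
expected_log1p_pois <- function(lambda) {
  vapply(lambda, function(l) {
    if (l <= 0) return(0)
    if (l > 400) return(log1p(l) - l / (2 * (1 + l)^2))
    kmax <- max(20, ceiling(l + 10 * sqrt(l) + 10))
    k <- 0:kmax
    sum(dpois(k, l) * log1p(k))
  }, numeric(1))
}

# Intensity scale s such that E[log1p(Pois(s * exp(sdlog * Z)))] = target for
# Z ~ N(0,1); keeps the configured background/signal means exact on the
# log1p-count scale that DSB consumes.
calibrate_log1p_intensity <- function(target_mean, sdlog) {
  z <- seq(-5, 5, length.out = 61)
  w <- dnorm(z); w <- w / sum(w)
  f <- function(ls) sum(w * expected_log1p_pois(exp(ls + sdlog * z))) - target_mean
  exp(uniroot(f, c(-12, 15), tol = 1e-10)$root)
}
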