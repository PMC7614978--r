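#' Simulation configuration for multiomic droplet datasets
#'
#' Collects every parameter of the ground-truth generator. The defaults
#' describe the study conditions exercised throughout the test-suite: five
#' cell states sampled across five gestational age bins (3, 4, 5, 7 and 8
#' post-conception weeks), with the first state tripling in proportion from
#' the earliest to the latest bin (0.10 to 0.30) and the second state doing
#' the reverse, natural-log marker enrichment of 1.0, a 5% doublet rate,
#' 5,000 ambient (empty) droplets, and CD45+/CD45- sorting gates in which the
#' CD45+ gate holds a true proportion pi = 0.8 of cells.
#'
#' @param n_cells total number of cells (across all samples).
#' @param n_genes number of genes.
#' @param n_proteins number of surface proteins (ADTs).
#' @param n_states number of cell states.
#' @param n_samples number of biological samples; samples are spread evenly
#'   over `age_bins`.
#' @param age_bins gestational ages, in post-conception weeks.
#' @param state_proportions_by_age matrix (length(age_bins) x n_states) of
#'   simplex rows; `NULL` uses the default ramp described above.
#' @param marker_logfc natural-log fold enrichment of a state's marker genes
#'   within that state.
#' @param n_markers_per_state marker genes planted per state.
#' @param doublet_rate fraction of cell-containing droplets that are
#'   doublets, in `[0, 1)`.
#' @param empty_droplet_count number of ambient droplets in the protein
#'   assay.
#' @param protein_background_mean,protein_background_sd location/spread of
#'   the ambient antibody background on the log1p-count scale; intensities
#'   are calibrated so the mean of `log1p(counts)` over empty droplets equals
#'   `protein_background_mean` in expectation.
#' @param protein_signal_mean,protein_signal_sd same, for the state-specific
#'   antibody signal component.
#' @param gene_dispersion negative-binomial dispersion (1/size) shared by all
#'   genes.
#' @param depth_log10_mean,depth_log10_sd per-cell library size is
#'   `10^N(depth_log10_mean, depth_log10_sd)` UMIs.
#' @param empty_log10umi_mean,empty_log10umi_sd empty droplets' total RNA
#'   UMIs are `10^N(mean, sd)`.
#' @param gate_of_state FACS gate of each state; default puts every state but
#'   the last in `"CD45+"`.
#' @param facs_sorted_fraction per-sample sorted fraction Si/S of the first
#'   gate; `NULL` sorts without bias (Si/S = pi). Recycled to `n_samples`.
#' @param sort_yield fraction of a sample's generated cells that pass the
#'   sorter in [generate_sorted_timeseries()]; the rest form the finite pool
#'   from which gates are drawn.
#' @param seed master seed; one derived stream per matrix kind (cells, genes,
#'   RNA counts, proteins, sorting) so that, e.g., adding proteins does not
#'   perturb the RNA draws.
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [generate_multiomic_dataset()], [generate_sorted_timeseries()]
#' @export
sim_config <- function(n_cells = 3000,
                       n_genes = 500,
                       n_proteins = 10,
                       n_states = 5,
                       n_samples = 10,
                       age_bins = c(3, 4, 5, 7, 8),
                       state_proportions_by_age = NULL,
                       marker_logfc = 1.0,
                       n_markers_per_state = 20,
                       doublet_rate = 0.05,
                       empty_droplet_count = 5000,
                       protein_background_mean = 2.0,
                       protein_background_sd = 0.5,
                       protein_signal_mean = 4.0,
                       protein_signal_sd = 0.5,
                       gene_dispersion = 0.3,
                       depth_log10_mean = 3.6,
                       depth_log10_sd = 0.15,
                       empty_log10umi_mean = 2.0,
                       empty_log10umi_sd = 0.15,
                       gate_of_state = NULL,
                       facs_sorted_fraction = NULL,
                       sort_yield = 0.5,
                       seed = 1L) {
  if (is.null(state_proportions_by_age))
    state_proportions_by_age <- default_state_proportions(length(age_bins), n_states)
  if (is.null(gate_of_state))
    gate_of_state <- c(rep("CD45+", n_states - 1L), "CD45-")
  cfg <- structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_proteins = as.integer(n_proteins), n_states = as.integer(n_states),
    n_samples = as.integer(n_samples), age_bins = as.numeric(age_bins),
    state_proportions_by_age = as.matrix(state_proportions_by_age),
    marker_logfc = marker_logfc,
    n_markers_per_state = as.integer(n_markers_per_state),
    doublet_rate = doublet_rate,
    empty_droplet_count = as.integer(empty_droplet_count),
    protein_background_mean = protein_background_mean,
    protein_background_sd = protein_background_sd,
    protein_signal_mean = protein_signal_mean,
    protein_signal_sd = protein_signal_sd,
    gene_dispersion = gene_dispersion,
    depth_log10_mean = depth_log10_mean, depth_log10_sd = depth_log10_sd,
    empty_log10umi_mean = empty_log10umi_mean,
    empty_log10umi_sd = empty_log10umi_sd,
    gate_of_state = gate_of_state,
    facs_sorted_fraction = facs_sorted_fraction,
    sort_yield = sort_yield,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# Default temporal composition: state 1 ramps p0 -> 3*p0 across the bins,
# state 2 does the reverse; remaining states share the remainder equally.
default_state_proportions <- function(n_bins, n_states) {
  if (n_states == 1L) return(matrix(1, n_bins, 1L))
  p0 <- 0.1
  ramp <- seq(p0, 3 * p0, length.out = n_bins)
  if (n_states == 2L) return(cbind(ramp, 1 - ramp))
  rest <- (1 - ramp - rev(ramp)) / (n_states - 2L)
  cbind(ramp, rev(ramp), matrix(rest, n_bins, n_states - 2L))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    counts <- c(n_cells, n_genes, n_proteins, n_states, n_samples,
                n_markers_per_state, empty_droplet_count)
    if (any(counts < 0)) stop("all counts must be nonnegative")
    if (doublet_rate < 0 || doublet_rate >= 1)
      stop("doublet_rate must lie in [0, 1)")
    if (nrow(state_proportions_by_age) != length(age_bins) ||
        ncol(state_proportions_by_age) != n_states)
      stop("state_proportions_by_age must be length(age_bins) x n_states")
    if (any(state_proportions_by_age < 0) ||
        any(abs(rowSums(state_proportions_by_age) - 1) > 1e-9))
      stop("each state_proportions_by_age row must be a simplex (sum 1 within 1e-9)")
    if (length(gate_of_state) != n_states)
      stop("gate_of_state must have one entry per state")
    if (!is.null(facs_sorted_fraction) &&
        any(facs_sorted_fraction <= 0 | facs_sorted_fraction >= 1))
      stop("facs_sorted_fraction values must lie in (0, 1)")
    if (n_markers_per_state * n_states > n_genes)
      stop("marker genes exceed n_genes")
  })
  invisible(cfg)
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells,", x$n_genes, "genes,",
      x$n_proteins, "proteins,", x$n_states, "states,",
      x$n_samples, "samples over ages",
      paste(x$age_bins, collapse = "/"), "PCW; seed", x$seed, "\n")
  invisible(x)
}

# Derived per-stream seeds (kept below 2^31): independent streams for cell
# assignment, gene weights, RNA counts, protein counts, and sorting.
stream_seed <- function(seed, stream) {
  offs <- c(cells = 11L, genes = 23L, rna = 37L, protein = 53L, sort = 71L,
            scores = 89L)
  (as.integer(seed) %% 20000000L) * 100L + offs[[stream]]
}
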