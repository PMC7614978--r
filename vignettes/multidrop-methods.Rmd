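---
title: "Methods and design of the multidrop pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the multidrop pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multidrop)
```

`multidrop` packages, as tested and reusable functions, the bespoke
computational procedures used in droplet-based multiomic studies of early
human hematopoiesis: quality control of cell-by-gene UMI matrices, two-step
background correction of CITE-seq antibody (ADT) counts, probabilistic
elastic-net label transfer, differential cell-state abundance across
gestational age with a correction for FACS sorting bias, and gene-module
enrichment tracking. Every stage is exercised end-to-end on synthetic
droplet data with known ground truth; this vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where the procedure left genuine latitude.

## The synthetic-data generator

The generator (`sim_config()`, `generate_multiomic_dataset()`,
`generate_sorted_timeseries()`) is first-class, tested code: it defines the
study conditions under which every downstream claim is verified.

**RNA counts.** Cells belong to one of `n_states` cell states whose mixing
proportions vary across five gestational age bins (3, 4, 5, 7 and 8
post-conception weeks, two samples per bin by default). Counts are negative
binomial with a shared dispersion of 0.3 — the standard emulation of UMI
data — around per-state expected profiles. Each state carries
`n_markers_per_state` marker genes whose expected expression is multiplied
by `exp(marker_logfc)` in that state (default natural-log fold change 1.0).
Marker baselines are mildly varied (log-normal, sd 0.25) around a level
of roughly 15–40 counts per 10k: in that range `log1p` is effectively
linear, so the planted mean log-expression gap tracks `marker_logfc`
closely, and the variation spreads markers across expression bins as in
real data. Library sizes are log-normal (`10^N(3.6, 0.15)` UMIs).

**Temporal composition.** By default state 1 triples in proportion from the
earliest to the latest age bin (0.10 to 0.30) and state 2 does the reverse;
the remaining states are flat. Both ramping states sit in the CD45+ gate,
so the gate's total proportion `pi = 0.8` stays constant across age — the
composition shift and the sorting-gate structure are orthogonal by design.

**Doublets.** A fraction `doublet_rate` (default 5%) of cell barcodes are
doublets: the average of two random states' expected profiles at doubled
library size. Their doublet-detection scores are drawn around 0.8 and they
are assigned to their own cluster, emulating the co-clustering of doublets
that the cluster-level removal rule assumes. Singlet score locations differ
mildly between states (0.03–0.11, beta-distributed with concentration 800):
doublet detectors show exactly this cell-type dependence in real data, and
it is what makes the median + 1.48·MAD rule meaningful — between-cluster
spread dominates within-cluster sampling noise. With perfectly identical
singlet score distributions the rule would fire on pure noise.

**Protein counts.** Antibody counts are Poisson draws from log-normal
intensities: every droplet receives an ambient background component, and a
cell additionally receives a signal component for the (two, by default)
proteins assigned to its state. The background intensity scale is
*calibrated* (Gaussian quadrature over the log-normal mixing distribution
plus exact Poisson sums, solved by root finding) so that the mean of
`log1p(counts)` over empty droplets equals `protein_background_mean`
exactly in expectation. Without this calibration the Jensen bias of the
Poisson/log1p chain (~0.07 at the default scale) would make the configured
background level systematically wrong on the scale the DSB step consumes.

**Empty droplets and sorting.** `empty_droplet_count` ambient droplets
(default 5,000) carry background-only protein counts and low total RNA
UMIs (`10^N(2.0, 0.15)`). `generate_sorted_timeseries()` passes each
sample's cells through a two-gate sorter: `round(sort_yield * pool)` cells
are sorted, a fraction `Si/S` of them from the CD45+ gate. The default is
unbiased (`Si/S = pi`); setting `facs_sorted_fraction` below `pi`
under-represents the gate by a known factor, which is the planted bias the
differential-abundance correction must undo.

**What the generator does not emulate:** ambient RNA contamination,
read-level data, batch effects between lanes, maternal genotype mixtures,
or continuous differentiation trajectories (states are discrete). Passing
tests therefore demonstrate correctness of the procedures under these
idealized conditions, not robustness to every artifact of real droplet
data.

**Determinism.** One RNG stream per matrix kind (cell assignment, gene
weights, RNA counts, doublet/mito scores, protein counts, sorting) is
derived from the master seed, so changing the number of proteins does not
perturb the RNA draws, and the same configuration always yields
byte-identical output.

## RNA quality control

`filter_cells_and_genes()` removes cells with fewer than 2,000 total UMIs,
fewer than 200 detected genes, or more than 20% mitochondrial reads, then
genes expressed in fewer than 3 remaining cells. All inequalities are
strict (a cell with exactly 2,000 UMIs survives), "reads" is interpreted as
total UMI counts (the matrices are UMI counts), and the order is fixed —
cells first, then genes, no iteration.

`remove_doublet_clusters()` applies, per sequencing lane, the rule:
compute each cluster's median doublet score; remove clusters whose median
strictly exceeds `median + 1.48 × MAD` of the lane's cluster medians. The
MAD is the *raw* median absolute deviation, without the 1.4826 normal
consistency factor, because the 1.48 multiplier is written explicitly into
the threshold. The rule is shift-equivariant (adding a constant to all
scores changes nothing). A lane with a single cluster is never touched and
is flagged in the report — removing the only cluster would empty the lane,
and a relative outlier rule is meaningless with one observation. Clustering
itself (Leiden on a KNN graph in the source workflows) is consumed as input
labels, not computed.

`normalize_lognorm()` scales each cell to 10,000 counts and applies
`log(1+x)`. `select_hvgs()` ranks genes by binned normalized dispersion in
the droplet-field convention: mean and dispersion (variance/mean) of the
un-logged normalized expression, then `log1p(mean)` and `log(dispersion)`;
20 equal-frequency mean bins (a bin count the procedure leaves open);
z-scored dispersion within bins; eligibility bounds `(0.001, 10)` applied
to the `log1p` mean metric, on which those published bounds are defined.

`rank_marker_genes()` runs one-vs-rest two-sided Wilcoxon rank-sum tests on
log-normalized expression for genes expressed in more than 25% of the
group's cells, Benjamini–Hochberg adjusts within each group's tested
genes, and reports genes at `|log2FC| ≥ 0.25` (fold change of expm1 means
with a 1e-9 pseudocount, the droplet convention). `partition_metrics()`
returns AMI (hypergeometric expected-MI model, arithmetic normalization —
implemented here, validated against a frozen reference value), ARI,
mean silhouette width and within-cluster SSE; `partition_sweep()` evaluates
them across candidate partitions, e.g. from graphs built at k = 5..50.

## CITE-seq background correction

**Empty-droplet discovery.** `detect_empty_droplets()` histograms
log10(total RNA UMIs) over `round(3.322·log10(X))` bins — the Sturges-type
rule with `3.322 ≈ 1/log10(2)`, read as log base 10 since a natural-log
reading would give implausibly few bins — and detects peaks with
topographic prominences and widths over a sweep of minimum-prominence
(0–20) × minimum-width (0–10) settings. The tallest peak is taken as the
ambient peak when it lies below the mean log10 UMI. A stricter published
variant — requiring the peak below `mean − 1.96·sd` — is degenerate: the
mode of a distribution essentially cannot sit 1.96 standard deviations
below its own mean (for the bimodal benchmark here, the ambient peak sits
0.75 sd below the mean), so that clause is retained only as the *fallback
threshold*: when no peak qualifies (a unimodal cells-only lane, or a
degenerate histogram), droplets below `mean − 1.96·sd` are classed empty
and the partition is flagged. The empty boundary is the histogram valley
between the ambient peak and the tallest peak to its right — the natural
"everything under the ambient mode" cut; a half-width boundary would
truncate ~12% of a Gaussian ambient mode. With no peak to the right,
peak + FWHM/2 is used.

**DSB z-scoring.** `dsb_normalize()` z-scores `log1p` antibody counts per
protein against the empty-droplet distribution (subtract ambient mean,
divide by ambient sd; sd floored at 1e-8 with a warning for degenerate
proteins). Isotype-control denoising — the second step of classical DSB —
is out of scope; the background regression below plays its role here.

**Mixture background model.** `fit_background_gmm()` fits
diagonal-covariance Gaussian mixtures over cells in protein space for
k = 2..21 and computes both criteria in the conventional minimized
orientation, `BIC = −2L + df·log n` and `AIC = −2L + 2·df` (published
variants that print `+2L` are sign typos under any consistent reading).
BIC decides when the two disagree — it is consistency-preferring — and the
AIC choice is recorded. Model fitting is delegated to `mclust` (model
`"VVI"`), whose model-based hierarchical initialization is deterministic;
that determinism replaces the seeded multi-restart convention of other
toolkits. Whether the mixture should be multivariate over cells or
univariate per protein is genuinely ambiguous in the source workflows; the
multivariate reading ("cell clusters") is the default and a univariate
variant is available via `method = "univariate"`. The per-protein
background mean `mu_bg` is the smallest component mean for that protein.
Note that forcing k ≥ 2 on a unimodal population splits it, displacing the
lowest component mean by up to ~0.8 sd — the background estimate for
signal-free proteins is accurate to that order, not exactly the global
mean.

**Background scores and regression.** `compute_bg_scores()` computes, per
cell, the mean over proteins of `exp(mu_bg − x)` (the ratio of
e^background to e^expression; the mean is one of several reasonable
aggregations of the per-protein ratios — the median is available), min-max
scaled over cells to [0, 1]. The scaling is `(r − min)/(max − min)`;
dividing by the unshifted maximum could not reach 1 and contradicts the
intended 0–1 range. `regress_background()` then fits, per protein, an
ordinary Gaussian linear model of the dsb value on the background score
and stores intercept + residuals as the corrected layer: the
background-associated component is removed, the protein's location is
preserved, and by least-squares orthogonality the corrected values have
exactly zero sample covariance with the score.

## Probabilistic elastic-net label transfer

`train_transfer_model()` fits a multinomial elastic-net logistic
regression. The tuning grid is 6 mixing values (l1_ratio 0, 0.2, 0.4, 0.6,
0.8, 1 — the published list of six values is authoritative over its
"five intervals" caption, and both pure ridge and pure lasso are legal
ends) × 5 alpha values (0.2..1). Alpha is an *inverse* regularization
strength, honored literally: it maps to the glmnet penalty as
`lambda = 1/(alpha·n)`, so larger alpha is a weaker penalty. Five
stratified train/test splits are repeated three times with fold seeds
advancing deterministically (0, 1, 2). Each held-out fold is scored by the
mean squared error between one-hot labels and predicted *probabilities*
(an unusual criterion for a classifier, but the stated one; probabilities
rather than hard labels are used because the workflow is explicitly
probabilistic), class-frequency-weighted within the fold; the grid point
minimizing the unweighted mean of the 15 fold scores is refit on all data.
Features are not standardized, matching the convention of the Python
implementation this mirrors; caller-supplied low-dimensional
representations (PCs, VAE latents) can be passed directly as a matrix.

`predict_cells()` assigns the argmax class when its softmax probability
reaches the decision threshold of 0.9, else `"unassigned"`; raising the
threshold can only increase the unassigned fraction.
`assign_cluster_labels()` votes cluster labels: counts per projected label
(over the label set observed anywhere in the predictions, so absent labels
count as zero), and the modal label must strictly exceed
`mean + 1·std` of the counts, with the *population* standard deviation
(the sample/population choice is unstated in the source; population is
used and documented). Ties (e.g. 30/30) give `std = 0` and an unresolvable
threshold; near-ties (34/33/33) resolve to the modal label — a documented
sensitivity of the rule.

`feature_impact()` reports `impact = e^coefficient` per feature and class,
with significance from the survival function of a normal distribution
fitted to the class's coefficients (the named sf distribution is not
stated; a normal over log-impacts is the parsimonious choice, and an
empirical rank-based sf is available). This calibration flags the upper
tail of the coefficient distribution, so it presumes many non-informative
features; models intended for impact analysis should be trained on the
full gene set rather than a marker-dominated selection.

## Neighborhood differential abundance with FACS correction

`build_neighborhoods()` samples `round(prop·n)` index cells (prop = 0.05)
and forms one neighborhood per index cell from its KNN-graph neighbors,
tabulating per-sample counts; `label_neighborhoods()` assigns a label on a
strict >50% majority, else `"Mixed"`. The KNN graph is an input
(`knn_graph()` is a convenience brute-force builder over caller-supplied
coordinates; embedding computation is upstream). No refinement or merging
of neighborhoods is performed.

**The sorting correction.** For sample *s* sorted with gate *i*, the
correction factor is `fs = log(pi·S/Si)` with `pi` the gate's true cell
proportion, `Si` the sorted count from the gate, `S` the sample's total
sorted cells; `fs = 0` under unbiased sorting. Each sorted fraction enters
the model as its own (sample, gate) pseudo-sample — the natural unit when
a sample contributes both gates — with exposure offset
`log(S) − fs = log(Si/pi)`: this converts the fraction's within-gate cell
shares back to whole-tissue abundances, and is the only sign convention
under which unbiased sorting reduces exactly to the uncorrected
`log(total cells)` offset and the null simulation is calibrated. Columns
of gates absent from a neighborhood's member cells are structural zeros
and are dropped from that neighborhood's model. Note that a sorting bias
*shared by all samples* is absorbed by the intercept and inflates nothing;
the bias that matters — and the one the paired simulation plants — is
age-correlated sorting (here, a CD45+ sorted fraction ramping from
unbiased at 3 PCW to two-fold under-representation at 8 PCW), which a
naive per-sample analysis converts into spurious "abundance changes".

**Testing.** Counts are modeled per neighborhood as a negative-binomial
GLM on age, treated as a continuous covariate in weeks over the five bins
(a single slope delivers the signed per-neighborhood fold change the
workflow reports). A single common NB dispersion is estimated by the
method of moments on Poisson residuals pooled across neighborhoods — the
minimal faithful choice given that the cited framework's quasi-likelihood
machinery is out of scope — followed by a two-sided Wald test of the age
coefficient (LRT available via `test = "lrt"`). Multiplicity is controlled
by the spatial FDR: weighted Benjamini–Hochberg with weights equal to the
reciprocal k-distance of each neighborhood's index cell, one weighting
scheme applied once; with equal weights it reduces exactly to classical
BH.

## Gene-module enrichment tracking

`score_gene_module()` scores cells as mean module-gene expression minus
mean expression of up to 200 control genes sampled (seeded, without
replacement) from each module gene's bin among 50 equal-frequency bins of
mean expression; "200 reference genes at 50 bins" is read as 200 controls
per module gene's bin, the convention of the scoring function this
mirrors. Module genes are excluded from the control pool to avoid
self-deflation (degenerate bins fall back to the module genes themselves,
contributing zero). The score is invariant to adding a constant to all
genes and deterministic under a fixed seed. A cell is *enriched* when its
score is strictly positive.

`enriched_proportion_series()` computes, per age bin, the proportion of
eligible cells enriched; for single-gene tracking (e.g. embryonic vs fetal
globin switching) eligibility is `log-normalized expression > 0` for that
gene, so temporal changes in background expression and population size do
not masquerade as enrichment changes. The published display rule hiding
points with fewer than 500 enriched cells is presentational; it is exposed
as a `below_min_count` flag, never as a data filter.
`robust_standardize()` centers by the median and scales by the raw MAD,
erroring (not silently dividing by zero) when more than half the values
are identical.

## Problem sizes and numerical choices

The test-suite exercises the stages at sizes chosen to make every
statistical claim decidable while keeping a full run on a single CPU in
minutes: 100-seed doublet-cluster recovery at 400 cells per dataset;
DSB/empty-droplet checks at 5,000 ambient plus 3,000 cell droplets;
mixture recovery at 2,000 cells over k = 2..21; label transfer at 3,000
cells × 500 genes with the full 6 × 5 × 15 CV grid; the paired
sorting-bias simulation at 500 neighborhoods over 10,000 sorted cells; and
module tracking at 1,000 cells per age bin. Tolerances follow the
quantity's sampling error (binomial 3·SE bands for rates), machine
precision for algebraic identities (offset equivalence, BH equality,
shift invariance), and parameter-recovery bands of ±0.15 normalized units
for mixture means.

Degenerate inputs are handled explicitly rather than silently: zero-total
cells error in normalization; zero ambient variance floors the sd with a
warning; constant background scores skip the regression with a warning;
single-cluster lanes are never purged; all-identical raw background scores
yield zeros with a warning; a MAD of zero is an error naming the
degenerate input.

## Known limitations

The NB-GLM uses one common dispersion and Wald tests; with very small
per-column counts it runs slightly conservative, which the calibration
checks quantify but do not hide. The generator's states are discrete and
noise-free in the embedding sense, so neighborhood purity is higher than
in real data; majority-label voting on real graphs will produce more
`"Mixed"` neighborhoods. The elastic-net CV scores probabilities with MSE,
which is insensitive to calibration errors far from the decision boundary.
AMI is exact but O(R·C) in the expected-MI sum, which is fine for tens of
clusters but slow for thousands. The univariate GMM variant selects k per
protein independently and can be slow for large panels.
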