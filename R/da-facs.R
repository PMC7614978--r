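#' FACS isolation correction factors
#'
#' For each sample s sorted with gate i, the correction factor is
#' `fs = log(pi * S / Si)` (natural log), where `pi` is the true proportion
#' of cells in gate i, `Si` the number of cells sorted from that gate, and
#' `S` the sample's total sorted cells. Unbiased sorting (`Si/S = pi`) gives
#' `fs = 0`; under-sorting a gate gives `fs > 0`. The factor enters
#' [test_differential_abundance()] as part of the exposure offset
#' `log(S) - fs = log(Si / pi)` of the (sample, gate) pseudo-sample, which
#' converts the sorted fraction's within-gate cell shares back to
#' whole-tissue abundances.
#'
#' @param gates `data.frame` with columns `sample_id`, `gate`, `pi`, `Si`,
#'   `S` (one row per sample-gate), e.g. `truth$gates` from
#'   [generate_sorted_timeseries()].
#' @return A `"facs_correction"`: the input with `fs` and a `pseudo_sample`
#'   id column (`sample_id|gate`) used to match count-matrix columns.
#' @examples
#' facs_correction_factors(data.frame(sample_id = "S1", gate = "CD45+",
#'   pi = 0.8, Si = 400, S = 1000))$fs  # log(800/400) = log 2
#' @export
facs_correction_factors <- function(gates) {
  need <- c("sample_id", "gate", "pi", "Si", "S")
  if (!all(need %in% names(gates)))
    stop("gates needs columns: ", paste(need, collapse = ", "))
  if (any(gates$pi <= 0 | gates$pi >= 1)) stop("pi must lie in (0, 1)")
  if (any(gates$Si <= 0)) stop("Si must be positive")
  gates$fs <- log(gates$pi * gates$S / gates$Si)
  gates$pseudo_sample <- paste(gates$sample_id, gates$gate, sep = "|")
  structure(gates, class = c("facs_correction", "data.frame"))
}
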