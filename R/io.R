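#' Write a multiomic dataset as Matrix Market plus TSV metadata
#'
#' Writes `rna.mtx` / `cells.tsv` / `genes.tsv`, and when present
#' `protein.mtx` / `droplets.tsv` / `proteins.tsv` and `truth.json`, into
#' `dir`. Matrices are stored genes (proteins) x cells (droplets) in sparse
#' triplet format.
#'
#' @param sim list with `rna` (required), `protein`, `truth` -- e.g. the
#'   output of [generate_multiomic_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multiomic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rna <- sim$rna
  Matrix::writeMM(SummarizedExperiment::assay(rna, "counts"),
                  file.path(dir, "rna.mtx"))
  write_meta_tsv(data.frame(cell = colnames(rna),
                            as.data.frame(SummarizedExperiment::colData(rna))),
                 file.path(dir, "cells.tsv"))
  write_meta_tsv(data.frame(gene = rownames(rna),
                            as.data.frame(SummarizedExperiment::rowData(rna))),
                 file.path(dir, "genes.tsv"))
  if (!is.null(sim$protein)) {
    prot <- sim$protein
    Matrix::writeMM(SummarizedExperiment::assay(prot, "counts"),
                    file.path(dir, "protein.mtx"))
    write_meta_tsv(data.frame(droplet = colnames(prot),
                              as.data.frame(SummarizedExperiment::colData(prot))),
                   file.path(dir, "droplets.tsv"))
    write_meta_tsv(data.frame(protein = rownames(prot)),
                   file.path(dir, "proteins.tsv"))
  }
  if (!is.null(sim$truth)) {
    tr <- unclass(sim$truth)
    tr$config <- unclass(tr$config)
    tr$embedding <- NULL  # large; regenerate from config/seed instead
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE, dataframe = "columns")
  }
  invisible(dir)
}

#' Read a multiomic dataset written by [write_multiomic_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `rna`, and `protein`/`truth` when present (`truth` as a
#'   plain list).
#' @export
read_multiomic_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "rna.mtx")),
                        "CsparseMatrix")
  cells <- utils::read.delim(file.path(dir, "cells.tsv"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  dimnames(counts) <- list(genes$gene, cells$cell)
  out <- list(rna = rna_experiment(counts, cells[, -1, drop = FALSE],
                                   genes[, -1, drop = FALSE]))
  if (file.exists(file.path(dir, "protein.mtx"))) {
    pc <- methods::as(Matrix::readMM(file.path(dir, "protein.mtx")),
                      "CsparseMatrix")
    drops <- utils::read.delim(file.path(dir, "droplets.tsv"))
    prots <- utils::read.delim(file.path(dir, "proteins.tsv"))
    dimnames(pc) <- list(prots$protein, drops$droplet)
    out$protein <- protein_experiment(pc, drops[, -1, drop = FALSE])
  }
  if (file.exists(file.path(dir, "truth.json")))
    out$truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                     simplifyVector = TRUE)
  out
}

write_meta_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
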