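#' Write a cohort to disk (MTX + TSV + JSON)
#'
#' One MatrixMarket coordinate file per slice (1-based, integer) with
#' \code{barcodes.tsv} and \code{features.tsv}, a
#' \code{cohort_metadata.csv} (slice, patient, treatment), the gene
#' annotation TSV and the ground truth as JSON.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$slices)) {
    sdir <- file.path(dir, s)
    dir.create(sdir, showWarnings = FALSE)
    m <- .counts(cohort$slices[[s]])
    Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                    file.path(sdir, "matrix.mtx"))
    writeLines(colnames(m), file.path(sdir, "barcodes.tsv"))
    writeLines(rownames(m), file.path(sdir, "features.tsv"))
  }
  md <- unique(cohort$truth$cells[, c("slice", "patient", "treatment")])
  utils::write.csv(md, file.path(dir, "cohort_metadata.csv"),
                   row.names = FALSE)
  writeGeneAnnotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

#' Read one slice written by \code{\link{writeCohort}}
#' @param sdir slice directory containing matrix.mtx, barcodes.tsv,
#'   features.tsv.
#' @return sparse genes x cells count matrix.
#' @export
readSliceCounts <- function(sdir) {
  m <- Matrix::readMM(file.path(sdir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(sdir, "features.tsv")),
                      readLines(file.path(sdir, "barcodes.tsv")))
  methods::as(m, "CsparseMatrix")
}
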