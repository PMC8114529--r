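#' Per-cell factor signature scores
#'
#' The score of a cell for a factor signature is the mean counts-per-10,000
#' over the signature's genes (typically the factor's top 100 genes).
#'
#' @param x genes x cells counts or SingleCellExperiment.
#' @param signatures named list of gene vectors (see
#'   \code{\link{factorSignatures}}).
#' @param cell_metadata data.frame/DataFrame with rownames matching cells and
#'   columns \code{slice}, \code{patient}, \code{treatment},
#'   \code{cell_type}; taken from the colData when \code{x} is a
#'   SingleCellExperiment and this is NULL.
#' @return long data.frame: cell, slice, patient, treatment, cell_type,
#'   factor, score (one row per cell x factor).
#' @export
signatureScores <- function(x, signatures, cell_metadata = NULL) {
  m <- .counts(x)
  if (is.null(cell_metadata) && is(x, "SummarizedExperiment"))
    cell_metadata <- as.data.frame(SummarizedExperiment::colData(x))
  norm <- cp10k(m)
  out <- lapply(names(signatures), function(f) {
    genes <- intersect(signatures[[f]], rownames(norm))
    if (!length(genes))
      stop("signature '", f, "' shares no genes with the matrix")
    if (length(genes) < length(signatures[[f]]))
      message("signature '", f, "': ",
              length(signatures[[f]]) - length(genes), " gene(s) missing")
    data.frame(cell = colnames(norm),
               factor = f,
               score = Matrix::colMeans(norm[genes, , drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(cell_metadata)) {
    cm <- as.data.frame(cell_metadata)[out$cell, , drop = FALSE]
    for (col in intersect(c("slice", "patient", "treatment", "cell_type"),
                          names(cm)))
      out[[col]] <- cm[[col]]
  }
  out
}

#' Treated-vs-vehicle fold-change matrices of signature scores
#'
#' For each treated slice, the log2 ratio of the mean signature score in the
#' treated slice to that in each vehicle slice (columns), restricted to one
#' cell type, with a pseudocount \code{eps} on the per-10k scale. Slices
#' with fewer than \code{n_min} cells of the type are flagged missing (NA).
#'
#' @param scores long table from \code{\link{signatureScores}}.
#' @param cell_type cell type to restrict to.
#' @param treated_slices,vehicle_slices slice identifiers; defaults: every
#'   non-vehicle slice, every vehicle slice.
#' @param eps pseudocount (default 1).
#' @param n_min minimum cells of the type per slice (default 20).
#' @return named list (per treated slice) of factors x vehicle-slice
#'   matrices.
#' @export
treatmentFoldChange <- function(scores, cell_type,
                                treated_slices = NULL, vehicle_slices = NULL,
                                eps = 1, n_min = 20L) {
  sc <- scores[scores$cell_type == cell_type, , drop = FALSE]
  if (is.null(vehicle_slices))
    vehicle_slices <- unique(sc$slice[sc$treatment == "vehicle"])
  if (is.null(treated_slices))
    treated_slices <- unique(sc$slice[sc$treatment != "vehicle"])
  if (!length(treated_slices) || !length(vehicle_slices))
    stop("need at least one treated and one vehicle slice")
  factors <- unique(sc$factor)
  sliceMean <- function(s, f) {
    v <- sc$score[sc$slice == s & sc$factor == f]
    if (length(v) < n_min) NA_real_ else mean(v)
  }
  out <- lapply(treated_slices, function(ts) {
    mat <- matrix(NA_real_, length(factors), length(vehicle_slices),
                  dimnames = list(factors, vehicle_slices))
    for (f in factors) {
      mt <- sliceMean(ts, f)
      for (vs in vehicle_slices)
        mat[f, vs] <- log2((mt + eps) / (sliceMean(vs, f) + eps))
    }
    mat
  })
  names(out) <- treated_slices
  out
}
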