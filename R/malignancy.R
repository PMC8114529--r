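#' Per-cell mean normalized expression on one chromosome
#'
#' Average of counts-per-10,000 values over the genes annotated to the given
#' chromosome, one value per cell.
#'
#' @param x genes x cells count matrix or SingleCellExperiment.
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param chromosome chromosome name (e.g. \code{"7"}).
#' @return named numeric, one mean per cell.
#' @export
chromosomeMeanExpression <- function(x, annotation, chromosome) {
  m <- .counts(x)
  genes <- intersect(genesOnChromosome(annotation, chromosome), rownames(m))
  if (length(genes) == 0)
    stop("no genes annotated to chromosome ", chromosome)
  norm <- cp10k(m)
  stats::setNames(Matrix::colMeans(norm[genes, , drop = FALSE]), colnames(m))
}

#' Per-cell malignancy score
#'
#' The log2 ratio of mean chromosome 7 to mean chromosome 10 normalized
#' expression: \code{log2((mean7 + eps) / (mean10 + eps))} with a pseudocount
#' \code{eps} on the per-10k scale. Transformed glioblastoma cells, which gain
#' chromosome 7 and lose chromosome 10, score high.
#'
#' @inheritParams chromosomeMeanExpression
#' @param eps pseudocount on the per-10k scale (default 1).
#' @return named numeric of finite per-cell scores.
#' @export
malignancyScore <- function(x, annotation, eps = 1) {
  m7 <- chromosomeMeanExpression(x, annotation, "7")
  m10 <- chromosomeMeanExpression(x, annotation, "10")
  log2((m7 + eps) / (m10 + eps))
}

#' Classify cells as malignant or non-tumor from malignancy scores
#'
#' Fits (or accepts) a two-component Gaussian mixture to the score
#' distribution and sets the classification threshold 1.96 standard deviations
#' below the mean of the higher-mean component. Putative tumor cells scoring
#' strictly below the threshold and putative non-tumor cells scoring at or
#' above it are discarded as misclassified or potential multiplets; all other
#' cells keep their putative identity.
#'
#' @param scores named per-cell malignancy scores.
#' @param putative named character, per-cell putative identity, values
#'   \code{"tumor"} or \code{"nontumor"} (other values treated as nontumor).
#' @param mixture optional pre-fitted mixture from
#'   \code{\link{fitDoubleGaussian}}.
#' @return a \linkS4class{MalignancyModel}.
#' @export
classifyMalignancy <- function(scores, putative, mixture = NULL) {
  if (is.null(names(scores))) stop("scores must be named by cell")
  if (is.null(mixture)) mixture <- fitDoubleGaussian(scores)
  missing <- setdiff(names(scores), names(putative))
  if (length(missing)) stop("putative identities missing for some cells")
  putative <- putative[names(scores)]
  tau <- mixture$muHi - 1.96 * mixture$sdHi
  isTumor <- putative == "tumor"
  labels <- ifelse(isTumor, "malignant", "nontumor")
  labels[isTumor & scores < tau] <- "discarded"
  labels[!isTumor & scores >= tau] <- "discarded"
  new("MalignancyModel", scores = scores,
      weight = mixture$weightHi,
      muLo = mixture$muLo, muHi = mixture$muHi,
      sdLo = mixture$sdLo, sdHi = mixture$sdHi,
      threshold = tau,
      labels = stats::setNames(labels, names(scores)))
}

#' @rdname MalignancyModel
#' @export
setMethod("malignancyThreshold", "MalignancyModel",
          function(object) object@threshold)

#' @rdname MalignancyModel
#' @export
setMethod("malignancyLabels", "MalignancyModel",
          function(object) object@labels)

setMethod("show", "MalignancyModel", function(object) {
  cat("MalignancyModel over", length(object@scores), "cells\n")
  cat(sprintf("  mixture: muLo=%.3f (sd %.3f), muHi=%.3f (sd %.3f), wHi=%.2f\n",
              object@muLo, object@sdLo, object@muHi, object@sdHi,
              object@weight))
  cat(sprintf("  threshold (muHi - 1.96 sdHi): %.3f\n", object@threshold))
  print(table(object@labels))
})
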