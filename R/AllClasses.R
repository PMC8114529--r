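#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

#' Gene annotation with chromosome map and named gene panels
#'
#' Maps each gene to a chromosome and carries named gene panels (mitochondrial,
#' housekeeping/ribosomal, stress, metallothionein, proliferation, per-lineage
#' markers, four-state signatures) used throughout the workflow.
#'
#' @slot genes character vector of gene identifiers.
#' @slot chromosome character vector parallel to \code{genes}; chromosome name
#'   for each gene (autosomes \code{"1"}..\code{"22"}, optionally
#'   \code{"X"}, \code{"Y"}, \code{"MT"}).
#' @slot panels named list of character vectors; each panel is a subset of
#'   \code{genes}.
#'
#' @export
setClass("GeneAnnotation",
  representation(genes = "character", chromosome = "character",
                 panels = "list"),
  prototype(genes = character(), chromosome = character(), panels = list())
)

setValidity("GeneAnnotation", function(object) {
  msg <- NULL
  if (length(object@genes) != length(object@chromosome))
    msg <- c(msg, "'genes' and 'chromosome' must have equal length")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene identifiers must be unique")
  if (length(object@panels)) {
    if (is.null(names(object@panels)) || any(!nzchar(names(object@panels))))
      msg <- c(msg, "all panels must be named")
    stray <- unlist(object@panels, use.names = FALSE)
    if (!all(stray %in% object@genes))
      msg <- c(msg, "panels contain genes absent from the annotation")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-cell malignancy classification from Chr7/Chr10 expression
#'
#' Holds the per-cell malignancy scores (log2 ratio of mean chromosome 7 to
#' chromosome 10 expression), the fitted two-component Gaussian mixture, the
#' derived classification threshold and the final per-cell labels.
#'
#' @slot scores named numeric; per-cell malignancy score.
#' @slot weight numeric(1); mixture weight of the high-mean component.
#' @slot muLo,muHi numeric(1); component means, \code{muHi >= muLo}.
#' @slot sdLo,sdHi numeric(1); component standard deviations, positive.
#' @slot threshold numeric(1); \code{muHi - 1.96 * sdHi}.
#' @slot labels named character; one of \code{"malignant"}, \code{"nontumor"},
#'   \code{"discarded"} per cell.
#'
#' @export
setClass("MalignancyModel",
  representation(scores = "numeric", weight = "numeric",
                 muLo = "numeric", muHi = "numeric",
                 sdLo = "numeric", sdHi = "numeric",
                 threshold = "numeric", labels = "character")
)

setValidity("MalignancyModel", function(object) {
  msg <- NULL
  if (length(object@muHi) == 1 && length(object@muLo) == 1 &&
      object@muHi < object@muLo)
    msg <- c(msg, "muHi must be >= muLo")
  if (any(c(object@sdLo, object@sdHi) <= 0))
    msg <- c(msg, "component standard deviations must be positive")
  if (length(object@threshold) == 1 &&
      abs(object@threshold - (object@muHi - 1.96 * object@sdHi)) > 1e-12)
    msg <- c(msg, "threshold must equal muHi - 1.96 * sdHi")
  if (length(object@labels) &&
      !all(object@labels %in% c("malignant", "nontumor", "discarded")))
    msg <- c(msg, "labels must be malignant/nontumor/discarded")
  if (length(object@labels) != length(object@scores))
    msg <- c(msg, "one label per scored cell required")
  if (is.null(msg)) TRUE else msg
})

#' Hierarchical Poisson factorization model
#'
#' Variational posterior expectations for a K-factor Gamma-Poisson hierarchy
#' fitted to a UMI count matrix: cell weights \eqn{\Theta} (cells x K, elements
#' \eqn{E[\theta_{i,k}|x]}), gene weights \eqn{B} (genes x K, elements
#' \eqn{E[\beta_{g,k}|x]}), cell budgets \eqn{\xi_i} and gene budgets
#' \eqn{\eta_g}. The full variational shape/rate parameters are retained so
#' held-out cells can be projected against fixed gene-side distributions.
#'
#' @slot K integer(1); number of factors.
#' @slot theta,beta numeric matrices (cells x K, genes x K) of posterior means.
#' @slot thetaShape,thetaRate,betaShape,betaRate variational Gamma parameters.
#' @slot xiShape,xiRate,etaShape,etaRate variational Gamma parameters of the
#'   budgets (vectors over cells / genes).
#' @slot hyper named list of hyperparameters (a, c, aPrime, cPrime, bPrime,
#'   dPrime).
#' @slot geneIds,cellIds identifiers of the genes / cells used in the fit.
#' @slot elbo numeric; evidence lower bound trace, one value per epoch.
#' @slot nuisance logical(K); factors flagged as technical (depth / stress).
#'
#' @export
setClass("FactorModel",
  representation(K = "integer",
                 theta = "matrix", beta = "matrix",
                 thetaShape = "matrix", thetaRate = "matrix",
                 betaShape = "matrix", betaRate = "matrix",
                 xiShape = "numeric", xiRate = "numeric",
                 etaShape = "numeric", etaRate = "numeric",
                 hyper = "list",
                 geneIds = "character", cellIds = "character",
                 elbo = "numeric", nuisance = "logical")
)

setValidity("FactorModel", function(object) {
  msg <- NULL
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (ncol(object@theta) != object@K || ncol(object@beta) != object@K)
    msg <- c(msg, "theta/beta must have K columns")
  if (any(object@theta <= 0) || any(object@beta <= 0))
    msg <- c(msg, "all factor expectations must be strictly positive")
  if (length(object@nuisance) != object@K)
    msg <- c(msg, "one nuisance flag per factor required")
  if (nrow(object@beta) != length(object@geneIds))
    msg <- c(msg, "beta rows must match geneIds")
  if (is.null(msg)) TRUE else msg
})
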