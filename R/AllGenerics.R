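#' @rdname GeneAnnotation
#' @param object a \code{GeneAnnotation}, \code{MalignancyModel} or
#'   \code{FactorModel}.
#' @export
setGeneric("genePanel", function(object, name) standardGeneric("genePanel"))

#' @rdname GeneAnnotation
#' @export
setGeneric("chromosomeOf", function(object, genes) standardGeneric("chromosomeOf"))

#' @rdname MalignancyModel
#' @export
setGeneric("malignancyThreshold",
           function(object) standardGeneric("malignancyThreshold"))

#' @rdname MalignancyModel
#' @export
setGeneric("malignancyLabels",
           function(object) standardGeneric("malignancyLabels"))

#' @rdname FactorModel
#' @export
setGeneric("nFactors", function(object) standardGeneric("nFactors"))

#' @rdname FactorModel
#' @export
setGeneric("cellScores", function(object, ...) standardGeneric("cellScores"))

#' @rdname FactorModel
#' @export
setGeneric("geneScores", function(object, ...) standardGeneric("geneScores"))

#' @rdname FactorModel
#' @export
setGeneric("nuisanceFactors",
           function(object) standardGeneric("nuisanceFactors"))

#' @rdname FactorModel
#' @export
setGeneric("factorSignatures",
           function(object, ...) standardGeneric("factorSignatures"))
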