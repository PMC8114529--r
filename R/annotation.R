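#' Construct a GeneAnnotation
#'
#' @param genes character vector of gene identifiers.
#' @param chromosome chromosome per gene. If \code{NULL}, genes are assigned
#'   round-robin to the 22 autosomes, which keeps per-chromosome gene counts
#'   balanced (in particular on chromosomes 7 and 10).
#' @param panels named list of gene panels (subsets of \code{genes}).
#'
#' @return a \linkS4class{GeneAnnotation}.
#' @examples
#' ann <- GeneAnnotation(paste0("g", 1:44))
#' table(chromosomeOf(ann, paste0("g", 1:44)))
#' @export
GeneAnnotation <- function(genes, chromosome = NULL, panels = list()) {
  genes <- as.character(genes)
  if (is.null(chromosome)) {
    chromosome <- as.character(rep_len(1:22, length(genes)))
  } else {
    chromosome <- as.character(chromosome)
    if (!is.null(names(chromosome))) chromosome <- chromosome[genes]
  }
  new("GeneAnnotation", genes = genes, chromosome = chromosome,
      panels = panels)
}

#' Read a two-column gene-to-chromosome TSV
#'
#' Expects columns \code{gene_id} and \code{chromosome} (header optional).
#'
#' @param path file path.
#' @param panels optional named list of gene panels.
#' @return a \linkS4class{GeneAnnotation}.
#' @export
readGeneAnnotation <- function(path, panels = list()) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (identical(tolower(tab[1, 1]), "gene_id")) tab <- tab[-1, , drop = FALSE]
  GeneAnnotation(tab[[1]], chromosome = as.character(tab[[2]]),
                 panels = panels)
}

#' Write a GeneAnnotation chromosome map to TSV
#' @param object a \linkS4class{GeneAnnotation}.
#' @param path output file path.
#' @export
writeGeneAnnotation <- function(object, path) {
  utils::write.table(
    data.frame(gene_id = object@genes, chromosome = object@chromosome),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname GeneAnnotation
#' @param name panel name.
#' @export
setMethod("genePanel", "GeneAnnotation", function(object, name) {
  if (!name %in% names(object@panels))
    stop("no panel named '", name, "'")
  object@panels[[name]]
})

#' @rdname GeneAnnotation
#' @param genes gene identifiers to look up.
#' @export
setMethod("chromosomeOf", "GeneAnnotation", function(object, genes) {
  idx <- match(genes, object@genes)
  if (anyNA(idx)) stop("genes absent from annotation: ",
                       paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
  stats::setNames(object@chromosome[idx], genes)
})

#' List panel names of a GeneAnnotation
#' @param object a \linkS4class{GeneAnnotation}.
#' @export
panelNames <- function(object) names(object@panels)

#' Genes on a given chromosome
#' @param object a \linkS4class{GeneAnnotation}.
#' @param chromosome chromosome name.
#' @export
genesOnChromosome <- function(object, chromosome) {
  object@genes[object@chromosome == as.character(chromosome)]
}

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation with", length(object@genes), "genes on",
      length(unique(object@chromosome)), "chromosomes\n")
  if (length(object@panels))
    cat("panels:", paste0(names(object@panels), " (",
        lengths(object@panels), ")", collapse = ", "), "\n")
})
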