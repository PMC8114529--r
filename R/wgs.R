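#' Estimate average chromosome copy number from WGS read counts
#'
#' For each chromosome, the tumor share of de-duplicated reads is divided by
#' the germline share (both normalized by total reads), the resulting ratio is
#' normalized by its median across chromosomes and multiplied by two. By
#' construction the median copy number across the supplied chromosomes is
#' exactly 2.
#'
#' @param tumor named numeric, per-chromosome de-duplicated tumor read counts,
#'   or a data.frame with columns \code{chromosome}, \code{tumor},
#'   \code{germline} (as produced by \code{\link{simulateWgsCounts}}).
#' @param germline named numeric, germline counts over the same chromosomes
#'   (ignored when \code{tumor} is a data.frame).
#' @param autosomes_only drop X/Y before computing ratios (default TRUE).
#' @return data.frame: chromosome, tumor, germline, ratio, copy_number.
#' @examples
#' estimateCopyNumber(c("1" = 100, "7" = 200, "10" = 100),
#'                    c("1" = 100, "7" = 100, "10" = 100))
#' @export
estimateCopyNumber <- function(tumor, germline = NULL, autosomes_only = TRUE) {
  if (is.data.frame(tumor)) {
    tab <- tumor
    stopifnot(all(c("chromosome", "tumor", "germline") %in% names(tab)))
  } else {
    chroms <- names(tumor)
    if (is.null(chroms) || is.null(names(germline)))
      stop("counts must be named by chromosome")
    if (!setequal(chroms, names(germline)))
      stop("tumor and germline must cover the same chromosome set")
    tab <- data.frame(chromosome = chroms, tumor = as.numeric(tumor),
                      germline = as.numeric(germline[chroms]),
                      stringsAsFactors = FALSE)
  }
  if (autosomes_only)
    tab <- tab[!tab$chromosome %in% c("X", "Y", "MT"), , drop = FALSE]
  if (any(tab$germline <= 0))
    stop("zero germline count on chromosome ",
         paste(tab$chromosome[tab$germline <= 0], collapse = ", "))
  ratio <- (tab$tumor / sum(tab$tumor)) / (tab$germline / sum(tab$germline))
  tab$ratio <- ratio
  tab$copy_number <- 2 * ratio / stats::median(ratio)
  tab
}

#' Read a two-column chromosome read-count TSV
#' @param path file with columns chromosome, dedup_read_count.
#' @return named numeric vector.
#' @export
readChromCounts <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}
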