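#' Gaussian-mixture intensity threshold for probe positivity
#'
#' Fits a two-component Gaussian mixture to the mean nuclear intensities of
#' all masks with area strictly greater than 6 square microns and returns a
#' threshold two standard deviations above the mean of the lowest-intensity
#' mode (the fluorescence background).
#'
#' @param nuclei data.frame with at least \code{area_um2} and
#'   \code{mean_intensity} (see \code{\link{simulateNucleusTable}}).
#' @param min_area area cutoff in um^2; masks with area \code{<= min_area}
#'   are excluded (strict inequality retained).
#' @param min_nuclei minimum qualifying nuclei required for a stable fit.
#' @return list: threshold, mixture (the \code{\link{fitDoubleGaussian}} fit),
#'   n_used.
#' @export
gmmIntensityThreshold <- function(nuclei, min_area = 6, min_nuclei = 50L) {
  keep <- nuclei$area_um2 > min_area
  x <- nuclei$mean_intensity[keep]
  if (length(x) < min_nuclei)
    stop("fewer than ", min_nuclei, " nuclei pass the area filter")
  fit <- fitDoubleGaussian(x)
  list(threshold = fit$muLo + 2 * fit$sdLo, mixture = fit,
       n_used = length(x))
}

#' Call probe-positive nuclei against an intensity threshold
#'
#' A nucleus is positive iff its mean intensity is strictly greater than the
#' threshold. Per-condition positive fractions are reported with Wilson 95%
#' confidence intervals.
#'
#' @param nuclei data.frame with \code{mean_intensity} and \code{condition}.
#' @param threshold intensity threshold (from
#'   \code{\link{gmmIntensityThreshold}}).
#' @return list: \code{calls} (nuclei with a \code{positive} column) and
#'   \code{fractions} (per condition: n, n_positive, fraction, ci_lower,
#'   ci_upper).
#' @export
callPositive <- function(nuclei, threshold) {
  if (!nrow(nuclei)) stop("empty nucleus table")
  nuclei$positive <- nuclei$mean_intensity > threshold
  bycond <- split(nuclei$positive, nuclei$condition)
  fractions <- do.call(rbind, lapply(names(bycond), function(cn) {
    pos <- bycond[[cn]]
    ci <- .wilsonCI(sum(pos), length(pos))
    data.frame(condition = cn, n = length(pos), n_positive = sum(pos),
               fraction = mean(pos), ci_lower = ci[["lower"]],
               ci_upper = ci[["upper"]], stringsAsFactors = FALSE)
  }))
  list(calls = nuclei, fractions = fractions)
}
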