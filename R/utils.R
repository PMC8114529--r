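#' @importFrom Matrix colSums rowSums rowMeans colMeans t sparseMatrix Diagonal
#' @importFrom BiocGenerics cbind rbind
NULL

# counts matrix extraction: accepts SingleCellExperiment / SummarizedExperiment
# or any matrix-like (genes x cells)
.counts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, "counts"))
  x
}

#' Counts-per-10,000 normalization
#'
#' Scales each cell (column) so that its counts sum to 10,000. This is the
#' normalization used for chromosome-average expression, malignancy scores and
#' factor signature scores.
#'
#' @param x genes x cells count matrix (dense, sparse, or a
#'   SingleCellExperiment carrying a \code{counts} assay).
#' @return matrix of the same shape on the per-10k scale.
#' @export
cp10k <- function(x) {
  m <- .counts(x)
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) stop("cells with zero total counts cannot be normalized")
  out <- m %*% Matrix::Diagonal(x = 10000 / tot)
  dimnames(out) <- dimnames(m)
  out
}

# deterministic child seeds below 2^31, derived from one master seed
.childSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h + 1)
}

# run expr under a local RNG state with the given seed
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# population standard deviation (divide by n), as used for the QC cutoffs
.popSD <- function(x) sqrt(mean((x - mean(x))^2))

# Wilson 95% score interval for a binomial proportion
.wilsonCI <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}
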