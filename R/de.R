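## Depth-matched, rank-based differential expression: condition subsampling,
## binomial depth matching, pooled-deconvolution normalization, a vectorised
## two-sided Mann-Whitney U test with tie and continuity corrections (exact
## enumeration tail for small untied samples), and Benjamini-Hochberg
## correction.

# two-sided MWU p for two numeric vectors; exact (pwilcox) when both
# samples are small and untied, tie-corrected normal approximation with
# continuity correction otherwise
.mwu2 <- function(a, b, exact_max = 8L) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && min(n1, n2) <= exact_max) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 1 - stats::pwilcox(u - 1, n1, n2))
    return(list(U = u, p = min(1, p), exact = TRUE))
  }
  N <- n1 + n2
  tt <- table(r)
  tcorr <- sum(tt^3 - tt)
  sdu <- sqrt(n1 * n2 / 12 * ((N + 1) - tcorr / (N * (N - 1))))
  mu <- n1 * n2 / 2
  z <- (abs(u - mu) - 0.5) / sdu
  p <- if (sdu == 0) 1 else 2 * stats::pnorm(-max(z, 0))
  list(U = u, p = min(1, p), exact = FALSE)
}

#' Two-sided rank-sum comparison of signature scores
#'
#' Exact enumeration (via the null Mann-Whitney distribution) when the
#' smaller sample has at most 8 observations and there are no ties;
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param treated,vehicle numeric score vectors (at least 3 cells each for a
#'   meaningful comparison).
#' @return list: U, p, exact.
#' @examples
#' compareSignature(c(1, 2, 3), c(4, 5, 6))$p   # 0.1
#' @export
compareSignature <- function(treated, vehicle) {
  if (!length(treated) || !length(vehicle)) stop("empty group")
  .mwu2(treated, vehicle)
}

#' Equalize cell numbers and mean depth between two conditions
#'
#' The condition with more cells is randomly subsampled to the size of the
#' smaller one; the condition with the greater mean molecules per cell is
#' then binomially downsampled per cell so both conditions share the same
#' average depth (relative difference below 0.5\%). Counts never increase.
#'
#' @param a,b genes x cells count matrices (or SingleCellExperiments).
#' @param seed integer seed.
#' @return list with matched matrices \code{a} and \code{b}.
#' @export
depthMatchSubsample <- function(a, b, seed = 1L) {
  ma <- .counts(a); mb <- .counts(b)
  if (sum(ma) == 0 || sum(mb) == 0)
    stop("a condition with zero total molecules cannot be matched")
  .withSeed(.childSeed(seed, "depthmatch"), {
    n <- min(ncol(ma), ncol(mb))
    if (ncol(ma) > n) ma <- ma[, sort(sample.int(ncol(ma), n)), drop = FALSE]
    if (ncol(mb) > n) mb <- mb[, sort(sample.int(ncol(mb), n)), drop = FALSE]
    da <- mean(Matrix::colSums(ma)); db <- mean(Matrix::colSums(mb))
    thin <- function(m, p) {
      sp <- methods::as(m, "CsparseMatrix")
      sp@x <- as.numeric(stats::rbinom(length(sp@x), sp@x, p))
      Matrix::drop0(sp)
    }
    if (da > db) ma <- thin(ma, db / da)
    else if (db > da) mb <- thin(mb, da / db)
    list(a = ma, b = mb)
  })
}

#' Pooled-deconvolution size-factor normalization
#'
#' Per-cell size factors by pooled deconvolution (sums over random cell
#' pools, solved for per-cell factors), rescaled to mean 1; normalized
#' values are counts divided by the cell's factor.
#'
#' @param x genes x cells counts (at least 20 cells).
#' @param pool_sizes pool sizes handed to the deconvolution.
#' @return list: \code{normalized} matrix, \code{size_factors} (mean 1),
#'   \code{dropped} (cells with zero counts, removed with a warning).
#' @export
normalizeCounts <- function(x, pool_sizes = c(21, 41, 61)) {
  m <- .counts(x)
  if (ncol(m) < 20) stop("need at least 20 cells to estimate size factors")
  tot <- Matrix::colSums(m)
  dropped <- colnames(m)[tot == 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-count cell(s) dropped")
    m <- m[, tot > 0, drop = FALSE]
  }
  sizes <- unique(pmin(pool_sizes, ncol(m) - 1))
  sf <- scran::calculateSumFactors(m, sizes = sizes, min.mean = 0)
  sf <- sf / mean(sf)
  nrm <- m %*% Matrix::Diagonal(x = 1 / sf)
  dimnames(nrm) <- dimnames(m)
  list(normalized = nrm,
       size_factors = stats::setNames(sf, colnames(m)),
       dropped = dropped)
}

#' Rank-based differential expression between two matched conditions
#'
#' Per-gene two-sided Mann-Whitney U tests on normalized values from
#' depth-matched matrices, with Benjamini-Hochberg correction across the
#' tested genes. Genes are restricted to a protein-coding list when
#' supplied.
#'
#' @param a,b genes x cells normalized matrices (conditions A and B),
#'   matched via \code{\link{depthMatchSubsample}} and
#'   \code{\link{normalizeCounts}}.
#' @param protein_coding optional admissible gene list.
#' @param eps pseudocount for the fold-change ratio (default 1).
#' @return data.frame: gene, mean_a, mean_b, log2fc, U, p, q.
#' @export
differentialExpression <- function(a, b, protein_coding = NULL, eps = 1) {
  ma <- as.matrix(.counts(a)); mb <- as.matrix(.counts(b))
  if (ncol(ma) < 3 || ncol(mb) < 3) stop("need at least 3 cells per group")
  genes <- intersect(rownames(ma), rownames(mb))
  if (!is.null(protein_coding)) genes <- intersect(genes, protein_coding)
  ma <- ma[genes, , drop = FALSE]; mb <- mb[genes, , drop = FALSE]
  n1 <- ncol(ma); n2 <- ncol(mb); N <- n1 + n2
  comb <- cbind(ma, mb)
  U <- numeric(length(genes)); p <- numeric(length(genes))
  for (gi in seq_along(genes)) {
    r <- rank(comb[gi, ])
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tt <- tabulate(match(r, unique(r)))
    tcorr <- sum(tt^3 - tt)
    sdu <- sqrt(n1 * n2 / 12 * ((N + 1) - tcorr / (N * (N - 1))))
    z <- if (sdu == 0) 0 else (abs(u - n1 * n2 / 2) - 0.5) / sdu
    U[gi] <- u
    p[gi] <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  data.frame(gene = genes,
             mean_a = rowMeans(ma), mean_b = rowMeans(mb),
             log2fc = log2((rowMeans(ma) + eps) / (rowMeans(mb) + eps)),
             U = U, p = p, q = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
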