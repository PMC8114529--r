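#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent 1)
#' of each gene set against a ranked gene list, with a gene-label
#' permutation null: the normalized enrichment score (NES) divides the
#' observed ES by the mean |ES| of the same-sign permutations, the
#' permutation p-value counts same-sign permutations at least as extreme,
#' and q is Benjamini-Hochberg across the gene sets tested.
#'
#' @param ranking named numeric ranking metric (e.g.
#'   \code{sign(log2fc) * -log10(p)}), one value per gene.
#' @param gene_sets named list of gene vectors; sets sharing fewer than
#'   \code{min_size} genes with the ranking are skipped with a message.
#' @param n_perm gene-label permutations (default 1000).
#' @param min_size minimum overlap (default 5).
#' @param seed integer seed.
#' @return data.frame: gene_set, size, ES, NES, p, q.
#' @examples
#' r <- stats::setNames(seq(3, -3, length.out = 100), paste0("g", 1:100))
#' gseaPreranked(r, list(top = paste0("g", 1:10)), n_perm = 200)
#' @export
gseaPreranked <- function(ranking, gene_sets, n_perm = 1000L,
                          min_size = 5L, seed = 1L) {
  ord <- order(ranking, decreasing = TRUE)
  r <- ranking[ord]
  genes <- names(r)
  N <- length(r)
  w <- abs(r)

  # ES from the sorted hit positions (weighted KS running sum)
  esFromPos <- function(pos) {
    pos <- sort(pos)
    s <- length(pos)
    wp <- w[pos]
    W <- sum(wp)
    if (W == 0) wp <- rep(1 / s, s) else wp <- wp / W
    hit <- cumsum(wp)
    missAfter <- (pos - seq_len(s)) / (N - s)
    devUp <- hit - missAfter                       # just after each hit
    devDown <- c(0, hit[-s]) - (pos - 1 - (seq_len(s) - 1)) / (N - s)
    hi <- max(devUp); lo <- min(devDown)
    if (hi >= -lo) hi else lo
  }

  rows <- lapply(names(gene_sets), function(gs) {
    hits <- which(genes %in% gene_sets[[gs]])
    if (length(hits) < min_size) {
      message("gene set '", gs, "' has fewer than ", min_size,
              " genes in the ranking; skipped")
      return(NULL)
    }
    es <- esFromPos(hits)
    perm <- .withSeed(.childSeed(seed, "gsea", gs), {
      vapply(seq_len(n_perm), function(i)
        esFromPos(sample.int(N, length(hits))), numeric(1))
    })
    same <- perm[sign(perm) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- if (length(same)) (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
         else 1 / (1 + n_perm)
    data.frame(gene_set = gs, size = length(hits), ES = es, NES = nes,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set passed the minimum-overlap filter")
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Default GSEA ranking metric from a DE table
#'
#' \code{sign(log2fc) * -log10(p)}, with zero p-values clamped to the
#' smallest nonzero p observed.
#'
#' @param de data.frame from \code{\link{differentialExpression}}.
#' @return named numeric ranking.
#' @export
gseaRanking <- function(de) {
  p <- de$p
  p[p == 0] <- min(p[p > 0], .Machine$double.xmin)
  stats::setNames(sign(de$log2fc) * -log10(p), de$gene)
}
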