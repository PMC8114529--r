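## Unsupervised clustering on marker genes, cluster identity assignment,
## multiplet-cluster flagging, factor-score clustering/classification, and
## the four-state projection of transformed cells.

# dropout-deviation marker selection for one sample: genes whose dropout
# rate exceeds the trend expected from their mean expression
.dropoutMarkers <- function(m, n_markers = 200L, min_cells = 10L) {
  det <- Matrix::rowSums(m > 0)
  ok <- det >= min_cells
  mu <- Matrix::rowMeans(m)[ok]
  fdrop <- 1 - det[ok] / ncol(m)
  lmu <- log10(mu + 1e-8)
  fit <- stats::loess(fdrop ~ lmu, span = 0.5, degree = 1)
  resid <- fdrop - stats::predict(fit)
  names(sort(resid, decreasing = TRUE))[seq_len(min(n_markers, sum(ok)))]
}

# k-nearest-neighbor graph under Pearson correlation distance on the rows
# of `mat`; constant rows fall back to Euclidean distance with a message
.pearsonKnn <- function(mat, k) {
  n <- nrow(mat)
  if (k >= n) stop("k must be smaller than the number of cells")
  sds <- apply(mat, 1, stats::sd)
  flat <- sds == 0
  z <- mat
  z[!flat, ] <- (mat[!flat, , drop = FALSE] - rowMeans(mat)[!flat]) /
    (sds[!flat] * sqrt(ncol(mat) - 1))
  sim <- tcrossprod(z)                 # Pearson r between non-flat rows
  if (any(flat)) {
    message(sum(flat), " constant-score cell(s): Euclidean fallback")
    d <- as.matrix(stats::dist(mat))
    sim[flat, ] <- -d[flat, , drop = FALSE]
    sim[, flat] <- -d[, flat, drop = FALSE]
  }
  diag(sim) <- -Inf
  idx <- t(apply(sim, 1, function(r) order(r, decreasing = TRUE)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(idx)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

# Louvain labels from a kNN graph, deterministic for a fixed graph
.louvain <- function(g) {
  cl <- igraph::cluster_louvain(g)
  igraph::membership(cl)
}

#' Cluster cells on marker genes and assign putative identities
#'
#' Markers are selected per sample by a dropout-deviation criterion and
#' unioned; cells are clustered by Louvain community detection on a
#' k-nearest-neighbor graph (Pearson correlation over log-normalized marker
#' expression); each cluster is assigned the lineage whose marker panel has
#' the highest rank-sum enrichment in that cluster.
#'
#' @param x genes x cells counts or SingleCellExperiment; when the colData
#'   has a \code{slice} column markers are selected per slice.
#' @param annotation \linkS4class{GeneAnnotation} whose \code{markers_*}
#'   panels define the candidate identities.
#' @param k neighbors for the kNN graph (default 20).
#' @param n_markers markers per sample.
#' @param seed seed (marker union is deterministic; kept for interface
#'   stability).
#' @return list: \code{clusters} (named integer per cell),
#'   \code{identities} (per cluster), \code{cell_identity} (named character),
#'   \code{enrichment} (cluster x panel z-scores), \code{markers}.
#' @export
clusterAndType <- function(x, annotation, k = 20L, n_markers = 200L,
                           seed = 1L) {
  m <- .counts(x)
  if (2L * k > ncol(m)) stop("need at least 2k cells")
  groups <- if (is(x, "SummarizedExperiment") &&
                "slice" %in% names(SummarizedExperiment::colData(x)))
    split(seq_len(ncol(m)), SummarizedExperiment::colData(x)$slice)
  else list(all = seq_len(ncol(m)))
  markers <- sort(unique(unlist(lapply(groups, function(idx)
    .dropoutMarkers(m[, idx, drop = FALSE], n_markers)))))
  expr <- log2(as.matrix(cp10k(m)[markers, , drop = FALSE]) + 1)
  g <- .pearsonKnn(t(expr), k)
  clusters <- stats::setNames(as.integer(.louvain(g)), colnames(m))

  panels <- panelNames(annotation)
  panels <- panels[startsWith(panels, "markers_")]
  if (!length(panels)) stop("annotation has no markers_* panels")
  norm <- cp10k(m)
  panelScore <- vapply(panels, function(p) {
    genes <- intersect(genePanel(annotation, p), rownames(norm))
    if (!length(genes)) return(rep(NA_real_, ncol(norm)))
    Matrix::colMeans(norm[genes, , drop = FALSE])
  }, numeric(ncol(m)))
  if (all(is.na(panelScore))) stop("no marker panel matches any gene")
  ids <- sort(unique(clusters))
  enr <- matrix(NA_real_, length(ids), length(panels),
                dimnames = list(ids, sub("^markers_", "", panels)))
  for (ci in seq_along(ids)) {
    inC <- clusters == ids[ci]
    for (pi in seq_along(panels)) {
      sc <- panelScore[, pi]
      if (all(is.na(sc))) next
      r <- rank(sc)
      n1 <- sum(inC); n2 <- sum(!inC)
      u <- sum(r[inC]) - n1 * (n1 + 1) / 2
      enr[ci, pi] <- (u - n1 * n2 / 2) /
        sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    }
  }
  identities <- stats::setNames(colnames(enr)[apply(enr, 1, which.max)],
                                ids)
  list(clusters = clusters, identities = identities,
       cell_identity = stats::setNames(
         unname(identities[as.character(clusters)]), names(clusters)),
       enrichment = enr, markers = markers)
}

#' Flag clusters enriched in multiple disjoint lineage panels
#'
#' A cluster is flagged as a putative multiplet population iff at least two
#' disjoint lineage panels are each significantly enriched in it (one-sided
#' rank-sum on per-cell panel scores, Benjamini-Hochberg q below
#' \code{fdr}). Each panel's enrichment is tested against all other cells
#' excluding the panel's home cluster (the cluster with the highest mean
#' panel score, unless that is the tested cluster itself): a doublet
#' population scores below the pure lineage it contains, so including the
#' pure cluster in the background would mask exactly the clusters this
#' filter exists to catch.
#'
#' @param x genes x cells counts or SingleCellExperiment.
#' @param clusters named cluster labels.
#' @param panels named list of disjoint lineage gene panels.
#' @param fdr significance level on BH-adjusted q (default 0.05).
#' @return list: \code{flagged} (cluster names), \code{q} (cluster x panel
#'   matrix of adjusted p-values).
#' @export
flagMultipletClusters <- function(x, clusters, panels, fdr = 0.05) {
  if (length(panels) < 2) stop("need at least 2 lineage panels")
  all <- unlist(panels)
  if (anyDuplicated(all)) stop("lineage panels must be disjoint")
  m <- .counts(x)
  norm <- cp10k(m)
  clusters <- clusters[colnames(m)]
  ids <- sort(unique(clusters))
  p <- matrix(NA_real_, length(ids), length(panels),
              dimnames = list(as.character(ids), names(panels)))
  for (pn in names(panels)) {
    genes <- intersect(panels[[pn]], rownames(norm))
    if (!length(genes)) next
    sc <- Matrix::colMeans(norm[genes, , drop = FALSE])
    home <- names(which.max(tapply(sc, clusters, mean)))
    for (ci in as.character(ids)) {
      inC <- clusters == ci
      bg <- !inC & (ci == home | clusters != home)
      p[ci, pn] <- stats::wilcox.test(sc[inC], sc[bg],
                                      alternative = "greater")$p.value
    }
  }
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
              dimnames = dimnames(p))
  nSig <- rowSums(q < fdr, na.rm = TRUE)
  list(flagged = rownames(q)[nSig >= 2], q = q)
}

#' Cluster cells on factor scores
#'
#' Louvain community detection on a k-nearest-neighbor graph built from the
#' Pearson correlation matrix of the cell score (theta) rows.
#'
#' @param theta cells x K factor score matrix with rownames.
#' @param k neighbors (default 50).
#' @return named integer cluster labels.
#' @export
clusterCellScores <- function(theta, k = 50L) {
  g <- .pearsonKnn(theta, k)
  stats::setNames(as.integer(.louvain(g)), rownames(theta))
}

#' Classify projected cells by majority vote of nearest trained cells
#'
#' @param theta_new projected cells x K scores (rownames required).
#' @param theta_train trained cells x K scores.
#' @param labels_train named labels of the trained cells.
#' @param k neighbors (default 50).
#' @return named labels for the new cells.
#' @export
classifyProjected <- function(theta_new, theta_train, labels_train,
                              k = 50L) {
  if (k > nrow(theta_train)) stop("k exceeds the number of trained cells")
  labels_train <- labels_train[rownames(theta_train)]
  zs <- function(m) {
    sds <- apply(m, 1, stats::sd)
    sds[sds == 0] <- 1
    (m - rowMeans(m)) / (sds * sqrt(ncol(m) - 1))
  }
  sim <- tcrossprod(zs(theta_new), zs(theta_train))
  out <- apply(sim, 1, function(r) {
    nb <- order(r, decreasing = TRUE)[seq_len(k)]
    votes <- table(labels_train[nb])
    names(votes)[which.max(votes)]
  })
  stats::setNames(out, rownames(theta_new))
}

#' Project transformed cells into the four-state model
#'
#' Scores each cell for the OPC-, NPC-, astrocyte- and mesenchymal-like
#' states as the mean centered log-normalized expression of the state gene
#' set minus that of an expression-matched control set (30 average-expression
#' bins, 100 control genes drawn per signature gene). The two-dimensional
#' coordinates place proneural states up (\code{y > 0}) and, within each
#' half, separate the two candidate states along x.
#'
#' @param x genes x cells counts of transformed cells.
#' @param state_sets named list with elements OPC, NPC, AC, MES.
#' @param n_bins,n_control control-set construction parameters.
#' @param seed seed for control-gene sampling.
#' @return data.frame: cell, OPC, NPC, AC, MES, state, x, y, ambiguous.
#' @export
fourStateProjection <- function(x, state_sets, n_bins = 30L,
                                n_control = 100L, seed = 1L) {
  states <- c("OPC", "NPC", "AC", "MES")
  if (!all(states %in% names(state_sets)))
    stop("state_sets must contain OPC, NPC, AC and MES")
  if (any(lengths(state_sets[states]) == 0)) stop("empty state gene set")
  m <- .counts(x)
  E <- log2(as.matrix(cp10k(m)) + 1)
  Erel <- E - rowMeans(E)              # centered relative expression
  avg <- rowMeans(E)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  binPool <- split(rownames(m), bins)
  score1 <- function(set) {
    set <- intersect(set, rownames(m))
    if (!length(set)) stop("state gene set shares no genes with the matrix")
    ctrl <- .withSeed(.childSeed(seed, "ctrl", set[1]), {
      unlist(lapply(set, function(g) {
        pool <- setdiff(binPool[[bins[match(g, rownames(m))]]], set)
        if (!length(pool)) return(character(0))
        pool[sample.int(length(pool), min(n_control, length(pool)))]
      }))
    })
    colMeans(Erel[set, , drop = FALSE]) -
      colMeans(Erel[unique(ctrl), , drop = FALSE])
  }
  sc <- vapply(states, function(s) score1(state_sets[[s]]),
               numeric(ncol(m)))
  y <- pmax(sc[, "OPC"], sc[, "NPC"]) - pmax(sc[, "AC"], sc[, "MES"])
  xx <- ifelse(y > 0, sc[, "NPC"] - sc[, "OPC"], sc[, "MES"] - sc[, "AC"])
  best <- apply(sc, 1, function(r) states[which.max(r)])
  amb <- apply(sc, 1, function(r) sum(r == max(r)) > 1)
  data.frame(cell = colnames(m), OPC = sc[, "OPC"], NPC = sc[, "NPC"],
             AC = sc[, "AC"], MES = sc[, "MES"], state = best, x = xx,
             y = y, ambiguous = amb, row.names = NULL,
             stringsAsFactors = FALSE)
}
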