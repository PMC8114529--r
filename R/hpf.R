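## Hierarchical Poisson factorization of UMI counts.
##
## Generative model: cell budgets xi_i ~ Gamma(a', b'), gene budgets
## eta_g ~ Gamma(c', d'), cell weights theta_ik ~ Gamma(a, xi_i), gene
## weights beta_gk ~ Gamma(c, eta_g), counts
## x_ig ~ Poisson(sum_k theta_ik beta_gk). Inference is coordinate-ascent
## variational (CAVI) with Gamma variational factors and the usual
## multinomial auxiliary lift of the Poisson sum.

#' @useDynLib slicepharm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Balanced subsampling of cells across samples
#'
#' Draws exactly \code{n_per_sample} cells uniformly without replacement from
#' every sample, so no sample dominates the factorization.
#'
#' @param slices list of genes x cells matrices or SingleCellExperiments
#'   sharing rownames.
#' @param n_per_sample cells to draw per sample.
#' @param seed integer seed.
#' @return a merged object of the same class with
#'   \code{n_samples * n_per_sample} cells, sample order preserved.
#' @examples
#' cohort <- generateCohort(cohortConfig(n_patients = 2, cells_per_slice = 60,
#'                                       n_genes = 300))
#' ncol(subsampleBalanced(cohort$slices, 50, seed = 1))
#' @export
subsampleBalanced <- function(slices, n_per_sample, seed = 1L) {
  sizes <- vapply(slices, ncol, integer(1))
  if (any(sizes < n_per_sample))
    stop("sample(s) smaller than n_per_sample: ",
         paste(names(slices)[sizes < n_per_sample], collapse = ", "))
  .withSeed(.childSeed(seed, "subsample"), {
    picked <- lapply(slices, function(s)
      s[, sort(sample.int(ncol(s), n_per_sample)), drop = FALSE])
    do.call(cbind, unname(picked))
  })
}

#' Select genes for factorization
#'
#' Keeps genes detected (count > 0) in at least \code{min_cells} cells and,
#' when given, restricted to a protein-coding list. A fitted model records
#' its gene subset so projection reuses it exactly.
#'
#' @param x genes x cells count matrix or SingleCellExperiment.
#' @param min_cells detection threshold (default 10).
#' @param protein_coding optional character vector of admissible genes.
#' @return character vector of selected gene identifiers.
#' @export
selectGenes <- function(x, min_cells = 10L, protein_coding = NULL) {
  m <- .counts(x)
  det <- Matrix::rowSums(m > 0)
  keep <- rownames(m)[det >= min_cells]
  if (!is.null(protein_coding)) keep <- intersect(keep, protein_coding)
  if (!length(keep)) stop("no genes pass selection")
  keep
}

.gammaEntropy <- function(shape, rate) {
  shape - log(rate) + lgamma(shape) + (1 - shape) * digamma(shape)
}

# full ELBO given current variational parameters and the profile likelihood
# term from the allocation step
.hpfElbo <- function(lik, par, hyper, lgx) {
  Et <- par$thetaShape / par$thetaRate
  Eb <- par$betaShape / par$betaRate
  Exi <- par$xiShape / par$xiRate
  Eeta <- par$etaShape / par$etaRate
  Elt <- digamma(par$thetaShape) - log(par$thetaRate)
  Elb <- digamma(par$betaShape) - log(par$betaRate)
  Elxi <- digamma(par$xiShape) - log(par$xiRate)
  Eleta <- digamma(par$etaShape) - log(par$etaRate)
  K <- ncol(Et)
  a <- hyper$a; cc <- hyper$c
  aP <- hyper$aPrime; cP <- hyper$cPrime
  bP <- hyper$bPrime; dP <- hyper$dPrime
  lik - sum(colSums(Et) * colSums(Eb)) - lgx +
    sum(a * Elxi * K + (a - 1) * rowSums(Elt) - Exi * rowSums(Et) -
          K * lgamma(a)) +
    sum(cc * Eleta * K + (cc - 1) * rowSums(Elb) - Eeta * rowSums(Eb) -
          K * lgamma(cc)) +
    sum(aP * log(bP) + (aP - 1) * Elxi - bP * Exi - lgamma(aP)) +
    sum(cP * log(dP) + (cP - 1) * Eleta - dP * Eeta - lgamma(cP)) +
    sum(.gammaEntropy(par$thetaShape, par$thetaRate)) +
    sum(.gammaEntropy(par$betaShape, par$betaRate)) +
    sum(.gammaEntropy(par$xiShape, par$xiRate)) +
    sum(.gammaEntropy(par$etaShape, par$etaRate))
}

#' Fit a hierarchical Poisson factorization
#'
#' Coordinate-ascent variational inference for the Gamma-Poisson hierarchy
#' described above. The evidence lower bound is non-decreasing at every
#' epoch; convergence is declared when the relative ELBO change between
#' successive checks (every \code{check_every} epochs) falls below
#' \code{tol}. The best of \code{n_restarts} seeded restarts (by final ELBO)
#' is returned.
#'
#' @param x genes x cells integer count matrix or SingleCellExperiment.
#' @param K number of factors.
#' @param a,c Gamma shape hyperparameters of the cell / gene weights
#'   (default 0.3, the sparse regime typical for UMI data).
#' @param aPrime,cPrime budget hyperprior shapes (default 1); the budget
#'   rates are set from the per-cell / per-gene means of the data.
#' @param max_epochs,tol,check_every convergence control.
#' @param n_restarts independent seeded initializations.
#' @param seed master seed.
#' @param verbose print ELBO progress.
#' @return a \linkS4class{FactorModel}.
#' @export
fitHPF <- function(x, K, a = 0.3, c = 0.3, aPrime = 1, cPrime = 1,
                   max_epochs = 500L, tol = 1e-5, check_every = 10L,
                   n_restarts = 3L, seed = 1L, verbose = FALSE) {
  m <- .counts(x)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  n <- ncol(m); G <- nrow(m)
  if (K >= min(n, G)) stop("K must be smaller than both dimensions")
  K <- as.integer(K)
  sp <- methods::as(m, "TsparseMatrix")
  ci <- sp@j; gi <- sp@i; xv <- sp@x   # cells are columns
  keep <- xv > 0
  ci <- ci[keep]; gi <- gi[keep]; xv <- xv[keep]
  lgx <- sum(lgamma(xv + 1))
  dbar <- sum(xv) / n
  t0 <- sqrt(dbar / (K * G))           # target scale of E[theta], E[beta]
  xi0 <- a / t0; eta0 <- c / t0
  hyper <- list(a = a, c = c, aPrime = aPrime, cPrime = cPrime,
                bPrime = aPrime / xi0, dPrime = cPrime / eta0, K = K)

  runOne <- function(rseed) {
    par <- .withSeed(rseed, list(
      thetaShape = matrix(a * (1 + stats::runif(n * K)), n, K),
      thetaRate = matrix(xi0 * (1 + stats::runif(n * K)), n, K),
      betaShape = matrix(c * (1 + stats::runif(G * K)), G, K),
      betaRate = matrix(eta0 * (1 + stats::runif(G * K)), G, K),
      xiShape = rep(aPrime + K * a, n),
      xiRate = rep(hyper$bPrime * 2, n),
      etaShape = rep(cPrime + K * c, G),
      etaRate = rep(hyper$dPrime * 2, G)))
    elbo <- numeric(0)
    last <- -Inf
    Elb <- digamma(par$betaShape) - log(par$betaRate)
    Elt <- digamma(par$thetaShape) - log(par$thetaRate)
    al <- hpf_allocate(ci, gi, xv, Elt, Elb)
    for (epoch in seq_len(max_epochs)) {
      # cell side (al is the allocation at the current Elt/Elb)
      Eb <- par$betaShape / par$betaRate
      Exi <- par$xiShape / par$xiRate
      par$thetaShape <- a + al$thetaAcc
      par$thetaRate <- Exi + matrix(colSums(Eb), n, K, byrow = TRUE)
      Et <- par$thetaShape / par$thetaRate
      par$xiRate <- hyper$bPrime + rowSums(Et)
      # gene side with refreshed cell-side expectations
      Elt <- digamma(par$thetaShape) - log(par$thetaRate)
      al <- hpf_allocate(ci, gi, xv, Elt, Elb)
      Eeta <- par$etaShape / par$etaRate
      par$betaShape <- c + al$betaAcc
      par$betaRate <- Eeta + matrix(colSums(Et), G, K, byrow = TRUE)
      Eb <- par$betaShape / par$betaRate
      par$etaRate <- hyper$dPrime + rowSums(Eb)
      # profile ELBO at the refreshed state; this allocation doubles as the
      # next epoch's cell-side step (Elt/Elb unchanged until then)
      Elb <- digamma(par$betaShape) - log(par$betaRate)
      al <- hpf_allocate(ci, gi, xv, Elt, Elb)
      e <- .hpfElbo(al$lik, par, hyper, lgx)
      elbo <- append(elbo, e)   # note: `c` is a hyperparameter in this scope
      if (verbose && epoch %% check_every == 0)
        message(sprintf("epoch %d  ELBO %.4f", epoch, e))
      if (epoch %% check_every == 0) {
        if (is.finite(last) && abs((e - last) / last) < tol) break
        last <- e
      }
    }
    list(par = par, elbo = elbo)
  }

  runs <- lapply(seq_len(n_restarts), function(r)
    runOne(.childSeed(seed, "hpf", r)))
  best <- runs[[which.max(vapply(runs, function(r) max(r$elbo),
                                 numeric(1)))]]
  par <- best$par
  new("FactorModel", K = K,
      theta = par$thetaShape / par$thetaRate,
      beta = par$betaShape / par$betaRate,
      thetaShape = par$thetaShape, thetaRate = par$thetaRate,
      betaShape = par$betaShape, betaRate = par$betaRate,
      xiShape = par$xiShape, xiRate = par$xiRate,
      etaShape = par$etaShape, etaRate = par$etaRate,
      hyper = hyper,
      geneIds = rownames(m),
      cellIds = if (is.null(colnames(m))) as.character(seq_len(n))
                else colnames(m),
      elbo = best$elbo,
      nuisance = rep(FALSE, K))
}

#' Project held-out cells onto a fitted factor model
#'
#' Holds the variational distributions of the gene-side (global) variables
#' fixed and iterates the cell-side updates for the new cells; the returned
#' gene parameters of the model are untouched.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param x genes x cells counts for the new cells, restricted to (or
#'   containing) the model's gene subset.
#' @param max_iter,tol convergence control on the relative change of the
#'   cell weights.
#' @param init optional warm start: list with \code{thetaShape},
#'   \code{thetaRate}, \code{xiShape}, \code{xiRate} for the new cells
#'   (e.g. the training-cell parameters when re-projecting training data).
#'   The default cold start is deterministic (prior-scale initialization);
#'   because the cell-side objective is multimodal, isolated cells can
#'   converge to a different local optimum than a random-restart training
#'   run found.
#' @return list: \code{theta} (new cells x K), \code{xi} (budget
#'   expectations), \code{thetaShape}, \code{thetaRate}, \code{zeroCells}
#'   (cells with no counts, returned at the prior mean and flagged).
#' @export
projectCells <- function(model, x, max_iter = 200L, tol = 1e-10,
                         init = NULL) {
  m <- .counts(x)
  if (!all(model@geneIds %in% rownames(m)))
    stop("projection data lack genes used by the model")
  m <- m[model@geneIds, , drop = FALSE]
  n <- ncol(m); G <- nrow(m); K <- model@K
  h <- model@hyper
  sp <- methods::as(m, "TsparseMatrix")
  ci <- sp@j; gi <- sp@i; xv <- sp@x
  keep <- xv > 0; ci <- ci[keep]; gi <- gi[keep]; xv <- xv[keep]
  Elb <- digamma(model@betaShape) - log(model@betaRate)
  Eb <- model@beta
  colB <- colSums(Eb)
  if (is.null(init)) {
    thetaShape <- matrix(h$a * 1.5, n, K)
    thetaRate <- matrix(h$aPrime / h$bPrime, n, K)  # prior mean of xi
    xiShape <- rep(h$aPrime + K * h$a, n)
    xiRate <- rep(h$bPrime * 2, n)
  } else {
    thetaShape <- init$thetaShape; thetaRate <- init$thetaRate
    xiShape <- init$xiShape; xiRate <- init$xiRate
  }
  prev <- thetaShape / thetaRate
  for (it in seq_len(max_iter)) {
    Elt <- digamma(thetaShape) - log(thetaRate)
    acc <- hpf_allocate_cells(ci, gi, xv, Elt, Elb)
    thetaShape <- h$a + acc
    thetaRate <- (xiShape / xiRate) + matrix(colB, n, K, byrow = TRUE)
    Et <- thetaShape / thetaRate
    xiRate <- h$bPrime + rowSums(Et)
    rel <- max(abs(Et - prev) / (abs(prev) + 1e-12))
    prev <- Et
    if (rel < tol) break
  }
  zero <- Matrix::colSums(m) == 0
  if (any(zero))
    message(sum(zero), " all-zero cell(s) projected at the prior mean")
  rownames(prev) <- colnames(m)
  list(theta = prev, xi = xiShape / xiRate,
       thetaShape = thetaShape, thetaRate = thetaRate,
       zeroCells = colnames(m)[zero])
}

#' Imputed expression matrix from a factor model
#'
#' \eqn{G = \log_2(\Xi \Theta B^T + 1)} where \eqn{\Xi} is the diagonal cell
#' scaling matrix with entries \eqn{E[\xi_i | x] \times 10{,}000}.
#'
#' @param model a \linkS4class{FactorModel}, or a list with elements
#'   \code{theta} and \code{xi} (e.g. from \code{\link{projectCells}}) when
#'   \code{beta} is supplied separately.
#' @param genes optional subset of model genes to impute (saves memory).
#' @param theta,xi optional cell-side replacements (projected cells).
#' @return dense cells x genes matrix of imputed log2 expression.
#' @export
imputeExpression <- function(model, genes = NULL, theta = NULL, xi = NULL) {
  if (is.null(theta)) theta <- model@theta
  if (is.null(xi)) xi <- model@xiShape / model@xiRate
  beta <- model@beta
  rownames(beta) <- model@geneIds
  if (!is.null(genes)) beta <- beta[genes, , drop = FALSE]
  lam <- (theta %*% t(beta)) * (xi * 10000)
  log2(lam + 1)
}

#' Flag nuisance (technical) factors
#'
#' A factor is flagged when its cell scores track sequencing depth
#' (|Pearson r| with log total UMIs above \code{r_min}), or when at least
#' \code{p_min} of its top-\code{n_top} genes lie in the
#' housekeeping/ribosomal panel or in the stress panel.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param annotation \linkS4class{GeneAnnotation}; panels
#'   \code{"housekeeping_ribosomal"} (or \code{"housekeeping"}) and
#'   \code{"stress"} are used when present.
#' @param total_umis named per-cell total molecule counts for the fitted
#'   cells.
#' @param r_min depth-correlation threshold (default 0.5).
#' @param p_min panel-overlap threshold (default 0.2).
#' @param n_top signature size examined (default 100).
#' @return the model with updated nuisance flags.
#' @export
detectNuisanceFactors <- function(model, annotation, total_umis,
                                  r_min = 0.5, p_min = 0.2, n_top = 100L) {
  ld <- log(total_umis[model@cellIds])
  flags <- rep(FALSE, model@K)
  for (k in seq_len(model@K))
    flags[k] <- isTRUE(abs(stats::cor(model@theta[, k], ld)) > r_min)
  pn <- panelNames(annotation)
  hk <- if ("housekeeping_ribosomal" %in% pn)
    genePanel(annotation, "housekeeping_ribosomal")
  else if ("housekeeping" %in% pn) genePanel(annotation, "housekeeping")
  else NULL
  st <- if ("stress" %in% pn) genePanel(annotation, "stress") else NULL
  if (is.null(hk) && is.null(st))
    message("no housekeeping/stress panels; only the coverage rule applied")
  sigs <- factorSignatures(model, n = n_top, exclude_nuisance = FALSE)
  for (k in seq_len(model@K)) {
    top <- sigs[[k]]
    if (!is.null(hk) && mean(top %in% hk) >= p_min) flags[k] <- TRUE
    if (!is.null(st) && mean(top %in% st) >= p_min) flags[k] <- TRUE
  }
  model@nuisance <- flags
  model
}

#' Aneuploidy calls from imputed expression
#'
#' Scores each cell by the difference between the mean imputed expression of
#' chromosome 7 genes and that of chromosome 10 genes, averages the score
#' per cluster, and calls clusters whose score exceeds the grand mean of
#' cluster scores malignantly transformed.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param annotation \linkS4class{GeneAnnotation}.
#' @param clusters named cluster labels for the model's cells.
#' @param theta,xi optional cell-side replacements (projected cells with
#'   names on the rows of theta).
#' @return list: \code{cell_score}, \code{cluster_score},
#'   \code{malignant_clusters}, \code{cell_call} (logical).
#' @export
factorAneuploidyCall <- function(model, annotation, clusters,
                                 theta = NULL, xi = NULL) {
  g7 <- intersect(genesOnChromosome(annotation, "7"), model@geneIds)
  g10 <- intersect(genesOnChromosome(annotation, "10"), model@geneIds)
  if (!length(g7) || !length(g10))
    stop("chromosome 7/10 genes absent from the model's gene subset")
  G7 <- imputeExpression(model, genes = g7, theta = theta, xi = xi)
  G10 <- imputeExpression(model, genes = g10, theta = theta, xi = xi)
  score <- rowMeans(G7) - rowMeans(G10)
  cells <- if (is.null(theta)) model@cellIds else rownames(theta)
  names(score) <- cells
  clusters <- clusters[cells]
  cs <- tapply(score, clusters, mean)
  mal <- names(cs)[cs > mean(cs)]
  list(cell_score = score, cluster_score = cs, malignant_clusters = mal,
       cell_call = stats::setNames(as.character(clusters) %in% mal, cells))
}

#' @rdname FactorModel
#' @export
setMethod("nFactors", "FactorModel", function(object) object@K)

#' @rdname FactorModel
#' @param normalized when TRUE (default), weights are normalized by the
#'   corresponding budget expectation (cell scores \eqn{\theta_{ik}\xi_i},
#'   gene scores \eqn{\beta_{gk}\eta_g}), which divides out overall depth /
#'   expression level and leaves the factor-specific signal; FALSE returns
#'   the raw posterior means.
#' @param ... unused.
#' @export
setMethod("cellScores", "FactorModel", function(object, normalized = TRUE,
                                                ...) {
  out <- object@theta
  if (normalized) out <- out * (object@xiShape / object@xiRate)
  rownames(out) <- object@cellIds
  colnames(out) <- paste0("F", seq_len(object@K))
  out
})

#' @rdname FactorModel
#' @export
setMethod("geneScores", "FactorModel", function(object, normalized = TRUE,
                                                ...) {
  out <- object@beta
  if (normalized) out <- out * (object@etaShape / object@etaRate)
  rownames(out) <- object@geneIds
  colnames(out) <- paste0("F", seq_len(object@K))
  out
})

#' @rdname FactorModel
#' @export
setMethod("nuisanceFactors", "FactorModel", function(object)
  which(object@nuisance))

#' Ranked factor signatures
#'
#' Top genes of each factor, ranked by factor specificity: the
#' budget-normalized gene score \eqn{\beta_{gk}\eta_g} divided by the
#' gene's total score across factors, so genes whose weight concentrates on
#' one factor rank first and ubiquitously expressed genes (which load on
#' every factor) rank low. Ties are broken by gene identifier, so the
#' ranking is deterministic.
#'
#' @param object a \linkS4class{FactorModel}.
#' @param n signature size (default 100).
#' @param exclude_nuisance drop flagged factors (default TRUE).
#' @return named list of character vectors.
#' @rdname FactorModel
#' @export
setMethod("factorSignatures", "FactorModel",
          function(object, n = 100L, exclude_nuisance = TRUE, ...) {
  keep <- if (exclude_nuisance) which(!object@nuisance)
          else seq_len(object@K)
  gs <- geneScores(object, normalized = TRUE)
  gs <- gs / rowSums(gs)
  sigs <- lapply(keep, function(k) {
    ord <- order(-gs[, k], object@geneIds)
    object@geneIds[ord[seq_len(min(n, length(ord)))]]
  })
  names(sigs) <- paste0("F", keep)
  sigs
})

setMethod("show", "FactorModel", function(object) {
  cat("FactorModel:", length(object@cellIds), "cells x",
      length(object@geneIds), "genes,", object@K, "factors\n")
  cat(sprintf("  final ELBO %.2f after %d epochs; %d nuisance factor(s)\n",
              utils::tail(object@elbo, 1), length(object@elbo),
              sum(object@nuisance)))
})
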