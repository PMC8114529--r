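# Shared fixtures and independent oracles, built in code at test time.

suppressPackageStartupMessages({
  library(Matrix)
  library(SingleCellExperiment)
})

# small cohort reused across tests (generated once per test run)
.smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(cohortConfig(n_patients = 2,
                                            cells_per_slice = 120,
                                            n_genes = 600, seed = 101))
    cache
  }
})

# exhaustive two-sided Mann-Whitney oracle: enumerate all C(n1+n2, n1)
# assignments of the observed (untied) values to group A
mwuExactOracle <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  stat <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  uObs <- stat(seq_len(n1))
  all <- utils::combn(length(vals), n1)
  us <- apply(all, 2, stat)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# textbook Benjamini-Hochberg step-up
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# best factor matching over all permutations (small K): mean Pearson r of
# matched gene-weight columns
matchFactors <- function(trueBeta, fitBeta) {
  K <- ncol(trueBeta)
  cm <- stats::cor(trueBeta, fitBeta)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  max(vapply(perms(seq_len(K)),
             function(p) mean(cm[cbind(seq_len(K), p)]), numeric(1)))
}

# adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  (sumij - expected) / (maxidx - expected)
}

# minimal FactorModel built directly from matrices (for accessor/flagging
# tests that need controlled structure)
makeFactorModel <- function(theta, beta, xi = NULL, eta = NULL,
                            geneIds = NULL, cellIds = NULL) {
  n <- nrow(theta); G <- nrow(beta); K <- ncol(theta)
  if (is.null(xi)) xi <- rep(1, n)
  if (is.null(eta)) eta <- rep(1, G)
  if (is.null(geneIds)) geneIds <- sprintf("G%04d", seq_len(G))
  if (is.null(cellIds)) cellIds <- sprintf("C%04d", seq_len(n))
  new("FactorModel", K = as.integer(K), theta = theta, beta = beta,
      thetaShape = theta, thetaRate = matrix(1, n, K),
      betaShape = beta, betaRate = matrix(1, G, K),
      xiShape = xi, xiRate = rep(1, n),
      etaShape = eta, etaRate = rep(1, G),
      hyper = list(a = 0.3, c = 0.3, aPrime = 1, cPrime = 1,
                   bPrime = 1, dPrime = 1, K = as.integer(K)),
      geneIds = geneIds, cellIds = cellIds,
      elbo = c(-2, -1), nuisance = rep(FALSE, K))
}
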