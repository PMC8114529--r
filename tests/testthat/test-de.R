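test_that("rank-sum p-values match exhaustive enumeration for small samples", {
  # the canonical extreme case: U = 0, two-sided p = 2/20
  res <- compareSignature(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_true(res$exact)
  # identical groups score p = 1
  expect_equal(compareSignature(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(compareSignature(numeric(0), 1:3), "empty")
  # random untied cases, n = m <= 8: agree with the enumeration oracle
  set.seed(20)
  for (n in c(3, 5, 8)) {
    for (rep in 1:5) {
      a <- sample(seq_len(100), n); b <- sample(setdiff(seq_len(100), a), n)
      got <- compareSignature(a, b)
      expect_true(got$exact)
      expect_equal(got$p, mwuExactOracle(a, b))
    }
  }
  # approximation agrees with the exact tail within 10% at n = m = 8
  set.seed(21)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    pe <- compareSignature(a, b)$p
    pa <- slicepharm:::.mwu2(a, b, exact_max = 0)$p
    expect_lt(abs(pa - pe) / pe, 0.12)
  }
})

test_that("rank-sum tests are invariant under monotone transforms", {
  set.seed(22)
  a <- rlnorm(30); b <- rlnorm(25, 0.5)
  p0 <- compareSignature(a, b)$p
  expect_equal(compareSignature(log(a), log(b))$p, p0)
  expect_equal(compareSignature(a^3, b^3)$p, p0)
  expect_equal(compareSignature(exp(a), exp(b))$p, p0)
})

test_that("implementation agrees with wilcox.test as an independent check", {
  set.seed(23)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  got <- compareSignature(a, b)
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # and in the exact small-sample regime
  a2 <- sample(100, 6); b2 <- sample(setdiff(1:100, a2), 7)
  ref2 <- stats::wilcox.test(a2, b2, exact = TRUE)
  expect_equal(compareSignature(a2, b2)$p, ref2$p.value)
})

test_that("BH adjustment equals the step-up definition on small inputs", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               rep(0.03, 3))
  set.seed(24)
  for (m in c(1, 2, 5, 10)) {
    for (rep in 1:20) {
      p <- runif(m)
      expect_equal(stats::p.adjust(p, method = "BH"), bhOracle(p))
    }
  }
})

test_that("depth matching equalizes cell numbers and mean depth", {
  set.seed(25)
  G <- 200
  a <- matrix(rpois(G * 120, 10), G, 120,
              dimnames = list(paste0("g", 1:G), paste0("a", 1:120)))
  b <- matrix(rpois(G * 80, 5), G, 80,
              dimnames = list(paste0("g", 1:G), paste0("b", 1:80)))
  eq <- depthMatchSubsample(a, b, seed = 3)
  expect_equal(ncol(eq$a), 80)
  expect_equal(ncol(eq$b), 80)
  da <- mean(Matrix::colSums(eq$a)); db <- mean(Matrix::colSums(eq$b))
  expect_lt(abs(da - db) / max(da, db), 0.005)
  # counts never increase
  expect_true(all(as.matrix(eq$a) <= a[, colnames(eq$a)]))
  # reproducible under the seed
  eq2 <- depthMatchSubsample(a, b, seed = 3)
  expect_identical(as.matrix(eq$a), as.matrix(eq2$a))
  # equal sizes and depths pass through unchanged
  eq3 <- depthMatchSubsample(b, b, seed = 1)
  expect_identical(as.matrix(eq3$a), as.matrix(eq3$b))
  expect_error(depthMatchSubsample(a * 0, b), "zero total")
})

test_that("pooled size factors track true depth ratios", {
  set.seed(26)
  G <- 300
  prof <- rgamma(G, 2, 2)
  # identical cells: all factors 1
  same <- matrix(rep(rpois(G, 20), 30), G, 30,
                 dimnames = list(paste0("g", 1:G), paste0("c", 1:30)))
  nf <- normalizeCounts(same)
  expect_true(all(abs(nf$size_factors - 1) < 1e-8))
  # a cell with exactly twice another's profile gets twice the factor
  base <- rpois(G, 20)
  dbl <- cbind(matrix(rep(base, 30), G, 30),
               matrix(rep(2L * base, 30), G, 30))
  rownames(dbl) <- paste0("g", 1:G)
  colnames(dbl) <- paste0("c", 1:60)
  nf2 <- normalizeCounts(dbl)
  ratio <- nf2$size_factors[31:60] / nf2$size_factors[1:30]
  expect_true(all(abs(ratio - 2) < 1e-6))
  # Poisson cells with varying depth: factors proportional to depth
  depth <- runif(100, 0.3, 3)
  pois <- vapply(depth, function(d) rpois(G, 30 * d * prof), numeric(G))
  rownames(pois) <- paste0("g", 1:G); colnames(pois) <- paste0("c", 1:100)
  nf3 <- normalizeCounts(pois)
  expect_gte(stats::cor(nf3$size_factors, depth), 0.99)
  expect_error(normalizeCounts(pois[, 1:10]), "20 cells")
})

test_that("differential expression recovers planted fold changes", {
  set.seed(27)
  G <- 400; n <- 150
  lam <- rgamma(G, 2, 0.5)
  planted <- 1:40
  a <- matrix(rpois(G * n, lam), G, n)
  lamB <- lam; lamB[planted] <- lamB[planted] * 4
  b <- matrix(rpois(G * n, lamB), G, n)
  dimnames(a) <- list(paste0("g", 1:G), paste0("a", 1:n))
  dimnames(b) <- list(paste0("g", 1:G), paste0("b", 1:n))
  de <- differentialExpression(b, a)
  hits <- de$gene[de$q < 0.05 & de$log2fc > 0]
  expect_gte(mean(paste0("g", planted) %in% hits), 0.9)
  # BH column consistent with p.adjust, q in [0, 1]
  expect_equal(de$q, stats::p.adjust(de$p, method = "BH"))
  expect_true(all(de$q >= de$p | abs(de$q - de$p) < 1e-12))
  expect_true(all(de$q >= 0 & de$q <= 1))
  # protein-coding restriction
  de2 <- differentialExpression(b, a, protein_coding = paste0("g", 1:100))
  expect_equal(nrow(de2), 100)
  expect_error(differentialExpression(a[, 1:2], b), "3 cells")
})

test_that("null data give calibrated rank-sum p-values", {
  set.seed(28)
  fp <- numeric(5)
  for (s in 1:5) {
    G <- 500
    lam <- rgamma(G, 2, 0.5)
    a <- matrix(rpois(G * 100, lam), G, 100,
                dimnames = list(paste0("g", 1:G), paste0("a", 1:100)))
    b <- matrix(rpois(G * 100, lam), G, 100,
                dimnames = list(paste0("g", 1:G), paste0("b", 1:100)))
    de <- differentialExpression(a, b)
    fp[s] <- mean(de$p < 0.05)
  }
  expect_lt(abs(mean(fp) - 0.05), 0.02)
})

test_that("signature scores equal a dense mean over the panel", {
  set.seed(29)
  G <- 60; n <- 25
  m <- matrix(rpois(G * n, 5), G, n,
              dimnames = list(paste0("g", 1:G), paste0("c", 1:n)))
  sig <- list(f1 = paste0("g", 1:10))
  st <- signatureScores(m, sig)
  dense <- apply(m, 2, function(x) mean(x[1:10] / sum(x) * 1e4))
  expect_equal(st$score, unname(dense))
  # one-gene signature equals that gene's normalized value
  st1 <- signatureScores(m, list(f = "g5"))
  expect_equal(st1$score, unname(m["g5", ] / colSums(m) * 1e4))
  # zero counts on the signature give zero
  m0 <- m; m0[1:10, 1] <- 0
  expect_equal(signatureScores(m0, sig)$score[1], 0)
  expect_error(signatureScores(m, list(f = "nope")), "no genes")
  expect_message(signatureScores(m, list(f = c("g1", "nope"))), "missing")
})

test_that("fold-change matrices are antisymmetric in the comparison", {
  set.seed(30)
  sc <- data.frame(
    cell = sprintf("c%03d", 1:200),
    factor = "F1",
    score = rgamma(200, 4, 1),
    slice = rep(c("T1", "V1", "V2", "T2"), each = 50),
    patient = "P1",
    treatment = rep(c("drug", "vehicle", "vehicle", "drug"), each = 50),
    cell_type = "tumor", stringsAsFactors = FALSE)
  fc <- treatmentFoldChange(sc, "tumor")
  # swapped roles negate every entry
  sc2 <- sc
  sc2$treatment <- ifelse(sc$treatment == "vehicle", "drug", "vehicle")
  fc2 <- treatmentFoldChange(sc2, "tumor")
  expect_equal(fc[["T1"]]["F1", "V1"], -fc2[["V1"]]["F1", "T1"])
  # equal means give zero; doubled means give ~1 well above the pseudocount
  scEq <- sc; scEq$score <- 7
  fcEq <- treatmentFoldChange(scEq, "tumor")
  expect_equal(unname(fcEq[["T1"]]["F1", ]), c(0, 0))
  scUp <- sc; scUp$score <- ifelse(scUp$treatment == "vehicle", 1000, 2000)
  expect_lt(abs(treatmentFoldChange(scUp, "tumor")[["T1"]]["F1", "V1"] - 1),
            0.01)
  # too few cells of the type flags the entry missing
  scFew <- sc[c(1:5, 51:100), ]
  expect_true(is.na(treatmentFoldChange(scFew, "tumor")[["T1"]]["F1", "V1"]))
})
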