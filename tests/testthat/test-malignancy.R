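test_that("chromosome mean expression equals a dense recomputation", {
  set.seed(5)
  G <- 44; n <- 30
  m <- matrix(rpois(G * n, 5), G, n,
              dimnames = list(paste0("g", 1:G), paste0("c", 1:n)))
  ann <- GeneAnnotation(rownames(m))      # round-robin over 22 autosomes
  got <- chromosomeMeanExpression(m, ann, "7")
  dense <- apply(m, 2, function(x) {
    v <- x / sum(x) * 1e4
    mean(v[ann@chromosome == "7"])
  })
  expect_equal(unname(got), unname(dense))
  # all-zero chromosome genes give mean 0
  m2 <- m; m2[ann@chromosome == "7", 1] <- 0
  expect_equal(unname(chromosomeMeanExpression(m2, ann, "7")[1]), 0)
  expect_error(chromosomeMeanExpression(m, ann, "99"), "no genes")
})

test_that("malignancy score is the log2 chromosome ratio with pseudocount", {
  # a cell with equal chromosome 7 and 10 means scores 0
  G <- 44
  m <- matrix(10, G, 3, dimnames = list(paste0("g", 1:G), paste0("c", 1:3)))
  ann <- GeneAnnotation(rownames(m))
  expect_equal(unname(malignancyScore(m, ann)), rep(0, 3))
  # doubling chromosome 7 counts well above the pseudocount gives ~1
  m[ann@chromosome == "7", ] <- 1000
  m[ann@chromosome == "10", ] <- 500
  sc <- malignancyScore(m, ann)
  expect_true(all(abs(sc - 1) < 0.1))
})

test_that("double-Gaussian EM recovers planted components", {
  for (s in 1:20) {
    set.seed(s)
    x <- c(rnorm(1000, 0, 0.2), rnorm(1000, 1.5, 0.3))
    fit <- fitDoubleGaussian(x)
    expect_lt(abs(fit$muLo - 0), 0.05)
    expect_lt(abs(fit$muHi - 1.5), 0.05)
    expect_true(all(diff(fit$logLik) >= -1e-7 * abs(fit$logLik[-1])))
  }
  # invariant to data order
  set.seed(1)
  x <- c(rnorm(500), rnorm(500, 3))
  f1 <- fitDoubleGaussian(x)
  f2 <- fitDoubleGaussian(rev(x))
  expect_equal(f1$muHi, f2$muHi)
  expect_equal(f1$sdLo, f2$sdLo)
  # single-component data flagged as poorly separated
  set.seed(2)
  f3 <- fitDoubleGaussian(rnorm(800))
  expect_false(f3$separated)
  expect_error(fitDoubleGaussian(rep(1, 100)), "distinct")
})

test_that("classification threshold and boundary conventions are exact", {
  set.seed(7)
  sc <- stats::setNames(c(rnorm(200, 0, 0.3), rnorm(200, 2, 0.5)),
                        sprintf("c%03d", 1:400))
  put <- stats::setNames(rep(c("nontumor", "tumor"), each = 200), names(sc))
  mix <- fitDoubleGaussian(sc)
  mal <- classifyMalignancy(sc, put, mixture = mix)
  expect_equal(malignancyThreshold(mal), mix$muHi - 1.96 * mix$sdHi)
  # muHi = 2.0, sdHi = 0.5 gives tau = 1.02
  mix2 <- mix; mix2$muHi <- 2.0; mix2$sdHi <- 0.5
  tau <- 2.0 - 1.96 * 0.5
  sc2 <- stats::setNames(c(tau, tau - 1e-9, tau, 3),
                         c("t1", "t2", "n1", "n2"))
  put2 <- stats::setNames(c("tumor", "tumor", "nontumor", "nontumor"),
                          names(sc2))
  mal2 <- classifyMalignancy(sc2, put2, mixture = mix2)
  expect_equal(malignancyThreshold(mal2), 1.02)
  lab <- malignancyLabels(mal2)
  expect_equal(unname(lab["t1"]), "malignant")   # at threshold: kept
  expect_equal(unname(lab["t2"]), "discarded")   # strictly below: discarded
  expect_equal(unname(lab["n1"]), "discarded")   # nontumor at/above: discarded
  expect_equal(unname(lab["n2"]), "discarded")
  expect_error(classifyMalignancy(sc2, put2[1:2], mixture = mix2), "missing")
})

test_that("threshold shifts with the scores and labels are unchanged", {
  set.seed(8)
  sc <- stats::setNames(c(rnorm(300, 0, 0.3), rnorm(300, 2, 0.4)),
                        sprintf("c%03d", 1:600))
  put <- stats::setNames(rep(c("nontumor", "tumor"), each = 300), names(sc))
  m1 <- classifyMalignancy(sc, put)
  m2 <- classifyMalignancy(sc + 5, put)
  expect_equal(malignancyThreshold(m2), malignancyThreshold(m1) + 5,
               tolerance = 1e-6)
  expect_equal(malignancyLabels(m2), malignancyLabels(m1))
})

test_that("mirrored scores give mirrored discards", {
  set.seed(9)
  sc <- stats::setNames(c(rnorm(300, 0, 0.3), rnorm(300, 2, 0.4)),
                        sprintf("c%03d", 1:600))
  put <- stats::setNames(rep(c("nontumor", "tumor"), each = 300), names(sc))
  put2 <- stats::setNames(ifelse(put == "tumor", "nontumor", "tumor"),
                          names(put))
  # a mixture whose 1.96-SD bands meet at zero mirrors onto itself
  # (muHi - 1.96 sdHi = -(muLo + 1.96 sdLo) = 0), so the mirrored threshold
  # is exactly the negated one and discards must coincide off the boundary
  symMix <- list(weightHi = 0.5, muLo = -1, muHi = 1,
                 sdLo = 1 / 1.96, sdHi = 1 / 1.96)
  x <- sc - mean(sc)
  mA <- classifyMalignancy(x, put, mixture = symMix)
  mB <- classifyMalignancy(-x, put2, mixture = symMix)
  offBoundary <- abs(x) > 1e-8
  expect_equal(malignancyLabels(mA)[offBoundary] == "discarded",
               malignancyLabels(mB)[offBoundary] == "discarded")
})

test_that("marker clustering separates planted cell types", {
  # two well-separated types: clusters recover them (ARI vs truth)
  cfg <- cohortConfig(n_patients = 1,
                      slices_per_patient = c(vehicle = 2L),
                      cells_per_slice = 150, n_genes = 400,
                      celltype_proportions = c(tumor = 0.5, myeloid = 0.5,
                                               oligodendrocyte = 0, tcell = 0,
                                               endothelial = 0, pericyte = 0),
                      tumor_fraction = 0.5, doublet_rate = 0, seed = 55)
  two <- generateCohort(cfg)
  ty2 <- clusterAndType(mergeSlices(two), two$annotation, k = 20)
  # Louvain may resolve real substructure (states, CD163+/-) within a type;
  # clusters must be pure and, merged by assigned identity, recover the types
  purity <- vapply(split(two$truth$cells$cell_type, ty2$clusters),
                   function(z) max(table(z)) / length(z), numeric(1))
  expect_true(all(purity >= 0.95))
  expect_gte(adjustedRand(ty2$cell_identity, two$truth$cells$cell_type), 0.9)
  # full cohort: per-cell assigned identities match the planted types
  cohort <- .smallCohort()
  m <- mergeSlices(cohort)
  ty <- clusterAndType(m, cohort$annotation, k = 20)
  truth <- cohort$truth$cells
  ok <- truth$cell_type != "doublet"
  expect_gte(mean(ty$cell_identity[ok] == truth$cell_type[ok]), 0.9)
  expect_error(clusterAndType(m[, 1:10], cohort$annotation, k = 20),
               "2k cells")
})

test_that("multiplet clusters are flagged only with multiple enrichments", {
  cohort <- .smallCohort()
  m <- mergeSlices(cohort)
  truth <- cohort$truth$cells
  panels <- list(tumor = genePanel(cohort$annotation, "markers_tumor"),
                 myeloid = genePanel(cohort$annotation, "markers_myeloid"))
  # use truth cell types as clusters: the doublet group is tumor+myeloid
  clusters <- stats::setNames(truth$cell_type, truth$barcode)
  fl <- flagMultipletClusters(m, clusters, panels)
  expect_true("doublet" %in% fl$flagged)
  expect_false("myeloid" %in% fl$flagged)
  expect_false("oligodendrocyte" %in% fl$flagged)
  expect_error(flagMultipletClusters(m, clusters,
                                     list(a = panels$tumor,
                                          b = panels$tumor)), "disjoint")
})

test_that("four-state projection scores, coordinates and ties behave", {
  cohort <- .smallCohort()
  ann <- cohort$annotation
  truth <- cohort$truth$cells
  m <- mergeSlices(cohort)
  tum <- truth$barcode[truth$cell_type == "tumor"]
  sets <- list(OPC = genePanel(ann, "state_OPC"),
               NPC = genePanel(ann, "state_NPC"),
               AC = genePanel(ann, "state_AC"),
               MES = genePanel(ann, "state_MES"))
  proj <- fourStateProjection(m[, tum], sets)
  acc <- mean(proj$state == truth[tum, "state"])
  expect_gte(acc, 0.9)
  # AC-dominant cells sit in the lower half-plane
  expect_lt(stats::median(proj$y[proj$state == "AC"]), 0)
  expect_error(fourStateProjection(m[, tum], sets[c("OPC", "NPC")]),
               "must contain")
  # exact four-way tie is flagged ambiguous and assigned by fixed order
  g <- 200
  flat <- matrix(5, g, 4, dimnames = list(sprintf("g%03d", 1:g),
                                          paste0("c", 1:4)))
  sets2 <- split(rownames(flat)[1:120], rep(c("OPC", "NPC", "AC", "MES"),
                                            each = 30))
  p2 <- fourStateProjection(flat, sets2)
  expect_true(all(p2$ambiguous))
  expect_true(all(p2$state == "OPC"))
})
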