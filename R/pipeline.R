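## End-to-end orchestration: malignancy typing, factorization, signatures,
## depth-matched differential expression and GSEA, with seeded
## reproducibility and provenance in every output.

# DE between two cell sets: equalize, normalize jointly, split, test
.runDE <- function(matA, matB, seed, protein_coding = NULL) {
  eq <- depthMatchSubsample(matA, matB, seed = seed)
  comb <- cbind(eq$a, eq$b)
  nrm <- normalizeCounts(comb)
  keep <- colnames(nrm$normalized)
  a <- nrm$normalized[, intersect(colnames(eq$a), keep), drop = FALSE]
  b <- nrm$normalized[, intersect(colnames(eq$b), keep), drop = FALSE]
  differentialExpression(a, b, protein_coding = protein_coding)
}

#' Run the slice-culture deconvolution pipeline end to end
#'
#' Orchestrates marker-based clustering and malignancy classification,
#' balanced subsampling and hierarchical Poisson factorization with
#' nuisance-factor removal, projection and classification of held-out
#' cells, factor-signature scores and fold-changes, per-patient
#' depth-matched differential expression, and GSEA over factor signatures.
#' Outputs are written as CSV/JSON with provenance (seed, parameters,
#' package version); reruns with the same inputs and seed are identical for
#' the deterministic stages.
#'
#' @param cohort a cohort as returned by \code{\link{generateCohort}}
#'   (slices + annotation; the ground truth is not consulted).
#' @param out_dir output directory; \code{NULL} skips writing.
#' @param K number of factors.
#' @param n_per_sample balanced subsample size per slice; default is the
#'   smallest slice.
#' @param comparison \code{"conserved"} (each treated slice's cells vs all
#'   vehicle cells within patient, pooled per patient) or
#'   \code{"replicate"} (each treated slice vs one paired vehicle slice).
#' @param de_celltypes cell types analysed for differential expression.
#' @param n_min minimum cells per group for a DE comparison.
#' @param n_perm GSEA permutations.
#' @param seed master seed.
#' @return list with the stage results (typing, malignancy, model,
#'   cell_types, signature scores, fold-changes, DE tables, GSEA tables,
#'   provenance).
#' @export
runPipeline <- function(cohort, out_dir = NULL, K = 10L,
                        n_per_sample = NULL,
                        comparison = c("conserved", "replicate"),
                        de_celltypes = c("tumor", "myeloid",
                                         "oligodendrocyte"),
                        n_min = 20L, n_perm = 250L, seed = 1L) {
  comparison <- match.arg(comparison)
  merged <- mergeSlices(cohort)
  ann <- cohort$annotation
  cd <- as.data.frame(SummarizedExperiment::colData(merged))

  ## 1. putative identities and malignancy classification
  typing <- clusterAndType(merged, ann, k = 20L)
  putative <- ifelse(typing$cell_identity == "tumor", "tumor", "nontumor")
  mscore <- malignancyScore(merged, ann)
  mal <- classifyMalignancy(mscore, putative)
  cellType <- typing$cell_identity
  cellType[malignancyLabels(mal) == "discarded"] <- NA
  cd$cell_type_called <- cellType

  ## 2. factorization on a balanced subsample, projection of the rest
  nper <- if (is.null(n_per_sample))
    min(vapply(cohort$slices, ncol, integer(1))) else n_per_sample
  sub <- subsampleBalanced(cohort$slices, nper, seed = seed)
  genes <- selectGenes(sub, min_cells = 10L)
  fit <- fitHPF(sub[genes, ], K = K, seed = seed, n_restarts = 1L,
                max_epochs = 200L, tol = 1e-4)
  tot <- Matrix::colSums(.counts(merged))
  fit <- detectNuisanceFactors(fit, ann, tot)
  heldOut <- setdiff(colnames(merged), fit@cellIds)
  trainClusters <- clusterCellScores(cellScores(fit), k = 50L)
  if (length(heldOut)) {
    proj <- projectCells(fit, merged[genes, heldOut])
    projClusters <- classifyProjected(proj$theta * proj$xi, cellScores(fit),
                                      trainClusters, k = 50L)
    allClusters <- c(trainClusters, projClusters)[colnames(merged)]
  } else {
    proj <- NULL
    allClusters <- trainClusters[colnames(merged)]
  }
  aneu <- factorAneuploidyCall(fit, ann, allClusters[fit@cellIds])

  ## 3. signature scores and fold-changes
  sigs <- factorSignatures(fit, n = 100L)
  scoreTab <- signatureScores(merged, sigs,
                              cbind(cd, cell_type = cellType))
  fc <- lapply(stats::setNames(de_celltypes, de_celltypes), function(ct) {
    ok <- tryCatch(treatmentFoldChange(scoreTab, ct, n_min = n_min),
                   error = function(e) NULL)
    ok
  })

  ## 4. differential expression per patient x drug x cell type
  drugs <- setdiff(unique(cd$treatment), "vehicle")
  deTabs <- list(); gseaTabs <- list()
  for (pat in unique(cd$patient)) {
    vehSlices <- unique(cd$slice[cd$patient == pat &
                                   cd$treatment == "vehicle"])
    if (!length(vehSlices)) {
      message("patient ", pat, ": no vehicle slices; DE skipped")
      next
    }
    for (drug in drugs) {
      trtSlices <- unique(cd$slice[cd$patient == pat &
                                     cd$treatment == drug])
      if (!length(trtSlices)) next
      pairs <- if (comparison == "conserved")
        list(list(trt = trtSlices, veh = vehSlices, tag = "pooled"))
      else lapply(seq_along(trtSlices), function(i)
        list(trt = trtSlices[i],
             veh = vehSlices[1 + (i - 1) %% length(vehSlices)],
             tag = trtSlices[i]))
      for (pr in pairs) {
        for (ct in de_celltypes) {
          inA <- cd$slice %in% pr$trt & !is.na(cellType) & cellType == ct
          inB <- cd$slice %in% pr$veh & !is.na(cellType) & cellType == ct
          if (sum(inA) < n_min || sum(inB) < n_min) {
            message(pat, "/", drug, "/", ct, " (", pr$tag,
                    "): too few cells; skipped")
            next
          }
          de <- .runDE(.counts(merged)[, inA, drop = FALSE],
                       .counts(merged)[, inB, drop = FALSE],
                       seed = .childSeed(seed, pat, drug, ct, pr$tag))
          key <- paste(pat, drug, ct, pr$tag, sep = ".")
          de$patient <- pat; de$drug <- drug; de$cell_type <- ct
          de$comparison <- pr$tag
          deTabs[[key]] <- de
          gs <- tryCatch(
            gseaPreranked(gseaRanking(de), sigs, n_perm = n_perm,
                          seed = .childSeed(seed, "gsea", key)),
            error = function(e) NULL)
          if (!is.null(gs)) {
            gs$patient <- pat; gs$drug <- drug; gs$cell_type <- ct
            gs$comparison <- pr$tag
            gseaTabs[[key]] <- gs
          }
        }
      }
    }
  }

  prov <- list(package = "slicepharm",
               version = as.character(utils::packageVersion("slicepharm")),
               seed = seed, K = K, n_per_sample = nper,
               comparison = comparison, n_perm = n_perm)
  res <- list(typing = typing, malignancy = mal, model = fit,
              projection = proj, clusters = allClusters,
              aneuploidy = aneu, cell_types = cellType,
              signature_scores = scoreTab, foldchanges = fc,
              de = deTabs, gsea = gseaTabs, provenance = prov)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(cell = names(mscore), score = mscore,
                                label = malignancyLabels(mal),
                                row.names = NULL),
                     file.path(out_dir, "malignancy.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(cell = names(allClusters),
                                cluster = allClusters,
                                cell_type = cellType[names(allClusters)],
                                row.names = NULL),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(scoreTab, file.path(out_dir, "signature_scores.csv"),
                     row.names = FALSE)
    if (length(deTabs))
      utils::write.csv(do.call(rbind, deTabs),
                       file.path(out_dir, "de_results.csv"),
                       row.names = FALSE)
    if (length(gseaTabs))
      utils::write.csv(do.call(rbind, gseaTabs),
                       file.path(out_dir, "gsea.csv"), row.names = FALSE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
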