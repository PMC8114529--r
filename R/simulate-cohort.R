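#' Configuration for a synthetic slice-culture cohort
#'
#' Defines the study conditions the generator emulates: a multi-patient
#' glioblastoma slice-culture experiment with vehicle, etoposide and
#' panobinostat slices, tumor cells carrying a chromosome 7 gain and
#' chromosome 10 loss, major microenvironment populations, ambient background,
#' tumor-myeloid doublets, and planted drug effects (proliferative-cell
#' depletion under etoposide; metallothionein induction and CD163+ macrophage
#' depletion under panobinostat).
#'
#' @param n_patients number of patients.
#' @param slices_per_patient named integer vector, slices per treatment arm
#'   for every patient.
#' @param cells_per_slice cells recovered per slice.
#' @param n_genes number of genes.
#' @param chromosome_map optional named character vector gene -> chromosome;
#'   by default genes are assigned round-robin to the 22 autosomes (a small
#'   trailing block is reserved as mitochondrial).
#' @param celltype_proportions named proportions over tumor, myeloid,
#'   oligodendrocyte, tcell, endothelial, pericyte; must sum to 1.
#' @param tumor_fraction convenience alias for
#'   \code{celltype_proportions["tumor"]}; must agree with it.
#' @param chr7_gain_factor,chr10_loss_factor multiplicative expression factors
#'   applied to chromosome 7 / 10 genes of transformed cells (copy numbers 3
#'   and 1 on the expression scale).
#' @param depth_mean,depth_dispersion mean UMIs per cell and lognormal sdlog
#'   of per-cell depth.
#' @param ambient_fraction fraction of each cell's molecules swapped into the
#'   slice-wide pseudobulk profile.
#' @param doublet_rate fraction of cells that are tumor-myeloid doublets.
#' @param effect_sizes named list: \code{proliferative_depletion} (fraction of
#'   proliferative tumor cells lost under etoposide), \code{mt_log2fc}
#'   (metallothionein log2 induction under panobinostat, all cell types),
#'   \code{cd163_depletion} (fraction of CD163+ myeloid lost under
#'   panobinostat).
#' @param program_sizes named integer vector of gene-program block sizes.
#' @param baseline_sdlog lognormal spread of per-gene baseline expression
#'   (sdlog; smaller values spread expression more evenly across genes,
#'   tightening per-chromosome averages).
#' @param dispersion_shape Gamma shape of the per-cell-per-gene
#'   over-dispersion (mean 1; larger is closer to Poisson).
#' @param proliferative_fraction baseline fraction of tumor cells in the
#'   proliferative program.
#' @param cd163_fraction baseline CD163+ fraction of myeloid cells.
#' @param stress_fraction fraction of cells with a dissociation-stress program.
#' @param seed master seed; all randomness derives from it.
#'
#' @return a validated list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(n_patients = 6L,
                         slices_per_patient = c(vehicle = 2L, etoposide = 1L,
                                                panobinostat = 1L),
                         cells_per_slice = 210L,
                         n_genes = 1000L,
                         chromosome_map = NULL,
                         celltype_proportions = c(tumor = 0.50, myeloid = 0.20,
                                                  oligodendrocyte = 0.14,
                                                  tcell = 0.06,
                                                  endothelial = 0.05,
                                                  pericyte = 0.05),
                         tumor_fraction = unname(celltype_proportions["tumor"]),
                         chr7_gain_factor = 1.5,
                         chr10_loss_factor = 0.5,
                         depth_mean = 1500,
                         depth_dispersion = 0.35,
                         ambient_fraction = 0.05,
                         doublet_rate = 0.02,
                         effect_sizes = list(proliferative_depletion = 0.9,
                                             mt_log2fc = 2,
                                             cd163_depletion = 0.6),
                         program_sizes = NULL,
                         baseline_sdlog = 0.4,
                         dispersion_shape = 15,
                         proliferative_fraction = 0.2,
                         cd163_fraction = 0.5,
                         stress_fraction = 0.1,
                         seed = 1L) {
  if (is.null(program_sizes)) {
    # block sizes proportional to the genome size (fractions of n_genes)
    fr <- c(markers = 0.04, proliferation = 0.04, metallothionein = 0.02,
            cd163_program = 0.04, housekeeping = 0.06, stress = 0.04,
            state = 0.03, mitochondrial = 0.01)
    program_sizes <- stats::setNames(pmax(4L, as.integer(round(fr * n_genes))),
                                     names(fr))
  }
  cfg <- list(n_patients = as.integer(n_patients),
              slices_per_patient = slices_per_patient,
              cells_per_slice = as.integer(cells_per_slice),
              n_genes = as.integer(n_genes),
              chromosome_map = chromosome_map,
              celltype_proportions = celltype_proportions,
              tumor_fraction = tumor_fraction,
              chr7_gain_factor = chr7_gain_factor,
              chr10_loss_factor = chr10_loss_factor,
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              ambient_fraction = ambient_fraction,
              doublet_rate = doublet_rate,
              effect_sizes = effect_sizes,
              program_sizes = program_sizes,
              baseline_sdlog = baseline_sdlog,
              dispersion_shape = dispersion_shape,
              proliferative_fraction = proliferative_fraction,
              cd163_fraction = cd163_fraction,
              stress_fraction = stress_fraction,
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' Validate a CohortConfig
#' @param config a \code{CohortConfig}.
#' @return invisibly \code{TRUE}; stops on an invalid configuration.
#' @export
validateCohortConfig <- function(config) {
  p <- config$celltype_proportions
  if (abs(sum(p) - 1) > 1e-9)
    stop("celltype_proportions must sum to 1")
  if (any(p < 0)) stop("celltype_proportions must be non-negative")
  need <- c("tumor", "myeloid", "oligodendrocyte", "tcell", "endothelial",
            "pericyte")
  if (!all(need %in% names(p)))
    stop("celltype_proportions must cover: ", paste(need, collapse = ", "))
  if (abs(config$tumor_fraction - p[["tumor"]]) > 1e-9)
    stop("tumor_fraction must equal celltype_proportions['tumor']")
  if (config$chr7_gain_factor <= 0 || config$chr10_loss_factor <= 0)
    stop("chromosome expression factors must be positive")
  if (config$chr10_loss_factor >= 1 && config$chr10_loss_factor != 1)
    warning("chr10_loss_factor >= 1 models no loss")
  if (config$ambient_fraction < 0 || config$ambient_fraction >= 1)
    stop("ambient_fraction must be in [0, 1)")
  if (config$doublet_rate < 0 || config$doublet_rate >= 1)
    stop("doublet_rate must be in [0, 1)")
  if (config$depth_mean <= 0 || config$depth_dispersion <= 0)
    stop("depth parameters must be positive")
  if (!is.null(config$chromosome_map)) {
    if (length(config$chromosome_map) < config$n_genes)
      stop("chromosome_map must cover all genes")
  }
  invisible(TRUE)
}

# disjoint gene-program blocks with named roles; returns GeneAnnotation plus
# per-gene program table
.buildGenePrograms <- function(config) {
  ng <- config$n_genes
  ps <- config$program_sizes
  types <- c("tumor", "myeloid", "oligodendrocyte", "tcell", "endothelial",
             "pericyte")
  states <- c("OPC", "NPC", "AC", "MES")
  blocks <- c(stats::setNames(rep(ps[["markers"]], 6),
                              paste0("markers_", types)),
              proliferation = ps[["proliferation"]],
              metallothionein = ps[["metallothionein"]],
              cd163_program = ps[["cd163_program"]],
              housekeeping = ps[["housekeeping"]],
              stress = ps[["stress"]],
              stats::setNames(rep(ps[["state"]], 4), paste0("state_", states)),
              mitochondrial = ps[["mitochondrial"]])
  if (sum(blocks) > ng)
    stop("program blocks exceed n_genes; enlarge n_genes or shrink programs")
  genes <- sprintf("G%04d", seq_len(ng))
  program <- rep("background", ng)
  at <- 1L
  for (b in names(blocks)) {
    program[at:(at + blocks[[b]] - 1L)] <- b
    at <- at + blocks[[b]]
  }
  if (is.null(config$chromosome_map)) {
    # background genes cover all 22 autosomes round-robin; program genes go
    # round-robin to autosomes other than 7 and 10, so the aneuploid
    # chromosomes carry only baseline genes and chromosome averages track
    # copy number rather than lineage/drug programs
    chrom <- character(ng)
    bg <- program == "background"
    chrom[bg] <- as.character(rep_len(1:22, sum(bg)))
    chrom[!bg] <- as.character(rep_len(setdiff(1:22, c(7, 10)), sum(!bg)))
    chrom[program == "mitochondrial"] <- "MT"
  } else {
    chrom <- as.character(config$chromosome_map[genes])
    if (anyNA(chrom)) stop("chromosome_map missing genes")
  }
  panels <- split(genes, program)
  panels$background <- NULL
  panels$housekeeping_ribosomal <- panels$housekeeping
  ann <- GeneAnnotation(genes, chromosome = chrom, panels = panels)
  list(annotation = ann,
       genes = data.frame(gene = genes, program = program, chromosome = chrom,
                          stringsAsFactors = FALSE))
}

# per-cell-type mean expression profiles (genes x types), before per-cell flags
.typeProfiles <- function(baseline, truthGenes, config) {
  types <- c("tumor", "myeloid", "oligodendrocyte", "tcell", "endothelial",
             "pericyte")
  prog <- truthGenes$program
  prof <- matrix(rep(baseline, length(types)), ncol = length(types),
                 dimnames = list(truthGenes$gene, types))
  for (t in types) {
    own <- prog == paste0("markers_", t)
    other <- startsWith(prog, "markers_") & !own
    prof[own, t] <- prof[own, t] * 10
    prof[other, t] <- prof[other, t] * 0.05
  }
  # programs silent unless switched on per cell
  prof[prog == "proliferation", ] <- prof[prog == "proliferation", ] * 0.05
  prof[prog == "cd163_program", ] <- prof[prog == "cd163_program", ] * 0.05
  prof[prog %in% paste0("state_", c("OPC", "NPC", "AC", "MES")), ] <-
    prof[prog %in% paste0("state_", c("OPC", "NPC", "AC", "MES")), ] * 0.3
  prof[prog == "metallothionein", ] <- prof[prog == "metallothionein", ] * 0.5
  prof[prog == "housekeeping", ] <- prof[prog == "housekeeping", ] * 5
  prof[prog == "mitochondrial", ] <- prof[prog == "mitochondrial", ] * 3
  prof
}

#' Generate a synthetic multi-patient slice-culture cohort
#'
#' Draws UMI counts from a Gamma-Poisson hierarchy: each cell type has a mean
#' expression program; transformed (tumor) cells have chromosome 7 genes scaled
#' by \code{chr7_gain_factor} and chromosome 10 genes by
#' \code{chr10_loss_factor}; per-cell depth is lognormal; an
#' \code{ambient_fraction} of each cell's molecules is swapped into the
#' slice-wide pseudobulk; doublet cells mix a tumor and a myeloid parent
#' profile; planted drug effects apply only to treated slices.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed overrides \code{config$seed} when given.
#'
#' @return list with elements \code{slices} (list of
#'   \code{SingleCellExperiment}, genes x cells, with per-cell metadata in
#'   \code{colData}), \code{annotation} (a \linkS4class{GeneAnnotation}),
#'   and \code{truth} (list of \code{cells}, \code{genes}, \code{patients}
#'   ground-truth tables).
#' @examples
#' cohort <- generateCohort(cohortConfig(n_patients = 2, cells_per_slice = 50,
#'                                       n_genes = 300, seed = 7))
#' length(cohort$slices)
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @export
generateCohort <- function(config = cohortConfig(), seed = config$seed) {
  validateCohortConfig(config)
  gp <- .buildGenePrograms(config)
  ann <- gp$annotation
  truthGenes <- gp$genes
  ng <- config$n_genes
  types <- names(config$celltype_proportions)
  states <- c("OPC", "NPC", "AC", "MES")
  es <- config$effect_sizes

  design <- expand.grid(treatment = names(config$slices_per_patient),
                        patient = sprintf("P%02d", seq_len(config$n_patients)),
                        stringsAsFactors = FALSE)
  design <- design[rep(seq_len(nrow(design)),
                       config$slices_per_patient[design$treatment]), ]
  design <- design[order(design$patient, design$treatment), ]
  design$slice <- sprintf("%s_%s_%d", design$patient, design$treatment,
                          stats::ave(seq_len(nrow(design)),
                                     paste(design$patient, design$treatment),
                                     FUN = seq_along))
  rownames(design) <- NULL

  out <- .withSeed(.childSeed(seed, "cohort"), {
    baseline <- stats::rlnorm(ng, meanlog = 0, sdlog = config$baseline_sdlog)
    prof <- .typeProfiles(baseline, truthGenes, config)
    prog <- truthGenes$program
    chr7 <- truthGenes$chromosome == "7"
    chr10 <- truthGenes$chromosome == "10"
    slices <- vector("list", nrow(design))
    cellTruth <- vector("list", nrow(design))
    for (s in seq_len(nrow(design))) {
      nc <- config$cells_per_slice
      trt <- design$treatment[s]
      ct <- sample(types, nc, replace = TRUE,
                   prob = config$celltype_proportions)
      doublet <- stats::runif(nc) < config$doublet_rate
      ct[doublet] <- "doublet"
      pProlif <- config$proliferative_fraction *
        (if (trt == "etoposide") 1 - es$proliferative_depletion else 1)
      pCd163 <- config$cd163_fraction *
        (if (trt == "panobinostat") 1 - es$cd163_depletion else 1)
      proliferative <- ct == "tumor" & stats::runif(nc) < pProlif
      cd163 <- ct == "myeloid" & stats::runif(nc) < pCd163
      state <- ifelse(ct == "tumor", sample(states, nc, replace = TRUE),
                      NA_character_)
      stressed <- stats::runif(nc) < config$stress_fraction
      depth <- pmax(50L, as.integer(round(stats::rlnorm(
        nc, meanlog = log(config$depth_mean) - config$depth_dispersion^2 / 2,
        sdlog = config$depth_dispersion))))

      rates <- matrix(0, ng, nc)
      for (i in seq_len(nc)) {
        if (ct[i] == "doublet") {
          r <- (prof[, "tumor"] + prof[, "myeloid"]) / 2
          r[chr7] <- r[chr7] * (1 + config$chr7_gain_factor) / 2
          r[chr10] <- r[chr10] * (1 + config$chr10_loss_factor) / 2
        } else {
          r <- prof[, ct[i]]
          if (ct[i] == "tumor") {
            r[chr7] <- r[chr7] * config$chr7_gain_factor
            r[chr10] <- r[chr10] * config$chr10_loss_factor
            sset <- prog == paste0("state_", state[i])
            r[sset] <- r[sset] * 6
          }
        }
        if (proliferative[i]) r[prog == "proliferation"] <-
            r[prog == "proliferation"] * 200
        if (cd163[i]) r[prog == "cd163_program"] <-
            r[prog == "cd163_program"] * 200
        if (stressed[i]) r[prog == "stress"] <- r[prog == "stress"] * 8
        if (trt == "panobinostat") r[prog == "metallothionein"] <-
            r[prog == "metallothionein"] * 2^es$mt_log2fc
        rates[, i] <- r
      }
      # Gamma-Poisson over-dispersion, then multinomial at the sampled depth
      rates <- rates * matrix(stats::rgamma(ng * nc,
                                            shape = config$dispersion_shape,
                                            rate = config$dispersion_shape),
                              ng, nc)
      counts <- matrix(0L, ng, nc)
      for (i in seq_len(nc))
        counts[, i] <- stats::rmultinom(1, depth[i], rates[, i])[, 1]
      # ambient swap into the slice pseudobulk (molecules reassigned, not added)
      if (config$ambient_fraction > 0) {
        pseudo <- rowSums(counts)
        for (i in seq_len(nc)) {
          namb <- stats::rbinom(1, depth[i], config$ambient_fraction)
          if (namb == 0) next
          own <- rep.int(seq_len(ng), counts[, i])
          drop <- tabulate(own[sample.int(length(own), namb)], nbins = ng)
          counts[, i] <- counts[, i] - drop +
            stats::rmultinom(1, namb, pseudo)[, 1]
        }
      }
      dimnames(counts) <- list(truthGenes$gene,
                               sprintf("%s_c%04d", design$slice[s],
                                       seq_len(nc)))
      cd <- S4Vectors::DataFrame(
        barcode = colnames(counts), slice = design$slice[s],
        patient = design$patient[s], treatment = trt,
        cell_type = ct, transformed = ct %in% c("tumor"),
        doublet = doublet, proliferative = proliferative,
        cd163_pos = cd163, state = state, stressed = stressed,
        depth = depth)
      slices[[s]] <- SingleCellExperiment(
        assays = list(counts = methods::as(counts, "CsparseMatrix")),
        colData = cd)
      cellTruth[[s]] <- as.data.frame(cd)
    }
    list(slices = slices, cellTruth = do.call(rbind, cellTruth))
  })
  names(out$slices) <- design$slice
  cellTruth <- out$cellTruth
  rownames(cellTruth) <- cellTruth$barcode
  stopifnot(!anyDuplicated(cellTruth$barcode))
  patients <- data.frame(patient = unique(design$patient),
                         chr7_copies = 2 * config$chr7_gain_factor,
                         chr10_copies = 2 * config$chr10_loss_factor)
  list(slices = out$slices, annotation = ann,
       truth = list(cells = cellTruth, genes = truthGenes,
                    patients = patients),
       design = design, config = config)
}

#' Merge cohort slices into one SingleCellExperiment
#' @param cohort result of \code{\link{generateCohort}} or a list of
#'   \code{SingleCellExperiment} objects sharing rownames.
#' @return a single \code{SingleCellExperiment}.
#' @export
mergeSlices <- function(cohort) {
  slices <- if (is.list(cohort) && !is.null(cohort$slices)) cohort$slices
            else cohort
  do.call(cbind, unname(slices))
}
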