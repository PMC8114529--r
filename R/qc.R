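## Barcode-level quality control: UMI address collapse with directed
## Hamming-1 error correction, ambient-aware cell calling, and the four
## per-sample barcode-removal criteria.

# all Hamming-1 neighbors of a fixed-length ACGT string
.hamming1 <- function(s) {
  n <- nchar(s)
  out <- character(3 * n)
  k <- 0L
  for (pos in seq_len(n)) {
    old <- substr(s, pos, pos)
    for (b in setdiff(c("A", "C", "G", "T"), old)) {
      k <- k + 1L
      v <- s
      substr(v, pos, pos) <- b
      out[k] <- v
    }
  }
  out[seq_len(k)]
}

# directed Hamming-1 merge: each sequence maps to itself or to a neighbor
# with a higher count (ties broken toward the lexicographically smaller
# sequence); chains resolved transitively
.directedMerge <- function(seqs, counts) {
  stopifnot(length(seqs) == length(counts))
  target <- stats::setNames(seqs, seqs)
  cnt <- stats::setNames(counts, seqs)
  ord <- order(counts, seqs)            # low counts first
  for (s in seqs[ord]) {
    nb <- .hamming1(s)
    nb <- nb[nb %in% seqs]
    if (!length(nb)) next
    better <- nb[cnt[nb] > cnt[s] | (cnt[nb] == cnt[s] & nb < s)]
    if (!length(better)) next
    best <- better[order(-cnt[better], better)][1]
    target[s] <- best
  }
  # resolve chains
  repeat {
    nxt <- target[target]
    names(nxt) <- names(target)
    if (identical(unname(nxt), unname(target))) break
    target <- nxt
  }
  target
}

#' Collapse read addresses into molecules
#'
#' Reads sharing the same (cell barcode, UMI, gene) address are collapsed
#' into one molecule; sequencing errors are corrected by absorbing a
#' low-count cell barcode (and, within each cell/gene pair, a low-count UMI)
#' into a higher-count sequence at Hamming distance 1 (count ties broken
#' lexicographically). The gene identifier is part of the address, so the
#' same barcode/UMI on two genes yields two molecules.
#'
#' @param reads data.frame with columns \code{cb}, \code{umi}, \code{gene}.
#'   Records with characters outside A/C/G/T are rejected with a warning.
#' @return list: \code{molecules} (data.frame cb, umi, gene, reads),
#'   \code{matrix} (sparse barcode x gene molecule counts).
#' @examples
#' reads <- data.frame(cb = "AAAA", umi = c("CCCC", "CCCC", "CCCG"),
#'                     gene = "G1")
#' collapseAddresses(reads)$molecules
#' @export
collapseAddresses <- function(reads) {
  ok <- grepl("^[ACGT]+$", reads$cb) & grepl("^[ACGT]+$", reads$umi)
  if (!all(ok)) {
    warning(sum(!ok), " read(s) with malformed barcode characters rejected")
    reads <- reads[ok, , drop = FALSE]
  }
  if (!nrow(reads)) stop("no valid reads")
  if (length(unique(nchar(reads$cb))) != 1 ||
      length(unique(nchar(reads$umi))) != 1)
    stop("barcodes and UMIs must be fixed-length")
  # correct cell barcodes by total read count
  cbCount <- table(reads$cb)
  cbMap <- .directedMerge(names(cbCount), as.integer(cbCount))
  reads$cb <- unname(cbMap[reads$cb])
  # collapse identical triplets, then correct UMIs within (cb, gene)
  key <- paste(reads$cb, reads$umi, reads$gene, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  mol <- data.frame(cb = parts[, 1], umi = parts[, 2], gene = parts[, 3],
                    reads = as.integer(tab), stringsAsFactors = FALSE)
  grp <- paste(mol$cb, mol$gene, sep = "\r")
  pieces <- split(seq_len(nrow(mol)), grp)
  for (idx in pieces) {
    if (length(idx) == 1) next
    map <- .directedMerge(mol$umi[idx], mol$reads[idx])
    mol$umi[idx] <- unname(map[mol$umi[idx]])
  }
  agg <- stats::aggregate(reads ~ cb + umi + gene, data = mol, FUN = sum)
  agg <- agg[order(agg$cb, agg$gene, agg$umi), , drop = FALSE]
  rownames(agg) <- NULL
  bc <- sort(unique(agg$cb)); gn <- sort(unique(agg$gene))
  mat <- Matrix::sparseMatrix(i = match(agg$cb, bc),
                              j = match(agg$gene, gn),
                              x = 1, dims = c(length(bc), length(gn)),
                              dimnames = list(bc, gn))
  list(molecules = agg, matrix = mat)
}

#' Ambient-aware cell calling
#'
#' A simplified ambient-profile cell caller: barcodes above a knee-derived
#' coverage bound are always called cells; barcodes below a low-count bound
#' form the ambient multinomial profile; mid-range barcodes are tested
#' against that profile by Monte-Carlo multinomial deviance with
#' Benjamini-Hochberg control at \code{fdr}.
#'
#' @param mat barcode x gene molecule count matrix (barcodes in rows).
#' @param n_expected_range integer(2), plausible range of true cell numbers
#'   (the lower end anchors the knee).
#' @param fdr false discovery rate for mid-range barcodes; \code{fdr = 0}
#'   calls only knee barcodes.
#' @param ambient_bound barcodes with at most this many molecules define the
#'   ambient profile.
#' @param n_mc Monte-Carlo draws per tested barcode.
#' @param known_cells optional barcode vector bypassing the caller.
#' @param seed seed for the Monte-Carlo draws.
#' @return list: \code{calls} (named character, "cell"/"ambient"),
#'   \code{coverage} (molecules per barcode), \code{ambient_profile},
#'   \code{knee_bound}.
#' @export
callCells <- function(mat, n_expected_range = c(50L, 5000L), fdr = 0.01,
                      ambient_bound = 25, n_mc = 500L, known_cells = NULL,
                      seed = 1L) {
  cov <- Matrix::rowSums(mat)
  if (!is.null(known_cells)) {
    calls <- ifelse(rownames(mat) %in% known_cells, "cell", "ambient")
    return(list(calls = stats::setNames(calls, rownames(mat)),
                coverage = cov, ambient_profile = NULL, knee_bound = NA))
  }
  if (nrow(mat) < 100) stop("need at least 100 barcodes to call cells")
  if (max(cov) == min(cov))
    stop("degenerate input: all barcodes have identical coverage")
  srt <- sort(cov, decreasing = TRUE)
  nExp <- min(n_expected_range[1], length(srt))
  kneeBound <- max(stats::quantile(srt[seq_len(nExp)], 0.99) / 10,
                   ambient_bound + 1)
  low <- cov <= ambient_bound
  if (sum(low) < 10)
    stop("too few low-count barcodes to form an ambient profile")
  amb <- Matrix::colSums(mat[low, , drop = FALSE])
  p <- (amb + 1 / ncol(mat)) / sum(amb + 1 / ncol(mat))
  calls <- ifelse(cov >= kneeBound, "cell", "ambient")
  mid <- which(cov > ambient_bound & cov < kneeBound)
  if (length(mid) && fdr > 0) {
    pvals <- .withSeed(.childSeed(seed, "callcells"), {
      vapply(mid, function(b) {
        x <- mat[b, ]
        t <- cov[b]
        obs <- 2 * sum(ifelse(x > 0, x * log(x / (t * p)), 0))
        sims <- stats::rmultinom(n_mc, t, p)
        e <- t * p
        devs <- 2 * Matrix::colSums(sims * log(pmax(sims, 1) / e) *
                                      (sims > 0))
        (1 + sum(devs >= obs)) / (n_mc + 1)
      }, numeric(1))
    })
    q <- stats::p.adjust(pvals, method = "BH")
    calls[mid[q <= fdr]] <- "cell"
  }
  list(calls = stats::setNames(calls, rownames(mat)), coverage = cov,
       ambient_profile = p, knee_bound = unname(kneeBound))
}

#' Per-barcode quality-control statistics
#'
#' Computes, for each barcode of one sample, the statistics behind the four
#' barcode-removal criteria: mitochondrial fraction, gene-body/exon molecule
#' ratio (only when intron-aware annotation is supplied), mean reads per
#' molecule, mean molecules per gene, the fraction of UMI bases that are T,
#' and the mean number of T bases per UMI.
#'
#' @param molecules data.frame from \code{\link{collapseAddresses}} (columns
#'   cb, umi, gene, reads).
#' @param annotation \linkS4class{GeneAnnotation} with a
#'   \code{"mitochondrial"} panel.
#' @param genebody_exon_ratio optional named numeric per barcode (requires
#'   intron-aware upstream quantification); \code{NA} otherwise.
#' @return data.frame, one row per barcode.
#' @export
computeBarcodeQC <- function(molecules, annotation,
                             genebody_exon_ratio = NULL) {
  if (!"mitochondrial" %in% panelNames(annotation))
    stop("annotation lacks a 'mitochondrial' panel")
  mito <- genePanel(annotation, "mitochondrial")
  bc <- sort(unique(molecules$cb))
  idx <- split(seq_len(nrow(molecules)), molecules$cb)[bc]
  tcount <- vapply(gregexpr("T", molecules$umi, fixed = TRUE),
                   function(m) sum(m > 0), numeric(1))
  umiLen <- nchar(molecules$umi[1])
  stats <- do.call(rbind, lapply(bc, function(b) {
    i <- idx[[b]]
    nm <- length(i)
    data.frame(
      barcode = b,
      total_molecules = nm,
      total_reads = sum(molecules$reads[i]),
      mito_fraction = mean(molecules$gene[i] %in% mito),
      genebody_exon_ratio = if (is.null(genebody_exon_ratio)) NA_real_
                            else unname(genebody_exon_ratio[b]),
      mean_reads_per_molecule = mean(molecules$reads[i]),
      mean_molecules_per_gene = nm / length(unique(molecules$gene[i])),
      frac_T_in_UMIs = sum(tcount[i]) / (nm * umiLen),
      mean_T_per_UMI = mean(tcount[i]),
      stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  stats
}

#' Apply the four barcode-removal criteria
#'
#' A barcode is removed iff it satisfies at least one criterion, with
#' per-sample cutoffs computed once over all supplied barcodes (population
#' SD, no iteration): (1) mitochondrial fraction strictly greater than
#' 1.96 SD above the mean; (2) gene-body/exon ratio strictly greater than
#' 1.96 SD above the mean (skipped with a message when the ratio is
#' unavailable); (3) mean reads per molecule or mean molecules per gene
#' strictly greater than 2.5 SD above the mean; (4) more than 40% of UMI
#' bases are T, or the mean number of T bases per UMI is at least 4.
#'
#' @param stats data.frame from \code{\link{computeBarcodeQC}} for one sample.
#' @return list: \code{kept} (barcodes), \code{removed} (data.frame barcode,
#'   reasons), \code{cutoffs}.
#' @export
filterBarcodes <- function(stats) {
  if (nrow(stats) < 3)
    stop("degenerate input: need at least 3 barcodes for SD-based cutoffs")
  cut1 <- mean(stats$mito_fraction) + 1.96 * .popSD(stats$mito_fraction)
  r1 <- stats$mito_fraction > cut1
  if (all(is.na(stats$genebody_exon_ratio))) {
    message("gene-body/exon ratio unavailable; criterion (2) skipped")
    r2 <- rep(FALSE, nrow(stats)); cut2 <- NA_real_
  } else {
    g <- stats$genebody_exon_ratio
    cut2 <- mean(g) + 1.96 * .popSD(g)
    r2 <- !is.na(g) & g > cut2
  }
  cut3a <- mean(stats$mean_reads_per_molecule) +
    2.5 * .popSD(stats$mean_reads_per_molecule)
  cut3b <- mean(stats$mean_molecules_per_gene) +
    2.5 * .popSD(stats$mean_molecules_per_gene)
  r3 <- stats$mean_reads_per_molecule > cut3a |
    stats$mean_molecules_per_gene > cut3b
  r4 <- stats$frac_T_in_UMIs > 0.4 | stats$mean_T_per_UMI >= 4
  reasons <- cbind(mito = r1, genebody = r2, reads_or_genes = r3, polyT = r4)
  removed <- rowSums(reasons) > 0
  list(kept = stats$barcode[!removed],
       removed = data.frame(
         barcode = stats$barcode[removed],
         reasons = apply(reasons[removed, , drop = FALSE], 1, function(z)
           paste(colnames(reasons)[z], collapse = "+")),
         stringsAsFactors = FALSE),
       cutoffs = c(mito = cut1, genebody = cut2,
                   reads_per_molecule = cut3a, molecules_per_gene = cut3b))
}

#' Compare cell vs ambient coverage across treatment groups
#'
#' For each slice, computes the median coverage of barcodes called cells and
#' of those called ambient, and their ratio; treated and vehicle ratios are
#' compared with a two-sided rank-sum test (elevated ambient background under
#' drug treatment would lower the treated ratios).
#'
#' @param cellCalls named list of \code{\link{callCells}} results, one per
#'   slice.
#' @param treatments named character, slice -> treatment ("vehicle" or drug).
#' @return list: \code{per_slice} summary data.frame, \code{p_value}.
#' @export
ambientCoverageComparison <- function(cellCalls, treatments) {
  per <- do.call(rbind, lapply(names(cellCalls), function(s) {
    cc <- cellCalls[[s]]
    isCell <- cc$calls == "cell"
    medC <- if (any(isCell)) stats::median(cc$coverage[isCell]) else NA_real_
    medA <- if (any(!isCell)) stats::median(cc$coverage[!isCell]) else NA_real_
    data.frame(slice = s, treatment = unname(treatments[s]),
               median_cell = medC, median_ambient = medA,
               ratio = medC / medA, stringsAsFactors = FALSE)
  }))
  bad <- !is.finite(per$ratio)
  if (any(bad)) {
    warning("slice(s) without ambient barcodes excluded: ",
            paste(per$slice[bad], collapse = ", "))
    per$flagged <- bad
  }
  ok <- per[!bad, , drop = FALSE]
  veh <- ok$ratio[ok$treatment == "vehicle"]
  trt <- ok$ratio[ok$treatment != "vehicle"]
  if (!length(veh) || !length(trt))
    stop("need at least one slice in each of the vehicle and treated groups")
  p <- stats::wilcox.test(trt, veh, exact = FALSE)$p.value
  list(per_slice = per, p_value = p)
}
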