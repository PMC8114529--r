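#' Simulate per-chromosome WGS de-duplicated read counts
#'
#' Tumor reads are multinomial with probabilities proportional to
#' chromosome_length x copy_number / 2; the diploid germline uses copy number
#' 2 everywhere.
#'
#' @param copy_numbers named numeric, chromosome -> copy number (> 0).
#' @param total_reads reads per sample.
#' @param chromosome_lengths named numeric; defaults to equal lengths.
#' @param seed integer seed.
#' @return data.frame with chromosome, tumor and germline read counts.
#' @examples
#' simulateWgsCounts(c("7" = 3, "10" = 1, "1" = 2, "2" = 2), 1e5, seed = 1)
#' @export
simulateWgsCounts <- function(copy_numbers, total_reads,
                              chromosome_lengths = NULL, seed = 1L) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (any(copy_numbers <= 0)) stop("copy numbers must be positive")
  chroms <- names(copy_numbers)
  if (is.null(chromosome_lengths))
    chromosome_lengths <- stats::setNames(rep(1, length(chroms)), chroms)
  len <- chromosome_lengths[chroms]
  .withSeed(.childSeed(seed, "wgs"), {
    pT <- len * copy_numbers / 2; pT <- pT / sum(pT)
    pG <- len / sum(len)
    data.frame(chromosome = chroms,
               tumor = stats::rmultinom(1, total_reads, pT)[, 1],
               germline = stats::rmultinom(1, total_reads, pG)[, 1],
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Simulate a per-nucleus intensity table
#'
#' Intensities are drawn from a two-component Gaussian mixture (fluorescence
#' background vs probe-positive nuclei); truth labels are recorded so that
#' threshold recovery can be scored.
#'
#' @param n_nuclei number of nuclei.
#' @param positive_fraction fraction of probe-positive nuclei, in [0, 1].
#' @param mu_bg,sd_bg background intensity mean / SD.
#' @param mu_pos,sd_pos positive-component mean / SD (\code{mu_pos > mu_bg}
#'   unless deliberately degenerate).
#' @param area_meanlog,area_sdlog lognormal nuclear area (um^2) parameters.
#' @param condition label stored in the table (e.g. "vehicle").
#' @param seed integer seed.
#' @return data.frame: mask_id, area_um2, mean_intensity, field, condition,
#'   true_positive.
#' @export
simulateNucleusTable <- function(n_nuclei, positive_fraction,
                                 mu_bg = 100, sd_bg = 20,
                                 mu_pos = 400, sd_pos = 50,
                                 area_meanlog = log(30), area_sdlog = 0.5,
                                 condition = "vehicle", seed = 1L) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must be in [0, 1]")
  if (sd_bg <= 0 || sd_pos <= 0) stop("component SDs must be positive")
  .withSeed(.childSeed(seed, "nuclei"), {
    pos <- stats::runif(n_nuclei) < positive_fraction
    intensity <- ifelse(pos, stats::rnorm(n_nuclei, mu_pos, sd_pos),
                        stats::rnorm(n_nuclei, mu_bg, sd_bg))
    data.frame(mask_id = seq_len(n_nuclei),
               area_um2 = stats::rlnorm(n_nuclei, area_meanlog, area_sdlog),
               mean_intensity = pmax(0, intensity),
               field = 1L + (seq_len(n_nuclei) - 1L) %% 5L,
               condition = condition,
               true_positive = pos,
               stringsAsFactors = FALSE)
  })
}

#' Simulate raw read addresses with sequencing errors
#'
#' Each molecule of a (cell barcode, UMI, gene) table emits one or more reads;
#' single-base substitutions are injected into the barcode or UMI at the given
#' per-read rate, emulating the raw addresses that UMI collapse must correct.
#'
#' @param molecule_table data.frame with columns \code{cb}, \code{umi},
#'   \code{gene} (one row per distinct molecule) and optionally \code{count}.
#' @param error_rate probability that a read carries one substituted base.
#' @param reads_per_molecule mean of the (shifted Poisson) reads-per-molecule
#'   distribution; every molecule emits at least one read.
#' @param seed integer seed.
#' @return data.frame of reads: cb, umi, gene, true_molecule (row index into
#'   \code{molecule_table}).
#' @export
simulateReadAddresses <- function(molecule_table, error_rate = 0.01,
                                  reads_per_molecule = 3, seed = 1L) {
  stopifnot(all(c("cb", "umi", "gene") %in% names(molecule_table)))
  .withSeed(.childSeed(seed, "reads"), {
    nm <- nrow(molecule_table)
    nreads <- 1L + stats::rpois(nm, max(0, reads_per_molecule - 1))
    idx <- rep.int(seq_len(nm), nreads)
    cb <- molecule_table$cb[idx]
    umi <- molecule_table$umi[idx]
    err <- stats::runif(length(idx)) < error_rate
    for (j in which(err)) {
      inUmi <- stats::runif(1) < 0.5
      s <- if (inUmi) umi[j] else cb[j]
      pos <- sample.int(nchar(s), 1)
      old <- substr(s, pos, pos)
      substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      if (inUmi) umi[j] <- s else cb[j] <- s
    }
    data.frame(cb = cb, umi = umi, gene = molecule_table$gene[idx],
               true_molecule = idx, stringsAsFactors = FALSE)
  })
}

# random fixed-length DNA barcodes, unique
.randomBarcodes <- function(n, width) {
  out <- character(0)
  while (length(out) < n) {
    more <- vapply(seq_len(n - length(out)), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1))
    out <- unique(c(out, more))
  }
  out[seq_len(n)]
}
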