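#' Relative CpG enrichment (relH)
#'
#' Ratio of the CpG density inside sequenced fragment footprints to the
#' genome-wide CpG density. Footprints are counted per fragment, so
#' overlapping fragments contribute independently; a CpG counts toward a
#' footprint only when both bases lie inside it.
#'
#' @param fragments filtered fragment data.frame (chrom, start, end).
#' @param genome a [Biostrings::DNAStringSet] (or named character vector) of
#'   the reference sequences, or a precomputed list from [genome_cpg_stats()].
#' @return relH, a non-negative real; 1 means no enrichment.
#' @export
relH <- function(fragments, genome) {
  gs <- if (is.list(genome) && !is.null(genome$cpg_positions)) genome
        else genome_cpg_stats(genome)
  footprint <- sum(fragments$end - fragments$start)
  if (footprint <= 0) stop("zero footprint bases")
  n_cpg <- 0
  for (chrom in unique(fragments$chrom)) {
    pos <- gs$cpg_positions[[chrom]]        # 0-based C positions, sorted
    if (is.null(pos)) next
    fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
    # CpG fully inside [start, end): C position in [start, end - 2]
    n_cpg <- n_cpg + sum(findInterval(fr$end - 2L, pos) -
                         findInterval(fr$start - 1L, pos))
  }
  (n_cpg / footprint) / (gs$total_cpg / gs$total_length)
}

#' Genome-wide CpG statistics
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @return list with `total_length`, `total_cpg`, and per-chromosome sorted
#'   0-based CpG (C base) positions.
#' @export
genome_cpg_stats <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  stopifnot(inherits(genome, "DNAStringSet"), !is.null(names(genome)))
  pos <- lapply(seq_along(genome), function(i) {
    Biostrings::start(Biostrings::matchPattern("CG", genome[[i]],
                                               fixed = TRUE)) - 1L
  })
  names(pos) <- names(genome)
  list(total_length = sum(Biostrings::width(genome)),
       total_cpg = sum(lengths(pos)),
       cpg_positions = pos)
}

#' Hyperstable fraction
#'
#' Fraction of a designated always-hypermethylated window panel whose
#' beta-value reaches `beta_min`. Missing betas count as below threshold. Low
#' values indicate failed methylation enrichment.
#'
#' @param beta_row named numeric vector of per-window betas for one sample
#'   (names = window_id), or one column of a `BetaMatrix`.
#' @param panel integer vector of panel window_ids.
#' @param beta_min threshold (default 0.8, inclusive).
#' @return fraction in \[0, 1\].
#' @export
hyperstable_fraction <- function(beta_row, panel, beta_min = 0.8) {
  if (length(panel) == 0) stop("empty hyperstable panel")
  b <- beta_row[as.character(panel)]
  mean(!is.na(b) & b >= beta_min)
}

#' Gate samples on QC metrics
#'
#' A sample passes when `relH >= relH_min` and
#' `hyperstable_fraction >= hf_min`; values strictly below either threshold
#' fail ("below ... are excluded", so the boundary passes).
#'
#' @param qc data.frame with columns `sample_id`, `relH`,
#'   `hyperstable_fraction` (and optionally `n_valid_fragments`).
#' @param relH_min,hf_min thresholds (defaults 2.5 and 0.4).
#' @return the data.frame with a logical `pass` column.
#' @export
gate_samples <- function(qc, relH_min = 2.5, hf_min = 0.4) {
  stopifnot(all(c("sample_id", "relH", "hyperstable_fraction") %in% names(qc)))
  qc$pass <- qc$relH >= relH_min & qc$hyperstable_fraction >= hf_min
  qc
}

#' Compute the full QC report for a set of samples
#'
#' @param fragments named list of filtered per-sample fragment data.frames.
#' @param beta a `BetaMatrix` with matching sample columns.
#' @param panel hyperstable panel window_ids.
#' @param genome reference sequences or [genome_cpg_stats()] output.
#' @param relH_min,hf_min gating thresholds.
#' @return gated QC data.frame (one row per sample).
#' @export
qc_report <- function(fragments, beta, panel, genome,
                      relH_min = 2.5, hf_min = 0.4) {
  gs <- if (is.list(genome) && !is.null(genome$cpg_positions)) genome
        else genome_cpg_stats(genome)
  rows <- lapply(names(fragments), function(s) {
    data.frame(sample_id = s,
               relH = relH(fragments[[s]], gs),
               hyperstable_fraction =
                 hyperstable_fraction(beta[, s], panel),
               n_valid_fragments = nrow(fragments[[s]]),
               stringsAsFactors = FALSE)
  })
  gate_samples(do.call(rbind, rows), relH_min, hf_min)
}
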