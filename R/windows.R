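#' Tile a genome into fixed-width windows
#'
#' Partitions every chromosome into consecutive non-overlapping windows of
#' `window_size` bp (BED convention: 0-based, half-open). The last window of a
#' chromosome may be shorter. When a genome sequence is supplied, each window
#' is annotated with its CpG ("CG" dinucleotide, forward strand,
#' case-insensitive) count; a CpG is assigned to a window only when both bases
#' lie inside it, so dinucleotides straddling a window boundary belong to
#' neither window.
#'
#' @param genome either a [Biostrings::DNAStringSet] (or named character vector
#'   of sequences), or a named numeric vector of chromosome lengths. With bare
#'   lengths, CpG counts are set to 0 and the result is flagged
#'   (`attr(ws, "has_cpg") == FALSE`); density-dependent operations
#'   (calibration, beta estimation) refuse such window sets.
#' @param window_size window width in bp (default 300).
#' @return a `WindowSet`: a `data.frame` with columns `window_id` (0-based,
#'   contiguous), `chrom`, `start`, `end`, `cpg_count`, `masked`.
#' @export
tile_genome <- function(genome, window_size = 300) {
  if (window_size < 1) stop("window_size must be >= 1")
  has_seq <- FALSE
  if (inherits(genome, "DNAStringSet")) {
    has_seq <- TRUE
    lens <- Biostrings::width(genome)
    names(lens) <- names(genome)
  } else if (is.character(genome)) {
    has_seq <- TRUE
    genome <- Biostrings::DNAStringSet(toupper(genome))
    lens <- Biostrings::width(genome)
    names(lens) <- names(genome)
  } else if (is.numeric(genome)) {
    lens <- genome
  } else {
    stop("genome must be sequences or a named vector of chromosome lengths")
  }
  if (length(lens) == 0L) stop("empty genome")
  if (is.null(names(lens)) || any(!nzchar(names(lens)))) {
    stop("chromosomes must be named")
  }
  if (anyDuplicated(names(lens))) stop("duplicate chromosome names")
  if (any(lens < 1)) stop("chromosome lengths must be >= 1")

  per_chrom <- lapply(seq_along(lens), function(i) {
    L <- lens[[i]]
    starts <- seq.int(0L, L - 1L, by = window_size)
    ends <- pmin(starts + window_size, L)
    data.frame(chrom = names(lens)[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  ws <- do.call(rbind, per_chrom)
  ws <- data.frame(window_id = seq_len(nrow(ws)) - 1L, ws,
                   cpg_count = 0L, masked = FALSE, stringsAsFactors = FALSE)

  if (has_seq) {
    for (i in seq_along(genome)) {
      chrom <- names(genome)[i]
      hits <- Biostrings::start(Biostrings::matchPattern(
        "CG", genome[[i]], fixed = TRUE))
      if (length(hits) == 0L) next
      s0 <- hits - 1L                      # 0-based position of the C
      idx <- s0 %/% window_size            # window index within chromosome
      same <- idx == ((s0 + 1L) %/% window_size)  # G in the same window
      tab <- tabulate(idx[same] + 1L, nbins = ceiling(lens[[i]] / window_size))
      sel <- ws$chrom == chrom
      ws$cpg_count[sel] <- as.integer(tab)
    }
  }
  attr(ws, "window_size") <- as.integer(window_size)
  attr(ws, "has_cpg") <- has_seq
  class(ws) <- c("WindowSet", "data.frame")
  ws
}

#' Locate the window containing each genomic position
#'
#' @param windows a `WindowSet`.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return integer vector of `window_id`s (NA for positions outside the set).
#' @export
locate_window <- function(windows, chrom, pos) {
  wsz <- attr(windows, "window_size")
  info <- window_chrom_index(windows)
  m <- match(chrom, info$chrom)
  off <- info$first_id[m]
  nwin <- info$n_windows[m]
  len <- info$length[m]
  idx <- pos %/% wsz
  out <- off + idx
  out[is.na(m) | pos < 0 | pos >= len | idx >= nwin] <- NA_integer_
  as.integer(out)
}

# per-chromosome offsets, cached shape helper
window_chrom_index <- function(windows) {
  r <- rle(windows$chrom)
  first <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  data.frame(chrom = r$values,
             first_id = windows$window_id[first],
             n_windows = r$lengths,
             length = windows$end[first + r$lengths - 1L],
             stringsAsFactors = FALSE)
}

#' Identify over-represented windows from pooled control counts
#'
#' Flags windows whose pooled fragment count reaches the empirical 99.9th
#' percentile (primary mask), plus genomically adjacent windows (same
#' chromosome, window_id +/- 1) reaching the 99th percentile (adjacent mask).
#' Quantiles are type-7 order statistics. When the 99.9th percentile equals
#' the median (degenerate, near-uniform counts) nothing is masked: the rule
#' targets outliers, not ties. The adjacency rule does not cascade.
#'
#' @param windows a `WindowSet`.
#' @param counts numeric vector of pooled per-window fragment counts, aligned
#'   to `windows`.
#' @param q_primary,q_adjacent quantile levels (defaults 0.999 and 0.99).
#' @return a `MaskReport` list: `primary_masked`, `adjacent_masked` (window_id
#'   vectors), `q999`, `q99`.
#' @export
find_overrepresented <- function(windows, counts,
                                 q_primary = 0.999, q_adjacent = 0.99) {
  stopifnot(length(counts) == nrow(windows))
  if (all(counts == 0)) {
    warning("all pooled counts are zero; empty mask")
    rep_ <- list(primary_masked = integer(0), adjacent_masked = integer(0),
                 q999 = 0, q99 = 0)
    class(rep_) <- "MaskReport"
    return(rep_)
  }
  q999 <- unname(stats::quantile(counts, q_primary, type = 7))
  q99 <- unname(stats::quantile(counts, q_adjacent, type = 7))
  if (q999 == stats::median(counts)) {
    rep_ <- list(primary_masked = integer(0), adjacent_masked = integer(0),
                 q999 = q999, q99 = q99)
    class(rep_) <- "MaskReport"
    return(rep_)
  }
  primary <- windows$window_id[counts >= q999]
  adj <- integer(0)
  if (length(primary)) {
    cand <- unique(c(primary - 1L, primary + 1L))
    cand <- setdiff(cand, primary)
    keep <- cand %in% windows$window_id
    cand <- cand[keep]
    # same-chromosome requirement
    pos <- match(cand, windows$window_id)
    near <- vapply(seq_along(cand), function(k) {
      w <- cand[k]
      any(windows$chrom[match(intersect(c(w - 1L, w + 1L), primary),
                              windows$window_id)] == windows$chrom[pos[k]])
    }, logical(1))
    cand <- cand[near]
    pos <- match(cand, windows$window_id)
    adj <- cand[counts[pos] >= q99]
  }
  rep_ <- list(primary_masked = sort(primary), adjacent_masked = sort(adj),
               q999 = q999, q99 = q99)
  class(rep_) <- "MaskReport"
  rep_
}

#' Apply a mask report to a window set
#'
#' @param windows a `WindowSet`.
#' @param report a `MaskReport` from [find_overrepresented()].
#' @return the `WindowSet` with its `masked` column set.
#' @export
mask_windows <- function(windows, report) {
  ids <- c(report$primary_masked, report$adjacent_masked)
  windows$masked <- windows$window_id %in% ids
  windows
}

#' Write / read a WindowSet as BED6 (name = window_id, score = cpg_count)
#' @param windows a `WindowSet`.
#' @param path output file.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    windows$window_id, windows$cpg_count,
                    ifelse(windows$masked, "-", "+"))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_bed
#' @param window_size window width used when the BED was written.
#' @export
read_windows_bed <- function(path, window_size = NULL) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end",
                                         "window_id", "cpg_count", "strand"))
  ws <- data.frame(window_id = as.integer(bed$window_id),
                   chrom = bed$chrom, start = as.integer(bed$start),
                   end = as.integer(bed$end),
                   cpg_count = as.integer(bed$cpg_count),
                   masked = bed$strand == "-", stringsAsFactors = FALSE)
  ws <- ws[order(ws$window_id), , drop = FALSE]
  rownames(ws) <- NULL
  if (is.null(window_size)) window_size <- max(ws$end - ws$start)
  attr(ws, "window_size") <- as.integer(window_size)
  attr(ws, "has_cpg") <- any(ws$cpg_count > 0)
  class(ws) <- c("WindowSet", "data.frame")
  ws
}
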