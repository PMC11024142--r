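#' Filter sequenced fragments
#'
#' Retains paired-end fragments where at least one mate maps with
#' MAPQ >= `min_mapq`, the reference span (end - start) lies within
#' `len_range` (both bounds inclusive) and is at least `min_span` bp. The
#' span floor is subsumed by the default length range but kept as an explicit
#' parameter. Malformed records (non-positive span, NA fields) are dropped and
#' tallied. Rejection reasons are assessed in order: malformed, mapq, length,
#' span; each reject is counted once under the first failing rule.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`, `mapq1`,
#'   `mapq2` (0-based half-open coordinates).
#' @param min_mapq minimum MAPQ for the better-mapped mate (default 10).
#' @param len_range inclusive fragment-length bounds in bp (default c(90, 1000)).
#' @param min_span minimum reference span in bp (default 30).
#' @return the retained fragments, with an integer `tally` attribute
#'   (`input`, `retained`, `malformed`, `fail_mapq`, `fail_length`,
#'   `fail_span`).
#' @export
filter_fragments <- function(fragments, min_mapq = 10,
                             len_range = c(90, 1000), min_span = 30) {
  need <- c("chrom", "start", "end", "mapq1", "mapq2")
  stopifnot(all(need %in% names(fragments)))
  n <- nrow(fragments)
  len <- fragments$end - fragments$start
  bad <- is.na(fragments$chrom) | is.na(len) | len <= 0 |
    is.na(fragments$mapq1) | is.na(fragments$mapq2)
  mq <- pmax(fragments$mapq1, fragments$mapq2) >= min_mapq
  okl <- len >= len_range[1] & len <= len_range[2]
  oks <- len >= min_span
  state <- ifelse(bad, "malformed",
           ifelse(!mq, "fail_mapq",
           ifelse(!okl, "fail_length",
           ifelse(!oks, "fail_span", "retained"))))
  keep <- state == "retained"
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  tally <- c(input = n, retained = sum(keep),
             malformed = sum(state == "malformed"),
             fail_mapq = sum(state == "fail_mapq"),
             fail_length = sum(state == "fail_length"),
             fail_span = sum(state == "fail_span"))
  attr(out, "tally") <- tally
  out
}

#' Assign filtered fragments to windows by midpoint
#'
#' Each fragment increments exactly one window: the one containing
#' `floor((start + end) / 2)` (even-length midpoints round down). Fragments on
#' chromosomes absent from the window set are skipped and tallied. Per-sample
#' valid totals count every assigned fragment, including those falling in
#' masked windows: totals describe the library, not the feature space.
#'
#' @param fragments a single data.frame of filtered fragments, or a named list
#'   of them (one element per sample).
#' @param windows a `WindowSet`.
#' @return a `CountMatrix`: list with `counts` (windows x samples integer
#'   matrix), `sample_ids`, `window_ids`, `valid_totals`, `cnv_factor`
#'   (NULL until set), `windows`, and a `skipped` tally.
#' @export
assign_counts <- function(fragments, windows) {
  if (is.data.frame(fragments)) fragments <- list(sample1 = fragments)
  if (is.null(names(fragments)) || any(!nzchar(names(fragments))))
    stop("fragment list must be named by sample")
  nwin <- nrow(windows)
  counts <- matrix(0L, nrow = nwin, ncol = length(fragments),
                   dimnames = list(windows$window_id, names(fragments)))
  skipped <- integer(length(fragments))
  names(skipped) <- names(fragments)
  for (s in seq_along(fragments)) {
    fr <- fragments[[s]]
    mid <- (fr$start + fr$end) %/% 2L
    wid <- locate_window(windows, fr$chrom, mid)
    skipped[s] <- sum(is.na(wid))
    tab <- tabulate(wid[!is.na(wid)] + 1L, nbins = nwin)
    counts[, s] <- as.integer(tab)
  }
  cm <- list(counts = counts,
             sample_ids = names(fragments),
             window_ids = windows$window_id,
             valid_totals = colSums(counts),
             cnv_factor = NULL,
             windows = windows,
             skipped = skipped)
  class(cm) <- "CountMatrix"
  cm
}

#' Build a CountMatrix from an existing windows x samples count matrix
#'
#' @param counts windows x samples matrix of non-negative counts.
#' @param windows a `WindowSet` with `nrow(windows) == nrow(counts)`.
#' @param valid_totals per-sample totals; defaults to column sums.
#' @param cnv_factor optional windows x samples matrix of copy-ratio factors.
#' @export
count_matrix <- function(counts, windows, valid_totals = NULL,
                         cnv_factor = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(windows), all(counts >= 0))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  rownames(counts) <- windows$window_id
  if (is.null(valid_totals)) valid_totals <- colSums(counts)
  if (!is.null(cnv_factor)) {
    cnv_factor <- as.matrix(cnv_factor)
    stopifnot(all(dim(cnv_factor) == dim(counts)), all(cnv_factor > 0))
  }
  cm <- list(counts = counts, sample_ids = colnames(counts),
             window_ids = windows$window_id,
             valid_totals = stats::setNames(valid_totals, colnames(counts)),
             cnv_factor = cnv_factor, windows = windows,
             skipped = integer(ncol(counts)))
  class(cm) <- "CountMatrix"
  cm
}

#' Normalised reads per million (NRPM)
#'
#' `nrpm[w, s] = counts[w, s] / valid_totals[s] * 1e6 / cnv_factor[w, s]`.
#' Masked windows are emitted as NA. No trimmed-mean-of-M normalisation is
#' applied.
#'
#' @param cm a `CountMatrix`.
#' @return windows x samples numeric matrix.
#' @export
nrpm <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (any(cm$valid_totals == 0)) {
    stop("zero valid fragments for sample(s): ",
         paste(cm$sample_ids[cm$valid_totals == 0], collapse = ", "))
  }
  out <- sweep(cm$counts, 2, cm$valid_totals, "/") * 1e6
  if (!is.null(cm$cnv_factor)) out <- out / cm$cnv_factor
  out[cm$windows$masked, ] <- NA_real_
  out
}

#' Blind calibration of NRPM to beta-values
#'
#' Maps enrichment signal to a methylation scale in \[0, 1\] without a matched
#' bisulfite reference. Per sample, the background level B is the median NRPM
#' of CpG-free windows, and the saturation level M_d of each CpG-density
#' stratum d is the `sat_quantile` (default 0.90) of NRPM within the stratum
#' (its strongest windows are presumed fully methylated). M_d is made
#' monotone non-decreasing in d by weighted isotonic regression; strata with
#' fewer than `min_support` windows are filled by interpolation from
#' neighbouring strata. Then `beta = clip((nrpm - B) / (M_d - B), 0, 1)`.
#' Windows with `cpg_count == 0`, masked windows, and strata where
#' `M_d <= B` yield NA.
#'
#' @param nrpm_mat windows x samples NRPM matrix (from [nrpm()]).
#' @param windows the matching `WindowSet` (must carry CpG counts).
#' @param sat_quantile quantile defining the presumed-methylated level.
#' @param min_support minimum windows per stratum for direct estimation.
#' @return a `BetaMatrix`: windows x samples numeric matrix in \[0, 1\]/NA
#'   with class attribute.
#' @export
calibrate_beta <- function(nrpm_mat, windows, sat_quantile = 0.9,
                           min_support = 10) {
  stopifnot(nrow(nrpm_mat) == nrow(windows))
  if (!isTRUE(attr(windows, "has_cpg")) && all(windows$cpg_count == 0))
    stop("window set carries no CpG densities; calibration impossible")
  d <- windows$cpg_count
  usable <- !windows$masked
  beta <- matrix(NA_real_, nrow(nrpm_mat), ncol(nrpm_mat),
                 dimnames = dimnames(nrpm_mat))
  dvals <- sort(unique(d[d > 0 & usable]))
  for (s in seq_len(ncol(nrpm_mat))) {
    x <- nrpm_mat[, s]
    zero_ok <- usable & d == 0 & !is.na(x)
    if (any(zero_ok)) {
      B <- stats::median(x[zero_ok])
    } else {
      warning("no CpG-free windows; background set to 0")
      B <- 0
    }
    M <- vapply(dvals, function(dd) {
      v <- x[usable & d == dd & !is.na(x)]
      if (length(v) < min_support) return(NA_real_)
      unname(stats::quantile(v, sat_quantile, type = 7))
    }, numeric(1))
    w <- vapply(dvals, function(dd) sum(usable & d == dd & !is.na(x)),
                numeric(1))
    known <- !is.na(M)
    if (!any(known)) next
    if (sum(known) == 1L) {
      M[] <- M[known]
    } else {
      M[!known] <- stats::approx(dvals[known], M[known], xout = dvals[!known],
                                 rule = 2)$y
    }
    M <- isotonic_fit(dvals, M, w)
    for (k in seq_along(dvals)) {
      sel <- usable & d == dvals[k] & !is.na(x)
      if (M[k] <= B) next
      beta[sel, s] <- pmin(pmax((x[sel] - B) / (M[k] - B), 0), 1)
    }
  }
  class(beta) <- c("BetaMatrix", class(beta))
  beta
}

# weighted isotonic (non-decreasing) least-squares fit: pool adjacent
# violators; x assumed sorted increasing
isotonic_fit <- function(x, y, w = rep(1, length(y))) {
  n <- length(y)
  if (n <= 1L) return(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L] + 1e-12) {
      nv <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) / (wt[i] + wt[i + 1L])
      val[i] <- nv; wt[i] <- wt[i] + wt[i + 1L]
      idx[[i]] <- c(idx[[i]], idx[[i + 1L]])
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; idx <- idx[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  out <- numeric(n)
  for (k in seq_along(val)) out[idx[[k]]] <- val[k]
  out
}

#' Read / write fragment tables and count matrices as TSV
#'
#' Fragments are BED-like TSV files with columns chrom, start, end, mapq1,
#' mapq2; count and beta matrices are TSV with a `window_id` column followed
#' by one column per sample.
#'
#' @param path file path (fragments may be gzipped).
#' @export
read_fragments_tsv <- function(path) {
  fr <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("chrom", "start", "end", "mapq1", "mapq2")
  stopifnot(all(need %in% names(fr)))
  as.data.frame(fr[, need, with = FALSE])
}

#' @rdname read_fragments_tsv
#' @param mat windows x samples matrix with window_id rownames.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(window_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname read_fragments_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
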