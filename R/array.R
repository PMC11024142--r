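#' Load the default class-regrouping table
#'
#' The shipped table maps source histology labels to the 30 classifier
#' classes (29 tumour classes plus the non-cancer NCC class), merging
#' anatomically adjacent histologies (e.g. oesophagus + stomach
#' adenocarcinoma into UpperGI, oesophagus squamous + head and neck squamous
#' into UpperSq) and excluding mixed-histology labels.
#'
#' @return data.frame with columns `source_label`, `cupid_class`, `exclude`,
#'   `reason`.
#' @export
default_class_map <- function() {
  path <- system.file("extdata", "class_map.tsv", package = "mbdtoo")
  read_class_map(path)
}

#' @rdname default_class_map
#' @param path TSV file with the class-map columns.
#' @export
read_class_map <- function(path) {
  m <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                       na.strings = "NA"))
  stopifnot(all(c("source_label", "cupid_class", "exclude") %in% names(m)))
  m$exclude <- as.logical(m$exclude)
  m
}

#' Regroup array samples into classifier classes
#'
#' Relabels each sample's source histology to its classifier class and drops
#' excluded histologies (logged in the `exclusions` attribute). Unmapped
#' labels are an error listing the offenders.
#'
#' @param samples data.frame with columns `sample_id`, `source_label`.
#' @param map a class map (see [default_class_map()]).
#' @return data.frame `sample_id`, `class`, with attribute `exclusions`.
#' @export
apply_class_map <- function(samples, map = default_class_map()) {
  stopifnot(all(c("sample_id", "source_label") %in% names(samples)))
  m <- match(samples$source_label, map$source_label)
  if (anyNA(m)) {
    stop("unmapped source labels: ",
         paste(unique(samples$source_label[is.na(m)]), collapse = ", "))
  }
  excl <- map$exclude[m]
  out <- data.frame(sample_id = samples$sample_id[!excl],
                    class = map$cupid_class[m][!excl],
                    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- data.frame(
    sample_id = samples$sample_id[excl],
    source_label = samples$source_label[excl],
    reason = map$reason[m][excl], stringsAsFactors = FALSE)
  out
}

#' Collapse probe-level betas to window-level betas
#'
#' Each probe (a point coordinate) is mapped to its containing window; where
#' several probes fall in one window the maximum beta-value is used. Windows
#' without probes are absent from the output. Probes outside every window are
#' skipped and tallied in the `skipped_probes` attribute.
#'
#' @param arr an array beta set: list with `beta` (probes x samples matrix,
#'   rownames = probe ids), `probes` (data.frame `probe_id`, `chrom`, `pos`),
#'   and optionally `samples` (data.frame `sample_id`, `class`).
#' @param windows a `WindowSet`.
#' @return a `BetaMatrix` restricted to probe-bearing windows (rownames =
#'   window_id).
#' @export
probe_to_window_beta <- function(arr, windows) {
  stopifnot(is.matrix(arr$beta), is.data.frame(arr$probes))
  wid <- locate_window(windows, arr$probes$chrom, arr$probes$pos)
  skipped <- sum(is.na(wid))
  keep <- !is.na(wid)
  b <- arr$beta[keep, , drop = FALSE]
  wid <- wid[keep]
  uw <- sort(unique(wid))
  out <- matrix(NA_real_, length(uw), ncol(b),
                dimnames = list(uw, colnames(b)))
  grp <- match(wid, uw)
  for (s in seq_len(ncol(b))) {
    out[, s] <- vapply(split(b[, s], grp), function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, numeric(1))
  }
  attr(out, "skipped_probes") <- skipped
  class(out) <- c("BetaMatrix", class(out))
  out
}

#' Build the enrichment calibration table from pooled control profiles
#'
#' Pools non-cancer control (NCC) cfDNA samples into an average enrichment
#' profile and tabulates expected NRPM as a function of window CpG density d
#' and beta-value (grid step `beta_step`). Densities are capped at their
#' `d_cap_quantile` (pooled above the cap). Empty (d, beta) bins are filled by
#' interpolation along beta within each stratum, then along d; monotonicity
#' of expected NRPM in beta is enforced by isotonic projection.
#'
#' @param ncc_counts a `CountMatrix` of NCC samples.
#' @param ncc_beta matching `BetaMatrix` (e.g. from [calibrate_beta()]).
#' @param windows the shared `WindowSet`.
#' @param beta_step beta grid resolution (default 0.01).
#' @param d_cap_quantile density cap quantile (default 0.99).
#' @return a `CalibrationTable`: list with `d_values`, `beta_grid`,
#'   `expected_nrpm` (d x beta matrix), `d_cap`.
#' @export
build_calibration <- function(ncc_counts, ncc_beta, windows,
                              beta_step = 0.01, d_cap_quantile = 0.99) {
  stopifnot(inherits(ncc_counts, "CountMatrix"))
  nr <- nrpm(ncc_counts)
  pooled_nrpm <- rowMeans(nr, na.rm = TRUE)
  pooled_beta <- rowMeans(ncc_beta, na.rm = TRUE)
  d <- windows$cpg_count
  d_cap <- as.integer(stats::quantile(d[d > 0], d_cap_quantile, type = 7))
  d_cap <- max(d_cap, 1L)
  dd <- pmin(d, d_cap)
  beta_grid <- seq(0, 1, by = beta_step)
  d_values <- 0:d_cap
  ok <- !windows$masked & !is.na(pooled_nrpm)
  bbin <- round(pooled_beta / beta_step)          # index into beta_grid - 1
  tab <- matrix(NA_real_, length(d_values), length(beta_grid),
                dimnames = list(d_values, format(beta_grid)))
  for (di in seq_along(d_values)) {
    dv <- d_values[di]
    if (dv == 0) {
      sel <- ok & dd == 0
      if (any(sel)) tab[di, ] <- mean(pooled_nrpm[sel])   # background, flat
      next
    }
    sel <- ok & dd == dv & !is.na(pooled_beta)
    if (!any(sel)) next
    means <- tapply(pooled_nrpm[sel], bbin[sel], mean)
    tab[di, as.integer(names(means)) + 1L] <- means
    known <- !is.na(tab[di, ])
    if (sum(known) == 1L) {
      tab[di, ] <- tab[di, known]
    } else {
      tab[di, !known] <- stats::approx(beta_grid[known], tab[di, known],
                                       xout = beta_grid[!known], rule = 2)$y
    }
    tab[di, ] <- isotonic_fit(beta_grid, tab[di, ])
  }
  # fill strata with no data by interpolating along d, per beta column
  known_d <- !apply(tab, 1, function(r) all(is.na(r)))
  if (sum(known_d) == 0L) stop("no usable windows for calibration")
  if (sum(known_d) == 1L) {
    warning("single density stratum only; flat calibration table")
    tab[!known_d, ] <- rep(tab[known_d, ], each = sum(!known_d))
  } else if (any(!known_d)) {
    for (bi in seq_along(beta_grid)) {
      tab[!known_d, bi] <- stats::approx(d_values[known_d], tab[known_d, bi],
                                         xout = d_values[!known_d], rule = 2)$y
    }
  }
  ct <- list(d_values = d_values, beta_grid = beta_grid,
             expected_nrpm = tab, d_cap = d_cap, beta_step = beta_step)
  class(ct) <- "CalibrationTable"
  ct
}

#' Look up expected NRPM for (density, beta) pairs
#' @param table a `CalibrationTable`.
#' @param d integer CpG densities (capped at the table's cap).
#' @param beta beta-values in \[0, 1\] (snapped to the grid).
#' @export
expected_nrpm <- function(table, d, beta) {
  di <- pmin(pmax(as.integer(d), 0L), table$d_cap) + 1L
  bi <- pmin(pmax(round(beta / table$beta_step), 0),
             length(table$beta_grid) - 1L) + 1L
  table$expected_nrpm[cbind(di, bi)]
}

#' Convert window-level array betas to pseudo enrichment counts
#'
#' Expected counts per window are proportional to the calibration table's
#' expected NRPM at the window's CpG density and beta, rescaled so that the
#' expectation sums to `library_size`; integer counts are then drawn
#' multinomially (realistic shot noise, reproducible via `seed`). Output is
#' restricted to the supplied (probe-overlapping) windows.
#'
#' @param window_betas named numeric vector (names = window_id) for one
#'   sample; NAs contribute zero expected signal.
#' @param table a `CalibrationTable`.
#' @param windows the `WindowSet` (for CpG densities).
#' @param library_size number of fragments to draw (> 0).
#' @param seed RNG seed (required for reproducibility).
#' @return named integer vector of counts over the input windows.
#' @export
convert_array <- function(window_betas, table, windows, library_size, seed) {
  stopifnot(library_size > 0)
  wid <- as.integer(names(window_betas))
  pos <- match(wid, windows$window_id)
  if (anyNA(pos)) stop("window_betas contain unknown window_ids")
  d <- windows$cpg_count[pos]
  beta <- window_betas
  beta[is.na(beta)] <- 0
  rate <- expected_nrpm(table, d, beta)
  rate[is.na(rate) | rate < 0] <- 0
  if (sum(rate) <= 0) stop("all expected rates are zero")
  p <- rate / sum(rate)
  counts <- with_seed(seed, as.integer(stats::rmultinom(1, library_size, p)))
  names(counts) <- names(window_betas)
  counts
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Write / read a calibration table as TSV (long format: d, beta, expected_nrpm)
#' @param table a `CalibrationTable`.
#' @param path file path.
#' @export
write_calibration_tsv <- function(table, path) {
  df <- expand.grid(d = table$d_values, beta = table$beta_grid)
  df$expected_nrpm <- as.vector(table$expected_nrpm)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_calibration_tsv
#' @export
read_calibration_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  d_values <- sort(unique(df$d))
  beta_grid <- sort(unique(df$beta))
  tab <- matrix(df$expected_nrpm[order(df$beta, df$d)],
                length(d_values), length(beta_grid),
                dimnames = list(d_values, format(beta_grid)))
  ct <- list(d_values = d_values, beta_grid = beta_grid, expected_nrpm = tab,
             d_cap = max(d_values), beta_step = diff(beta_grid[1:2]))
  class(ct) <- "CalibrationTable"
  ct
}
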