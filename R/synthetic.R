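#' Configuration for the synthetic toy world
#'
#' Desk-scale defaults: 2 chromosomes of 0.3 Mb tiled into 300-bp windows
#' (~2000 windows), 4 tumour classes with 10 arrays each, 6 non-cancer
#' controls at 5e4 fragments depth. CpG densities are drawn from five strata
#' so density-dependent calibration has structure to learn. Class signatures
#' are disjoint marker-window sets with elevated beta; a block of
#' high-density windows is constitutively methylated in every profile and
#' doubles as the hyperstable QC panel.
#'
#' @param ... overrides for any default field.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_chroms = 2, chrom_length = 3e5, window_size = 300,
    n_classes = 4, arrays_per_class = 10, n_ncc = 6,
    markers_per_class = 40,          # marker windows per class, disjoint
    marker_beta = 0.9,               # class-specific methylation level
    baseline_beta = 0.2,             # background methylation level
    methylated_beta = 0.92,          # constitutive methylation level
    frac_methylated = 0.25,          # fraction of each CpG stratum always-on
    n_hyperstable = 120,             # windows in the always-methylated panel
    beta_noise_sd = 0.05,
    density_strata = c(0, 2, 5, 10, 20),   # CpGs per window
    density_weights = c(0.55, 0.15, 0.12, 0.12, 0.06),
    bg_rate = 2,                     # enrichment curve: background NRPM
    sat_rate = 120,                  # saturation NRPM at high density
    curve_mid = 6, curve_scale = 2.5,      # logistic midpoint / scale in CpGs
    depth = 5e4,
    fragment_length = c(120, 220),   # uniform range for synthetic fragments
    seed = 1)
  out <- utils::modifyList(cfg, list(...))
  stopifnot(out$n_classes >= 2, out$arrays_per_class >= 2, out$n_ncc >= 2,
            out$depth > 0, out$chrom_length >= out$window_size)
  class(out) <- "SyntheticConfig"
  out
}

#' Expected NRPM under the synthetic enrichment curve
#'
#' Logistic in CpG density, scaled by beta:
#' `bg + sat * beta * plogis((d - mid) / scale)`; monotone non-decreasing in
#' both arguments, with CpG-free windows pinned at the background rate.
#'
#' @param cfg a `SyntheticConfig`.
#' @param d CpG counts.
#' @param beta beta-values.
#' @export
enrichment_curve <- function(cfg, d, beta) {
  out <- cfg$bg_rate + cfg$sat_rate * beta *
    stats::plogis((d - cfg$curve_mid) / cfg$curve_scale)
  out[d == 0] <- cfg$bg_rate
  out
}

#' Generate the synthetic reference genome and window set
#'
#' Per window, a CpG stratum is drawn from the configured mixture; that many
#' CG dinucleotides are placed at distinct positions inside the window over
#' an A/T background, so window CpG counts are exact by construction.
#'
#' @param cfg a `SyntheticConfig`.
#' @return list with `genome` ([Biostrings::DNAStringSet]) and `windows`
#'   (`WindowSet`), plus the per-window `target_density` drawn.
#' @export
make_reference <- function(cfg) {
  if (cfg$window_size > cfg$chrom_length)
    stop("window_size exceeds chrom_length")
  with_seed(cfg$seed, {
    wsz <- cfg$window_size
    seqs <- character(cfg$n_chroms)
    targets <- list()
    for (ch in seq_len(cfg$n_chroms)) {
      nwin <- ceiling(cfg$chrom_length / wsz)
      dens <- sample(cfg$density_strata, nwin, replace = TRUE,
                     prob = cfg$density_weights)
      targets[[ch]] <- dens
      win_seqs <- vapply(seq_len(nwin), function(w) {
        len <- min(wsz, cfg$chrom_length - (w - 1) * wsz)
        base <- sample(c("A", "T"), len, replace = TRUE)
        k <- dens[w]
        if (k > 0 && len >= 2 * k) {
          # place CGs on even offsets so they never merge or straddle
          slots <- seq(1, len - 1, by = 2)
          pos <- sort(sample(slots, k))
          base[pos] <- "C"; base[pos + 1] <- "G"
        }
        paste(base, collapse = "")
      }, character(1))
      seqs[ch] <- paste(win_seqs, collapse = "")
    }
    names(seqs) <- paste0("chr", seq_len(cfg$n_chroms))
    genome <- Biostrings::DNAStringSet(seqs)
    windows <- tile_genome(genome, wsz)
    list(genome = genome, windows = windows,
         target_density = unlist(targets))
  })
}

# internal: shared world layout (marker/hyperstable window assignment and
# per-class true beta profiles)
synthetic_truth <- function(cfg, windows) {
  with_seed(cfg$seed + 101, {
    d <- windows$cpg_count
    eligible <- windows$window_id[d > 0]
    # constitutively methylated windows in every positive density stratum,
    # so each stratum carries a presumed-fully-methylated upper tail
    methylated <- unlist(lapply(split(eligible, d[match(eligible,
                                                        windows$window_id)]),
                                function(ids) {
      k <- max(1L, round(cfg$frac_methylated * length(ids)))
      sample(ids, min(k, length(ids)))
    }), use.names = FALSE)
    methylated <- sort(methylated)
    # hyperstable QC panel: denser methylated windows (stable betas)
    dm <- d[match(methylated, windows$window_id)]
    panel_pool <- methylated[dm >= stats::median(d[d > 0])]
    if (length(panel_pool) < 2) panel_pool <- methylated
    hyperstable <- sort(sample(panel_pool,
                               min(cfg$n_hyperstable, length(panel_pool))))
    pool <- setdiff(eligible, methylated)
    need <- cfg$n_classes * cfg$markers_per_class
    if (length(pool) < need) stop("not enough CpG-bearing windows for markers")
    picked <- sample(pool, need)
    markers <- split(picked, rep(seq_len(cfg$n_classes),
                                 each = cfg$markers_per_class))
    base <- rep(cfg$baseline_beta, nrow(windows))
    base[match(methylated, windows$window_id)] <- cfg$methylated_beta
    beta_by_class <- matrix(base, nrow(windows), cfg$n_classes,
                            dimnames = list(windows$window_id,
                                            paste0("Class", LETTERS[
                                              seq_len(cfg$n_classes)])))
    for (k in seq_len(cfg$n_classes)) {
      beta_by_class[match(markers[[k]], windows$window_id), k] <-
        cfg$marker_beta
    }
    ncc_beta <- base
    list(markers = markers, hyperstable = hyperstable,
         beta_by_class = beta_by_class, ncc_beta = ncc_beta,
         classes = colnames(beta_by_class))
  })
}

#' Generate class-labelled methylation array samples
#'
#' One probe per CpG-bearing window (at the window midpoint). Class-k samples
#' have beta near `marker_beta` on the class-k marker windows and near the
#' baseline elsewhere; hyperstable windows are near-fully methylated in every
#' class. Gaussian noise (sd `beta_noise_sd`) is clipped to \[0, 1\].
#'
#' @param cfg a `SyntheticConfig`.
#' @param windows a `WindowSet` from [make_reference()].
#' @return list: `arrays` (array beta set as used by
#'   [probe_to_window_beta()]), `samples` (sample_id/class), `truth`
#'   (`GroundTruth`: markers, hyperstable panel, per-class true betas).
#' @export
make_class_arrays <- function(cfg, windows) {
  truth <- synthetic_truth(cfg, windows)
  probe_win <- windows[windows$cpg_count > 0, , drop = FALSE]
  probes <- data.frame(
    probe_id = paste0("p", probe_win$window_id),
    chrom = probe_win$chrom,
    pos = (probe_win$start + probe_win$end) %/% 2L,
    window_id = probe_win$window_id, stringsAsFactors = FALSE)
  n_arr <- cfg$n_classes * cfg$arrays_per_class
  sample_ids <- sprintf("arr_%s_%02d",
                        rep(truth$classes, each = cfg$arrays_per_class),
                        rep(seq_len(cfg$arrays_per_class), cfg$n_classes))
  cls <- rep(truth$classes, each = cfg$arrays_per_class)
  beta <- with_seed(cfg$seed + 202, {
    m <- truth$beta_by_class[match(probes$window_id,
                                   as.integer(rownames(truth$beta_by_class))),
                             match(cls, truth$classes), drop = FALSE]
    noisy <- m + stats::rnorm(length(m), 0, cfg$beta_noise_sd)
    matrix(pmin(pmax(noisy, 0), 1), nrow(probes), n_arr,
           dimnames = list(probes$probe_id, sample_ids))
  })
  samples <- data.frame(sample_id = sample_ids, class = cls,
                        stringsAsFactors = FALSE)
  truth_out <- list(markers = truth$markers,
                    hyperstable = truth$hyperstable,
                    beta_by_class = truth$beta_by_class,
                    ncc_beta = truth$ncc_beta,
                    sample_class = stats::setNames(cls, sample_ids))
  class(truth_out) <- "GroundTruth"
  list(arrays = list(beta = beta,
                     probes = probes[, c("probe_id", "chrom", "pos")],
                     samples = samples),
       samples = samples, truth = truth_out)
}

#' Generate non-cancer control count profiles and the hyperstable panel
#'
#' Expected NRPM per window follows the enrichment curve at the NCC beta
#' profile; per-sample counts are Poisson draws scaled to the configured
#' depth. The constitutively methylated window subset is returned as the
#' hyperstable QC panel.
#'
#' @param cfg a `SyntheticConfig`.
#' @param windows a `WindowSet`.
#' @return list: `counts` (a `CountMatrix` of `n_ncc` samples),
#'   `hyperstable_panel` (window_ids), `true_beta` (per-window NCC beta).
#' @export
make_ncc_counts <- function(cfg, windows) {
  if (cfg$depth <= 0) stop("depth must be positive")
  truth <- synthetic_truth(cfg, windows)
  rate <- enrichment_curve(cfg, windows$cpg_count, truth$ncc_beta)
  lam <- rate / sum(rate) * cfg$depth
  counts <- with_seed(cfg$seed + 303, {
    matrix(stats::rpois(nrow(windows) * cfg$n_ncc, rep(lam, cfg$n_ncc)),
           nrow(windows), cfg$n_ncc,
           dimnames = list(windows$window_id,
                           sprintf("ncc_%02d", seq_len(cfg$n_ncc))))
  })
  cm <- count_matrix(counts, windows)
  list(counts = cm, hyperstable_panel = truth$hyperstable,
       true_beta = truth$ncc_beta)
}

#' Generate per-sample NCC fragment tables
#'
#' Fragments are drawn window-proportionally to the enrichment curve, with
#' uniform start jitter and lengths uniform in `cfg$fragment_length`; mapping
#' qualities are high so default filters retain them. Useful for exercising
#' the fragment-level operations (filtering, midpoint counting, relH).
#'
#' @param cfg a `SyntheticConfig`.
#' @param reference output of [make_reference()].
#' @param n_fragments fragments per sample (default `cfg$depth`).
#' @return named list of fragment data.frames.
#' @export
make_ncc_fragments <- function(cfg, reference, n_fragments = cfg$depth) {
  windows <- reference$windows
  truth <- synthetic_truth(cfg, windows)
  rate <- enrichment_curve(cfg, windows$cpg_count, truth$ncc_beta)
  p <- rate / sum(rate)
  chrom_len <- stats::setNames(Biostrings::width(reference$genome),
                               names(reference$genome))
  with_seed(cfg$seed + 404, {
    out <- lapply(seq_len(cfg$n_ncc), function(s) {
      wid <- sample.int(nrow(windows), n_fragments, replace = TRUE, prob = p)
      len <- sample(seq(cfg$fragment_length[1], cfg$fragment_length[2]),
                    n_fragments, replace = TRUE)
      centre <- windows$start[wid] +
        sample.int(cfg$window_size, n_fragments, replace = TRUE) - 1L
      start <- pmax(centre - len %/% 2L, 0L)
      end <- start + len
      L <- chrom_len[windows$chrom[wid]]
      end <- pmin(end, L)
      start <- pmax(end - len, 0L)
      data.frame(chrom = windows$chrom[wid], start = start, end = end,
                 mapq1 = 60L, mapq2 = 60L, stringsAsFactors = FALSE)
    })
    names(out) <- sprintf("ncc_%02d", seq_len(cfg$n_ncc))
    out
  })
}
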