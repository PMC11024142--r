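#' Plan in-silico cfDNA mixtures
#'
#' Enumerates every (array, NCC) pair once and every ordered (NCC, NCC) pair
#' once, drawing for each a spike-in proportion and a fragment depth uniformly
#' from the legal ranges, then subsamples to at most `per_class_cap` mixtures
#' per class label. Tumour arrays keep their class label; NCC-NCC mixtures and
#' arrays whose class is `NCC` (e.g. adjacent normal liver references) are
#' labelled NCC. In NCC-NCC pairs component a is the "spiked" sample,
#' mirroring the tumour-mixture asymmetry.
#'
#' @param arrays data.frame `sample_id`, `class` of converted array samples.
#' @param nccs character vector of NCC sample ids (>= 2).
#' @param seed base RNG seed; per-mixture seeds are derived by counter.
#' @param per_class_cap maximum mixtures per class label (default 10000).
#' @param tumour_range spike-in proportion range for array components
#'   (default c(0.005, 0.10)).
#' @param ncc_range proportion range for NCC-NCC mixtures (default
#'   c(0.15, 0.50)).
#' @param depth_range fragment-depth bounds (default c(1e6, 1e7)); the
#'   per-mixture upper bound is `min(depth_range[2], ncc_totals[b])`.
#' @param ncc_totals optional named vector of available NCC fragment totals.
#' @param n_repeats number of rounds of the every-pair-once procedure (the
#'   mixing is performed repeatedly, each round drawing fresh proportions and
#'   depths; default 1).
#' @param balance_classes when TRUE (default), the NCC-NCC block is repeated
#'   extra times so the NCC label count approximately matches the mean
#'   tumour-class count, yielding the approximately equal class distribution
#'   the training procedure assumes.
#' @return data.frame of `MixtureSpec`s: `component_a_id`, `component_b_id`,
#'   `proportion_a`, `n_fragments`, `class_label`, `seed`.
#' @export
plan_mixtures <- function(arrays, nccs, seed, per_class_cap = 10000,
                          tumour_range = c(0.005, 0.10),
                          ncc_range = c(0.15, 0.50),
                          depth_range = c(1e6, 1e7), ncc_totals = NULL,
                          n_repeats = 1, balance_classes = TRUE) {
  stopifnot(length(nccs) >= 2, all(c("sample_id", "class") %in% names(arrays)))
  if (per_class_cap < 1) stop("per_class_cap must be >= 1")
  pairs_a <- expand.grid(a = arrays$sample_id, b = nccs,
                         stringsAsFactors = FALSE)
  pairs_a$class <- arrays$class[match(pairs_a$a, arrays$sample_id)]
  pairs_a$range_lo <- tumour_range[1]
  pairs_a$range_hi <- tumour_range[2]
  nn <- expand.grid(a = nccs, b = nccs, stringsAsFactors = FALSE)
  nn <- nn[nn$a != nn$b, , drop = FALSE]
  nn$class <- "NCC"
  nn$range_lo <- ncc_range[1]
  nn$range_hi <- ncc_range[2]
  ncc_factor <- 1L
  if (balance_classes && nrow(nn) > 0) {
    tum <- pairs_a$class != "NCC"
    if (any(tum)) {
      mean_tumour <- mean(table(pairs_a$class[tum]))
      n_ncc_labels <- nrow(nn) + sum(!tum)
      ncc_factor <- max(1L, as.integer(round(mean_tumour / n_ncc_labels)))
    }
  }
  plan <- rbind(pairs_a, nn[rep(seq_len(nrow(nn)), ncc_factor), , drop = FALSE])
  if (n_repeats > 1)
    plan <- plan[rep(seq_len(nrow(plan)), n_repeats), , drop = FALSE]
  with_seed(seed, {
    plan$proportion_a <- stats::runif(nrow(plan), plan$range_lo, plan$range_hi)
    hi <- rep(depth_range[2], nrow(plan))
    if (!is.null(ncc_totals)) {
      avail <- ncc_totals[plan$b]
      hi <- pmin(hi, ifelse(is.na(avail), depth_range[2], avail))
    }
    hi <- pmax(hi, depth_range[1])
    plan$n_fragments <- floor(stats::runif(nrow(plan), depth_range[1], hi + 1))
    # per-class cap
    keep <- unlist(lapply(split(seq_len(nrow(plan)), plan$class), function(ix) {
      if (length(ix) <= per_class_cap) ix else sample(ix, per_class_cap)
    }), use.names = FALSE)
    plan <- plan[sort(keep), , drop = FALSE]
  })
  out <- data.frame(component_a_id = plan$a, component_b_id = plan$b,
                    proportion_a = plan$proportion_a,
                    n_fragments = as.integer(pmin(plan$n_fragments,
                                                  .Machine$integer.max)),
                    class_label = plan$class,
                    seed = as.integer((seed %% 1e9) + seq_len(nrow(plan))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mix two count profiles at a given proportion
#'
#' The mixture rate vector is `p * a/sum(a) + (1-p) * b/sum(b)`; counts are a
#' seeded multinomial draw of `n_fragments` fragments, so row sums are exact.
#'
#' @param spec one row of a mixture plan (list or one-row data.frame with
#'   `proportion_a`, `n_fragments`, `seed`).
#' @param a_counts,b_counts numeric count vectors on the same window universe.
#' @return integer count vector of length `length(a_counts)`.
#' @export
mix_counts <- function(spec, a_counts, b_counts) {
  stopifnot(length(a_counts) == length(b_counts))
  sa <- sum(a_counts); sb <- sum(b_counts)
  if (sa <= 0 || sb <= 0) stop("component with zero total counts")
  p <- spec$proportion_a
  rate <- p * a_counts / sa + (1 - p) * b_counts / sb
  cnt <- with_seed(spec$seed,
                   as.integer(stats::rmultinom(1, spec$n_fragments, rate)))
  names(cnt) <- names(a_counts)
  cnt
}

#' Realise a mixture plan into a labelled count matrix
#'
#' @param plan a mixture plan from [plan_mixtures()].
#' @param profiles named list of count vectors (arrays and NCCs), all on the
#'   same window universe.
#' @param windows the `WindowSet` matching that universe (may be a subset of
#'   a genome-wide set restricted to probe-overlapping windows).
#' @return a `MixtureSet`: list with `counts` (windows x mixtures matrix),
#'   `labels`, `plan`, `windows`.
#' @export
simulate_mixtures <- function(plan, profiles, windows) {
  missing_ids <- setdiff(unique(c(plan$component_a_id, plan$component_b_id)),
                         names(profiles))
  if (length(missing_ids))
    stop("profiles missing for: ", paste(missing_ids, collapse = ", "))
  nwin <- length(profiles[[1]])
  counts <- matrix(0L, nrow = nwin, ncol = nrow(plan))
  for (i in seq_len(nrow(plan))) {
    counts[, i] <- mix_counts(plan[i, ], profiles[[plan$component_a_id[i]]],
                              profiles[[plan$component_b_id[i]]])
  }
  rownames(counts) <- names(profiles[[1]])
  colnames(counts) <- sprintf("mix%05d", seq_len(nrow(plan)))
  ms <- list(counts = counts, labels = plan$class_label, plan = plan,
             windows = windows)
  class(ms) <- "MixtureSet"
  ms
}

#' NRPM features for a mixture set (or any count matrix) over feature windows
#'
#' @param counts windows x samples count matrix (rownames = window_id).
#' @param feature_windows window_ids to keep, in order.
#' @return samples x features numeric matrix of NRPM values.
#' @export
mixture_nrpm <- function(counts, feature_windows) {
  tot <- colSums(counts)
  if (any(tot == 0)) stop("sample with zero fragments")
  sel <- match(as.character(feature_windows), rownames(counts))
  if (anyNA(sel)) stop("feature windows absent from count matrix")
  t(sweep(counts[sel, , drop = FALSE], 2, tot, "/") * 1e6)
}
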