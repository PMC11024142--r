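#' Pairwise differentially methylated region (DMR) selection
#'
#' For every unordered pair of classes, each window's beta-values are compared
#' between the two classes with Welch's unequal-variance t-test, p-values are
#' Benjamini-Hochberg adjusted within the pair, and among windows with
#' q <= `fdr` the `n_top` with the most positive and `n_top` with the most
#' negative mean difference (delta beta = mean_i - mean_j) are retained.
#' Ties in |delta beta| at the boundary break by smaller q, then lower
#' window_id, so output is deterministic. Windows with fewer than two
#' non-missing values in either class are dropped for that pair.
#'
#' @param beta windows x samples `BetaMatrix` of pure (unmixed) class samples;
#'   rownames are window_ids.
#' @param classes character vector of per-sample class labels, aligned to the
#'   columns of `beta`.
#' @param fdr within-pair FDR threshold (default 0.001).
#' @param n_top DMRs kept per direction per pair (default 250).
#' @return a `DMRCatalog` data.frame: `window_id`, `class_i`, `class_j`,
#'   `delta_beta`, `q_value`, `direction` ("top"/"bottom").
#' @export
pairwise_dmrs <- function(beta, classes, fdr = 0.001, n_top = 250) {
  stopifnot(ncol(beta) == length(classes))
  cls <- sort(unique(classes))
  sizes <- table(classes)
  if (any(sizes < 2)) {
    stop("classes with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  wid <- as.integer(rownames(beta))
  out <- list()
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (j <= i) next
      bi <- beta[, classes == cls[i], drop = FALSE]
      bj <- beta[, classes == cls[j], drop = FALSE]
      st <- welch_rows(bi, bj)
      usable <- !is.na(st$p)
      q <- rep(NA_real_, length(st$p))
      q[usable] <- stats::p.adjust(st$p[usable], method = "BH")
      sig <- which(usable & q <= fdr & !is.na(st$delta) & st$delta != 0)
      if (!length(sig)) next
      pick_dir <- function(idx, decreasing) {
        ord <- order(st$delta[idx] * if (decreasing) -1 else 1,
                     q[idx], wid[idx])
        idx[ord][seq_len(min(n_top, length(idx)))]
      }
      top <- pick_dir(sig[st$delta[sig] > 0], decreasing = TRUE)
      bot <- pick_dir(sig[st$delta[sig] < 0], decreasing = FALSE)
      if (length(top)) {
        out[[length(out) + 1L]] <- data.frame(
          window_id = wid[top], class_i = cls[i], class_j = cls[j],
          delta_beta = st$delta[top], q_value = q[top], direction = "top",
          stringsAsFactors = FALSE)
      }
      if (length(bot)) {
        out[[length(out) + 1L]] <- data.frame(
          window_id = wid[bot], class_i = cls[i], class_j = cls[j],
          delta_beta = st$delta[bot], q_value = q[bot], direction = "bottom",
          stringsAsFactors = FALSE)
      }
    }
  }
  catalog <- if (length(out)) do.call(rbind, out) else
    data.frame(window_id = integer(0), class_i = character(0),
               class_j = character(0), delta_beta = numeric(0),
               q_value = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)
  rownames(catalog) <- NULL
  class(catalog) <- c("DMRCatalog", "data.frame")
  catalog
}

# vectorised per-row Welch t-test between two sample matrices
welch_rows <- function(a, b) {
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowVar(a, ma); vb <- rowVar(b, mb)
  delta <- ma - mb
  se2 <- va / na + vb / nb
  tt <- delta / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate variances: equal constants -> null; distinct constants -> signal
  zero_se <- !is.na(se2) & se2 == 0
  p[zero_se & delta == 0] <- 1
  p[zero_se & delta != 0] <- 0
  p[na < 2 | nb < 2] <- NA
  delta[na < 1 | nb < 1] <- NA
  list(delta = delta, p = p)
}

rowVar <- function(m, mu) {
  n <- rowSums(!is.na(m))
  rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
}

#' Collapse a DMR catalog to its unique window list
#'
#' @param catalog a `DMRCatalog`.
#' @return sorted integer vector of distinct window_ids.
#' @export
dedupe_regions <- function(catalog) {
  sort(unique(catalog$window_id))
}
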