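# shared fixture builders; everything is generated in code

# a WindowSet over named chromosome lengths (no sequence -> cpg_count 0)
toy_windows <- function(lens = c(chr1 = 900), window_size = 300) {
  tile_genome(lens, window_size)
}

# windows with prescribed per-window CpG counts, bypassing sequence
windows_with_cpg <- function(cpg, window_size = 300) {
  ws <- tile_genome(c(chr1 = length(cpg) * window_size), window_size)
  ws$cpg_count <- as.integer(cpg)
  attr(ws, "has_cpg") <- TRUE
  ws
}

frag <- function(chrom, start, end, mapq1 = 60, mapq2 = 60) {
  data.frame(chrom = chrom, start = start, end = end,
             mapq1 = mapq1, mapq2 = mapq2, stringsAsFactors = FALSE)
}

# exhaustive reference implementation of the over-representation mask
oracle_mask <- function(windows, counts) {
  q999 <- unname(quantile(counts, 0.999, type = 7))
  q99 <- unname(quantile(counts, 0.99, type = 7))
  if (q999 == median(counts)) {
    return(list(primary = integer(0), adjacent = integer(0)))
  }
  primary <- windows$window_id[counts >= q999]
  adjacent <- integer(0)
  for (w in windows$window_id) {
    if (w %in% primary) next
    for (nb in c(w - 1L, w + 1L)) {
      if (!(nb %in% primary)) next
      same <- windows$chrom[windows$window_id == nb] ==
        windows$chrom[windows$window_id == w]
      if (same && counts[windows$window_id == w] >= q99) {
        adjacent <- c(adjacent, w)
        break
      }
    }
  }
  list(primary = sort(primary), adjacent = sort(unique(adjacent)))
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force weighted pool-adjacent-violators (isotonic least squares)
oracle_pava <- function(y, w = rep(1, length(y))) {
  blocks <- lapply(seq_along(y), function(i) list(v = y[i], w = w[i], n = 1))
  i <- 1
  while (i < length(blocks)) {
    if (blocks[[i]]$v > blocks[[i + 1]]$v + 1e-12) {
      b <- list(v = (blocks[[i]]$v * blocks[[i]]$w +
                       blocks[[i + 1]]$v * blocks[[i + 1]]$w) /
                  (blocks[[i]]$w + blocks[[i + 1]]$w),
                w = blocks[[i]]$w + blocks[[i + 1]]$w,
                n = blocks[[i]]$n + blocks[[i + 1]]$n)
      blocks[[i]] <- b
      blocks[[i + 1]] <- NULL
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  unlist(lapply(blocks, function(b) rep(b$v, b$n)))
}

# brute-force Hand-Till AUROC by pair enumeration
oracle_hand_till <- function(scores, labels) {
  cls <- intersect(colnames(scores), unique(labels))
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  auc_one <- function(ci, cj) {
    # A(ci | cj): P(class-ci sample outscores class-cj sample on ci score)
    si <- scores[labels == ci, ci]
    sj <- scores[labels == cj, ci]
    tot <- 0
    for (a in si) for (b in sj) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(si) * length(sj))
  }
  mean(vapply(pairs, function(pr) {
    (auc_one(pr[1], pr[2]) + auc_one(pr[2], pr[1])) / 2
  }, numeric(1)))
}

# small labelled mixture world for ensemble tests, built from raw pieces
tiny_mixture_world <- function(seed = 5, n_classes = 3, arrays_per_class = 4,
                               n_ncc = 4, n_windows = 60, n_repeats = 3,
                               depth = c(2e3, 5e3)) {
  set.seed(seed)
  classes <- paste0("C", seq_len(n_classes))
  arrays <- data.frame(
    sample_id = sprintf("a_%s_%d", rep(classes, each = arrays_per_class),
                        seq_len(arrays_per_class)),
    class = rep(classes, each = arrays_per_class), stringsAsFactors = FALSE)
  nccs <- sprintf("n_%d", seq_len(n_ncc))
  base <- runif(n_windows, 5, 20)
  profiles <- list()
  markers <- split(seq_len(n_classes * 10),
                   rep(seq_len(n_classes), each = 10))
  for (i in seq_len(nrow(arrays))) {
    r <- base
    r[markers[[match(arrays$class[i], classes)]]] <- 80
    profiles[[arrays$sample_id[i]]] <-
      setNames(rpois(n_windows, r), seq_len(n_windows) - 1L)
  }
  for (s in nccs) {
    profiles[[s]] <- setNames(rpois(n_windows, base), seq_len(n_windows) - 1L)
  }
  plan <- plan_mixtures(arrays, nccs, seed = seed + 1,
                        tumour_range = c(0.2, 0.6),
                        ncc_range = c(0.15, 0.5),
                        depth_range = depth, n_repeats = n_repeats)
  windows <- windows_with_cpg(rep(3, n_windows))
  mixtures <- simulate_mixtures(plan, profiles, windows)
  list(arrays = arrays, nccs = nccs, mixtures = mixtures,
       dmr_windows = unlist(markers) - 1L, classes = classes)
}
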