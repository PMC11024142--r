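test_that("tiling partitions chromosomes into fixed-width windows", {
  ws <- tile_genome(c(chr1 = 900), 300)
  expect_equal(nrow(ws), 3)
  expect_equal(ws$start, c(0, 300, 600))
  expect_equal(ws$end, c(300, 600, 900))

  ws <- tile_genome(c(chr1 = 650), 300)
  expect_equal(nrow(ws), 3)
  expect_equal(ws$start[3], 600)
  expect_equal(ws$end[3], 650)

  # partition property over random chromosome lengths
  set.seed(7)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    lens <- setNames(sample(50:2000, k), paste0("c", seq_len(k)))
    wsz <- sample(c(37, 100, 300), 1)
    ws <- tile_genome(lens, wsz)
    expect_equal(sum(ws$end - ws$start), sum(lens))
    expect_equal(ws$window_id, seq_len(nrow(ws)) - 1L)
    # within each chromosome, windows abut without overlap
    for (ch in names(lens)) {
      sub <- ws[ws$chrom == ch, ]
      expect_equal(sub$start[-1], sub$end[-nrow(sub)])
    }
  }
})

test_that("tiling rejects degenerate genomes", {
  expect_error(tile_genome(numeric(0)), "empty")
  expect_error(tile_genome(c(a = 100, a = 200)), "duplicate")
  expect_error(tile_genome(c(a = 100), window_size = 0), "window_size")
})

test_that("CpG counting scans CG dinucleotides on the forward strand", {
  seqs <- c(chr1 = paste0("CGCG", strrep("A", 296)))
  ws <- tile_genome(seqs, 300)
  expect_equal(ws$cpg_count, 2L)

  # CG straddling a window boundary belongs to neither window
  seqs <- c(chr1 = paste0(strrep("A", 299), "CG", strrep("A", 299)))
  ws <- tile_genome(seqs, 300)
  expect_equal(ws$cpg_count, c(0L, 0L))

  # case-insensitive, N never forms a CpG
  seqs <- c(chr1 = paste0("cgNCGN", strrep("T", 294)))
  ws <- tile_genome(seqs, 300)
  expect_equal(ws$cpg_count, 2L)
})

test_that("over-represented windows follow the two-tier quantile rule", {
  # extreme window plus one qualifying neighbour
  counts <- rep(c(1, 2, 3, 1), 250)
  counts[500] <- 1e6   # window_id 499
  counts[501] <- 50    # window_id 500, above the 99th percentile
  counts[499] <- 1     # other neighbour stays low
  ws <- toy_windows(c(chr1 = 1000 * 300))
  rep_ <- find_overrepresented(ws, counts)
  expect_equal(rep_$primary_masked, 499L)
  expect_equal(rep_$adjacent_masked, 500L)

  # degenerate uniform input masks nothing
  expect_equal(find_overrepresented(ws, rep(5, 1000))$primary_masked,
               integer(0))

  # isolated high window with low neighbours -> only that window
  counts2 <- rep(c(1, 2, 3, 1), 250)
  counts2[500] <- 1e6
  counts2[499] <- 1
  counts2[501] <- 1
  rep2 <- find_overrepresented(ws, counts2)
  expect_equal(rep2$primary_masked, 499L)
  expect_equal(rep2$adjacent_masked, integer(0))

  expect_warning(find_overrepresented(ws, rep(0, 1000)), "zero")
})

test_that("mask matches the exhaustive oracle and is monotone", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(c(1000, 2000), 1)
    ws <- toy_windows(c(chr1 = (n / 2) * 300, chr2 = (n / 2) * 300))
    counts <- rpois(n, 10) + rbinom(n, 1, 0.01) * rpois(n, 500)
    rep_ <- find_overrepresented(ws, counts)
    orc <- oracle_mask(ws, counts)
    expect_equal(rep_$primary_masked, orc$primary)
    expect_equal(rep_$adjacent_masked, orc$adjacent)
  }

  # own-window monotonicity: raising a window's count never unmasks that
  # window (global monotonicity cannot hold: the empirical thresholds
  # themselves rise, which may release other windows)
  set.seed(12)
  n <- 1000
  ws <- toy_windows(c(chr1 = n * 300))
  for (i in 1:10) {
    counts <- rpois(n, 10) + rbinom(n, 1, 0.01) * rpois(n, 500)
    before <- find_overrepresented(ws, counts)
    masked_before <- c(before$primary_masked, before$adjacent_masked)
    if (!length(masked_before)) next
    w <- masked_before[1]
    counts[w + 1L] <- counts[w + 1L] + sample(c(1, 100, 1e5), 1)
    after <- find_overrepresented(ws, counts)
    expect_true(w %in% c(after$primary_masked, after$adjacent_masked))
  }
})

test_that("mask_windows sets flags and adjacency respects chromosomes", {
  # primary at the end of chr1; chr2's first window must not become adjacent
  ws <- tile_genome(c(chr1 = 500 * 300, chr2 = 500 * 300), 300)
  counts <- rep(c(1, 2, 3, 1), 250)
  counts[500] <- 1e6  # window_id 499, last window of chr1
  counts[501] <- 50   # window_id 500, first window of chr2: high but cross-chrom
  counts[499] <- 50   # window_id 498, same chromosome: masked as adjacent
  rep_ <- find_overrepresented(ws, counts)
  expect_equal(rep_$primary_masked, 499L)
  expect_equal(rep_$adjacent_masked, 498L)
  ws2 <- mask_windows(ws, rep_)
  expect_equal(ws2$masked, ws2$window_id %in%
                 c(rep_$primary_masked, rep_$adjacent_masked))
})

test_that("window BED round-trips through disk", {
  ws <- tile_genome(c(chrA = 650, chrB = 550), 300)
  ws$cpg_count <- seq_len(nrow(ws))
  ws$masked <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  path <- tempfile(fileext = ".bed")
  write_windows_bed(ws, path)
  back <- read_windows_bed(path, window_size = 300)
  expect_equal(back$window_id, ws$window_id)
  expect_equal(back$start, ws$start)
  expect_equal(back$cpg_count, ws$cpg_count)
  expect_equal(back$masked, ws$masked)
})
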