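test_that("fragment filters apply the MAPQ, length and span rules", {
  fr <- rbind(
    frag("chr1", 0, 89),               # length 89: rejected
    frag("chr1", 0, 90),               # length 90: retained (inclusive)
    frag("chr1", 0, 1000),             # length 1000: retained
    frag("chr1", 0, 1001),             # length 1001: rejected
    frag("chr1", 0, 200, 5, 60),       # either-end MAPQ rule: retained
    frag("chr1", 0, 200, 5, 9),        # both mates below 10: rejected
    frag("chr1", 100, 100))            # malformed (zero span)
  out <- filter_fragments(fr)
  tally <- attr(out, "tally")
  expect_equal(nrow(out), 3)
  expect_equal(unname(tally["input"]), 7)
  expect_equal(unname(tally["retained"]), 3)
  expect_equal(unname(tally["fail_mapq"]), 1)
  expect_equal(unname(tally["fail_length"]), 2)
  expect_equal(unname(tally["malformed"]), 1)
  expect_equal(sum(tally[-1]), unname(tally["input"]))

  # span parameter is independently honoured
  out2 <- filter_fragments(frag("chr1", 0, 50), len_range = c(10, 1000),
                           min_span = 60)
  expect_equal(nrow(out2), 0)
})

test_that("midpoint assignment respects half-open window boundaries", {
  ws <- toy_windows(c(chr1 = 900))
  fr <- rbind(frag("chr1", 100, 400),   # midpoint 250 -> window 0
              frag("chr1", 150, 451),   # midpoint 300 -> window 1
              frag("chr1", 150, 450))   # midpoint 300 -> window 1
  cm <- assign_counts(list(s1 = fr), ws)
  expect_equal(unname(cm$counts[, "s1"]), c(1L, 2L, 0L))
  expect_equal(unname(cm$valid_totals["s1"]), 3)

  # fragments on unknown chromosomes are skipped but tallied
  fr2 <- rbind(frag("chr1", 0, 200), frag("chrX", 0, 200))
  cm2 <- assign_counts(list(s1 = fr2), ws)
  expect_equal(unname(cm2$valid_totals["s1"]), 1)
  expect_equal(unname(cm2$skipped["s1"]), 1)
})

test_that("counts are conserved under assignment", {
  set.seed(3)
  ws <- toy_windows(c(chr1 = 6000, chr2 = 4000))
  n <- 500
  fr <- frag(sample(c("chr1", "chr2", "chrUn"), n, replace = TRUE),
             start <- sample(0:3500, n, replace = TRUE), start + 150)
  cm <- assign_counts(list(s = fr), ws)
  expect_equal(sum(cm$counts) + unname(cm$skipped["s"]), n)
})

test_that("NRPM follows the definitional formula with CNV correction", {
  ws <- toy_windows(c(chr1 = 900))
  counts <- matrix(c(100, 0, 50), ncol = 1)
  cm <- count_matrix(counts, ws, valid_totals = 1e6)
  expect_equal(unname(nrpm(cm)[, 1]), c(100, 0, 50))

  cnv <- matrix(c(2, 1, 1), ncol = 1)
  cm2 <- count_matrix(counts, ws, valid_totals = 2e6, cnv_factor = cnv)
  expect_equal(unname(nrpm(cm2)[1, 1]), 100 / 2e6 * 1e6 / 2)  # = 25

  # masked windows are emitted as missing
  ws$masked[2] <- TRUE
  cm3 <- count_matrix(counts, ws, valid_totals = 1e6)
  expect_true(is.na(nrpm(cm3)[2, 1]))

  cm4 <- count_matrix(counts, ws, valid_totals = 0)
  expect_error(nrpm(cm4), "zero valid")
})

test_that("NRPM is invariant under fragment duplication", {
  set.seed(4)
  ws <- toy_windows(c(chr1 = 3000))
  fr <- frag("chr1", s <- sample(0:2800, 200, replace = TRUE), s + 150)
  one <- nrpm(assign_counts(list(s = fr), ws))
  two <- nrpm(assign_counts(list(s = rbind(fr, fr)), ws))
  expect_equal(one, two)
})

test_that("blind calibration hits the endpoints and stays bounded", {
  # 3 strata (0, 2, 5), constructed NRPM with known background and saturation
  set.seed(9)
  cpg <- rep(c(0, 2, 5), each = 40)
  ws <- windows_with_cpg(cpg)
  B <- 10
  M <- c(`2` = 60, `5` = 110)
  x <- numeric(nrow(ws))
  x[cpg == 0] <- B
  # per stratum: most windows midway, top decile exactly at saturation
  for (d in c(2, 5)) {
    idx <- which(cpg == d)
    x[idx] <- B + 0.5 * (M[as.character(d)] - B)
    x[idx[1:5]] <- M[as.character(d)]
  }
  nr <- matrix(x, ncol = 1, dimnames = list(ws$window_id, "s1"))
  beta <- calibrate_beta(nr, ws, min_support = 5)
  expect_true(all(beta[!is.na(beta)] >= 0 & beta[!is.na(beta)] <= 1))
  expect_true(all(is.na(beta[cpg == 0, 1])))
  d2 <- which(cpg == 2)
  expect_equal(unname(beta[d2[1], 1]), 1.0)          # at saturation
  expect_equal(unname(beta[d2[40], 1]), 0.5, tolerance = 1e-6)  # midway

  # monotone in NRPM within a stratum
  ord <- order(nr[d2, 1])
  expect_true(all(diff(beta[d2, 1][ord]) >= -1e-12))
})

test_that("calibration without CpG densities is refused", {
  ws <- toy_windows(c(chr1 = 900))
  nr <- matrix(1:3, ncol = 1, dimnames = list(ws$window_id, "s"))
  expect_error(calibrate_beta(nr, ws), "CpG")
})

test_that("weighted isotonic fit equals the PAVA oracle", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    y <- rnorm(n)
    w <- runif(n, 0.5, 3)
    expect_equal(mbdtoo:::isotonic_fit(seq_len(n), y, w), oracle_pava(y, w),
                 tolerance = 1e-10)
  }
})

test_that("matrix TSV round-trips", {
  m <- matrix(rnorm(12), 4, 3, dimnames = list(0:3, paste0("s", 1:3)))
  p <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, p)
  back <- read_matrix_tsv(p)
  expect_equal(back, m, tolerance = 1e-12)
})
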