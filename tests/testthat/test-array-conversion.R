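test_that("the shipped class map regroups histologies into 30 classes", {
  map <- default_class_map()
  kept <- map$cupid_class[!map$exclude]
  expect_equal(length(unique(kept)), 30)
  expect_true("NCC" %in% kept)

  samples <- data.frame(
    sample_id = paste0("s", 1:4),
    source_label = c("Oesophagus adenocarcinoma",
                     "Oesophagus squamous cell carcinoma",
                     "Hepatocholangiocarcinoma (Mixed)",
                     "Adjacent normal liver"))
  out <- apply_class_map(samples, map)
  expect_equal(out$class[out$sample_id == "s1"], "UpperGI")
  expect_equal(out$class[out$sample_id == "s2"], "UpperSq")
  expect_false("s3" %in% out$sample_id)
  expect_equal(attr(out, "exclusions")$sample_id, "s3")
  expect_equal(out$class[out$sample_id == "s4"], "NCC")

  expect_error(apply_class_map(
    data.frame(sample_id = "x", source_label = "No Such Histology"), map),
    "unmapped")
})

test_that("identity class map leaves synthetic labels unchanged", {
  map <- data.frame(source_label = c("A", "B"), cupid_class = c("A", "B"),
                    exclude = FALSE, reason = NA)
  samples <- data.frame(sample_id = c("s1", "s2"),
                        source_label = c("A", "B"))
  out <- apply_class_map(samples, map)
  expect_equal(out$class, c("A", "B"))
})

test_that("probe betas collapse to windows by maximum", {
  ws <- toy_windows(c(chr1 = 900))
  arr <- list(
    beta = matrix(c(0.2, 0.9, 0.4), ncol = 1,
                  dimnames = list(c("p1", "p2", "p3"), "s1")),
    probes = data.frame(probe_id = c("p1", "p2", "p3"),
                        chrom = "chr1", pos = c(10, 250, 400)))
  wb <- probe_to_window_beta(arr, ws)
  expect_equal(rownames(wb), c("0", "1"))       # window 2 has no probes
  expect_equal(unname(wb["0", 1]), 0.9)          # max(0.2, 0.9)
  expect_equal(unname(wb["1", 1]), 0.4)          # single probe

  # probe outside all windows is skipped with a tally
  arr$probes$pos[3] <- 5000
  wb2 <- probe_to_window_beta(arr, ws)
  expect_equal(attr(wb2, "skipped_probes"), 1)
})

test_that("calibration table averages constructed bins and is monotone", {
  # density-3 windows at pooled beta 1 averaging 50 NRPM
  cpg <- c(rep(0, 30), rep(3, 30))
  ws <- windows_with_cpg(cpg)
  counts <- matrix(0, nrow(ws), 2, dimnames = list(ws$window_id, c("n1", "n2")))
  counts[cpg == 0, ] <- 5
  counts[cpg == 3, ] <- 50
  cm <- count_matrix(counts, ws, valid_totals = c(n1 = 1e6, n2 = 1e6))
  beta <- matrix(NA_real_, nrow(ws), 2, dimnames = dimnames(counts))
  beta[cpg == 3, ] <- 1.0
  ct <- build_calibration(cm, beta, ws)
  expect_equal(unname(expected_nrpm(ct, 3, 1.0)), 50)
  # beta-0 entry of a stratum equals its interpolated background end
  expect_true(all(diff(ct$expected_nrpm["3", ]) >= -1e-9))
  # monotone in beta within every stratum (isotonic projection)
  expect_true(all(apply(ct$expected_nrpm, 1, function(r) all(diff(r) >= -1e-9))))
})

test_that("conversion draws multinomial counts from expected rates", {
  cpg <- c(2, 2)
  ws <- windows_with_cpg(cpg)
  ct <- list(d_values = 0:2, beta_grid = seq(0, 1, 0.01),
             expected_nrpm = matrix(rep(seq(0, 1, 0.01), each = 3) * 100,
                                    3, 101, dimnames = list(0:2, NULL)),
             d_cap = 2L, beta_step = 0.01)
  class(ct) <- "CalibrationTable"
  wb <- setNames(c(0.75, 0.25), ws$window_id)
  n <- 1e4
  cnt <- convert_array(wb, ct, ws, library_size = n, seed = 42)
  expect_equal(sum(cnt), n)
  # expected (7500, 2500); binomial sd ~ sqrt(n * .75 * .25) = 43.3
  expect_lt(abs(cnt[1] - 7500), 3 * sqrt(n * 0.75 * 0.25))

  # determinism under the same seed
  expect_identical(cnt, convert_array(wb, ct, ws, n, seed = 42))

  # all-zero rates are an error
  expect_error(convert_array(setNames(c(0, 0), ws$window_id), ct, ws, n, 1),
               "zero")
})

test_that("conversion preserves rank within a density stratum", {
  set.seed(31)
  cpg <- rep(4, 50)
  ws <- windows_with_cpg(cpg)
  ct <- list(d_values = 0:4, beta_grid = seq(0, 1, 0.01),
             expected_nrpm = matrix(rep(seq(2, 102, length.out = 101),
                                        each = 5), 5, 101,
                                    dimnames = list(0:4, NULL)),
             d_cap = 4L, beta_step = 0.01)
  class(ct) <- "CalibrationTable"
  wb <- setNames(runif(50), ws$window_id)
  r <- expected_nrpm(ct, rep(4, 50), wb)
  expect_true(all(diff(r[order(wb)]) >= 0))
})

test_that("calibration table TSV round-trips", {
  cpg <- c(rep(0, 20), rep(2, 20), rep(5, 20))
  ws <- windows_with_cpg(cpg)
  set.seed(8)
  counts <- matrix(rpois(60, rep(c(5, 20, 60), each = 20)), ncol = 1,
                   dimnames = list(ws$window_id, "n1"))
  cm <- count_matrix(counts, ws, valid_totals = 1e5)
  beta <- matrix(runif(60), ncol = 1, dimnames = dimnames(counts))
  beta[cpg == 0] <- NA
  ct <- build_calibration(cm, beta, ws)
  p <- tempfile(fileext = ".tsv")
  write_calibration_tsv(ct, p)
  back <- read_calibration_tsv(p)
  expect_equal(unname(back$expected_nrpm), unname(ct$expected_nrpm),
               tolerance = 1e-9)
  expect_equal(as.integer(back$d_values), as.integer(ct$d_values))
})
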