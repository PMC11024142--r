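test_that("Hand-Till AUROC hits the degenerate endpoints", {
  sc <- rbind(c(0.9, 0.05, 0.05), c(0.8, 0.1, 0.1),
              c(0.05, 0.9, 0.05), c(0.1, 0.8, 0.1),
              c(0.05, 0.05, 0.9), c(0.1, 0.1, 0.8))
  colnames(sc) <- c("A", "B", "C")
  labels <- c("A", "A", "B", "B", "C", "C")
  expect_equal(hand_till_auroc(sc, labels), 1.0)

  flat <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(hand_till_auroc(flat, labels), 0.5)

  expect_error(hand_till_auroc(sc, c("A", "A", "A", "A", "A", "A")),
               ">= 2 classes")
})

test_that("Hand-Till equals the brute-force pair oracle on random instances", {
  set.seed(13)
  for (i in 1:60) {
    C <- sample(2:5, 1)
    n <- sample(C:30, 1)
    labels <- c(paste0("k", 1:C),
                sample(paste0("k", 1:C), max(n - C, 0), replace = TRUE))
    sc <- matrix(rexp(length(labels) * C), ncol = C,
                 dimnames = list(NULL, paste0("k", 1:C)))
    sc <- sc / rowSums(sc)
    if (i %% 5 == 0) sc[] <- round(sc, 1)  # force ties
    expect_equal(hand_till_auroc(sc, labels), oracle_hand_till(sc, labels),
                 tolerance = 1e-12)
  }
})

test_that("two-class Hand-Till equals the rank AUROC", {
  set.seed(14)
  for (i in 1:10) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    s <- c(rnorm(n1, 1), rnorm(n2))
    sc <- cbind(pos = plogis(s), neg = 1 - plogis(s))
    labels <- rep(c("pos", "neg"), c(n1, n2))
    r <- rank(s)
    wilcox_auc <- (sum(r[1:n1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    expect_equal(hand_till_auroc(sc, labels), wilcox_auc, tolerance = 1e-12)
  }
})

test_that("the call rule requires a majority score from a tumour class", {
  sc <- rbind(c(0.62, 0.2, 0.18), c(0.4, 0.35, 0.25), c(0.05, 0.05, 0.9))
  colnames(sc) <- c("LUAD", "BRCA", "NCC")
  expect_equal(unname(apply_call_rule(sc)),
               c("LUAD", "UNCLASSIFIED", "UNCLASSIFIED"))

  # at most one class can exceed 0.5 on a simplex; calls are unique
  set.seed(15)
  sim <- matrix(rexp(5000 * 4), ncol = 4,
                dimnames = list(NULL, c("A", "B", "C", "NCC")))
  sim <- sim / rowSums(sim)
  expect_true(all(rowSums(sim > 0.5) <= 1))
  calls <- apply_call_rule(sim)
  top <- colnames(sim)[max.col(sim)]
  expect_equal(calls == "UNCLASSIFIED",
               sim[cbind(seq_len(nrow(sim)), max.col(sim))] <= 0.5 |
                 top == "NCC")
})

test_that("evaluation reproduces the worked cohort arithmetic", {
  # 143 cancer samples: 121 correct, 4 incorrect, 18 unclassified; 27 controls
  truth <- c(rep("LUAD", 143), rep("NCC", 27))
  names(truth) <- paste0("s", seq_along(truth))
  call <- c(rep("LUAD", 121), rep("BRCA", 4), rep("UNCLASSIFIED", 18),
            rep("UNCLASSIFIED", 27))
  preds <- data.frame(sample_id = names(truth), call = call)
  ev <- evaluate_predictions(preds, truth)
  expect_equal(ev$n_total, 143)
  expect_equal(round(100 * ev$sensitivity, 1), 84.6)
  expect_equal(round(100 * ev$too_accuracy, 1), 96.8)
  expect_equal(round(100 * ev$unclassified_rate, 1), 12.6)
  expect_equal(round(100 * ev$incorrect_rate, 1), 2.8)
  expect_equal(ev$ncc_specificity, 1.0)
  expect_equal(ev$n_correct + ev$n_incorrect + ev$n_unclassified, ev$n_total)

  # all-correct degenerate case
  preds2 <- data.frame(sample_id = paste0("s", 1:5), call = "GBM")
  ev2 <- evaluate_predictions(preds2, setNames(rep("GBM", 5),
                                               paste0("s", 1:5)))
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$too_accuracy, 1)
})

test_that("training records stratified splits and is reproducible", {
  w <- tiny_mixture_world(seed = 16)
  params <- list(n_members = 3, trees = 20, max_depth = 3)
  m1 <- train_ensemble(w$mixtures, w$dmr_windows, params, seed = 4,
                       arrays = w$arrays, nccs = w$nccs)
  m2 <- train_ensemble(w$mixtures, w$dmr_windows, params, seed = 4,
                       arrays = w$arrays, nccs = w$nccs)
  expect_identical(m1$manifest, m2$manifest)
  expect_equal(length(m1$members), 3)
  for (mb in m1$members) {
    # 80% of 4 arrays per class = 3, stratified
    per_class <- table(w$arrays$class[match(mb$train_array_ids,
                                            w$arrays$sample_id)])
    expect_true(all(per_class == 3))
    expect_equal(length(mb$train_ncc_ids), 3)  # floor(0.8 * 4)
  }
  # member scores sum to one and the ensemble mean does too
  pr <- predict(m1, w$mixtures$counts)
  sc <- as.matrix(pr[, m1$classes])
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-9)
  expect_error(predict(m1, w$mixtures$counts, members = integer(0)),
               "empty member")
})

test_that("held-out eligibility matches a manifest walk", {
  w <- tiny_mixture_world(seed = 17)
  model <- train_ensemble(w$mixtures, w$dmr_windows,
                          list(n_members = 4, trees = 10, max_depth = 3),
                          seed = 6, arrays = w$arrays, nccs = w$nccs)
  held <- heldout_scores(model, w$mixtures)
  plan <- w$mixtures$plan
  for (i in seq_len(nrow(plan))) {
    elig <- vapply(model$members, function(mb) {
      used <- c(mb$train_array_ids, mb$train_ncc_ids)
      !(plan$component_a_id[i] %in% used) &&
        !(plan$component_b_id[i] %in% used)
    }, logical(1))
    expect_equal(held$n_eligible[i], sum(elig))
    if (any(elig)) {
      feats <- mixture_nrpm(w$mixtures$counts, model$feature_windows)
      ref <- Reduce(`+`, lapply(which(elig), function(m)
        predict(model$members[[m]]$model, feats)[i, ])) / sum(elig)
      expect_equal(unname(held$scores[i, ]), unname(ref), tolerance = 1e-12)
    } else {
      expect_true(all(is.na(held$scores[i, ])))
    }
  }
})

test_that("ensemble JSON serialisation round-trips predictions", {
  w <- tiny_mixture_world(seed = 18)
  model <- train_ensemble(w$mixtures, w$dmr_windows,
                          list(n_members = 2, trees = 10, max_depth = 3),
                          seed = 2, arrays = w$arrays, nccs = w$nccs)
  dir <- tempfile("model")
  save_ensemble(model, dir)
  back <- load_ensemble(dir)
  p1 <- predict(model, w$mixtures$counts)
  p2 <- predict(back, w$mixtures$counts)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("clinical consistency and broad categories count calls", {
  calls <- c("CHOL", "LUAD", "UNCLASSIFIED", "BRCA")
  accepted <- list(c("CHOL", "PAAD"), "LUSC", "LUAD", character(0))
  cc <- clinical_consistency(calls, accepted)
  expect_equal(cc$n_evaluable, 2)   # unclassified and empty-set rows drop out
  expect_equal(cc$n_consistent, 1)

  bc <- broad_category_fraction(c("CHOL", "GBM", "LUAD", "UNCLASSIFIED"),
                                default_broad_categories(),
                                unique(default_broad_categories()))
  expect_equal(bc$n_called, 3)
  expect_equal(bc$n_in_category, 2)
})
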