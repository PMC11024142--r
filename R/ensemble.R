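#' Train an ensemble of gradient-boosted sub-classifiers on mixtures
#'
#' Each of the `n_members` sub-classifiers trains only on mixtures whose
#' array component belongs to a per-member 80% subset of arrays (stratified
#' by class, so small classes are never orphaned) and whose NCC component
#' belongs to an unstratified 80% subset of NCCs. Features are NRPM values
#' over the DMR windows. Member splits and seeds are recorded exactly in the
#' training manifest so held-out scoring can identify eligible members.
#'
#' @param mixtures a `MixtureSet` from [simulate_mixtures()].
#' @param dmr_windows integer vector of feature window_ids.
#' @param params list overriding any of: `n_members` (100), `array_frac`
#'   (0.8), `ncc_frac` (0.8), `trees` (200), `row_subsample` (0.5),
#'   `feature_subsample_frac` (0.10) or `feature_subsample_count` (absolute
#'   override), `learning_rate` (0.3), `max_depth` (6), `max_retries` (20).
#' @param seed RNG seed governing all member splits and boosters.
#' @param arrays data.frame `sample_id`, `class` describing the array pool
#'   used in `mixtures$plan` (required to stratify splits); array samples with
#'   class `NCC` (e.g. normal-liver references) are stratified like any other
#'   class.
#' @param nccs character vector of NCC component ids.
#' @return an `EnsembleModel`: list with `members` (each holding `model`,
#'   `train_array_ids`, `train_ncc_ids`, `seed`), `feature_windows`,
#'   `classes`, `params`, `manifest`.
#' @export
train_ensemble <- function(mixtures, dmr_windows, params = list(), seed = 1,
                           arrays, nccs) {
  p <- utils::modifyList(list(n_members = 100, array_frac = 0.8,
                              ncc_frac = 0.8, trees = 200,
                              row_subsample = 0.5,
                              feature_subsample_frac = 0.10,
                              feature_subsample_count = NULL,
                              learning_rate = 0.3, max_depth = 6,
                              max_retries = 20), params)
  plan <- mixtures$plan
  labels <- mixtures$labels
  classes <- sort(unique(labels))
  feats <- mixture_nrpm(mixtures$counts, dmr_windows)
  colnames(feats) <- paste0("w", dmr_windows)
  n_feat_sub <- if (!is.null(p$feature_subsample_count))
    p$feature_subsample_count else max(1L, round(p$feature_subsample_frac *
                                                   length(dmr_windows)))
  members <- vector("list", p$n_members)
  base_seed <- as.integer(seed %% 1e8)
  for (m in seq_len(p$n_members)) {
    ok <- FALSE
    for (try_ in seq_len(p$max_retries)) {
      split_seed <- base_seed + m * 1000L + try_
      picked <- with_seed(split_seed, {
        arr_ids <- unlist(lapply(split(arrays$sample_id, arrays$class),
                                 function(ids) {
          k <- max(1L, floor(p$array_frac * length(ids)))
          sample(ids, k)
        }), use.names = FALSE)
        ncc_ids <- sample(nccs, max(2L, floor(p$ncc_frac * length(nccs))))
        list(arr = arr_ids, ncc = ncc_ids)
      })
      in_train <- plan$component_a_id %in% c(picked$arr, picked$ncc) &
        plan$component_b_id %in% picked$ncc
      if (all(classes %in% labels[in_train])) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a split covering every class for member ", m)
    model <- gbt_fit(feats[in_train, , drop = FALSE], labels[in_train],
                     n_rounds = p$trees, learning_rate = p$learning_rate,
                     max_depth = p$max_depth, subsample = p$row_subsample,
                     colsample_count = n_feat_sub, seed = split_seed + 7L)
    members[[m]] <- list(model = model, train_array_ids = sort(picked$arr),
                         train_ncc_ids = sort(picked$ncc),
                         seed = split_seed)
  }
  manifest <- list(seed = seed, params = p, classes = classes,
                   n_features = length(dmr_windows),
                   feature_subsample_count = n_feat_sub,
                   n_mixtures = ncol(mixtures$counts),
                   member_splits = lapply(members, function(mb)
                     list(train_array_ids = mb$train_array_ids,
                          train_ncc_ids = mb$train_ncc_ids,
                          seed = mb$seed)))
  em <- list(members = members, feature_windows = dmr_windows,
             classes = classes, params = p, manifest = manifest)
  class(em) <- "EnsembleModel"
  em
}

#' Score samples with the ensemble and apply the call rule
#'
#' Per-class scores are the mean of the (optionally filtered) member
#' probability vectors; because each member's scores sum to one, so does the
#' mean, and at most one class can exceed 0.5. A tumour class is called when
#' its mean score exceeds 0.5; otherwise -- including when the non-cancer
#' (NCC) class wins -- the sample is UNCLASSIFIED.
#'
#' @param object an `EnsembleModel`.
#' @param newdata windows x samples count matrix (rownames = window_id)
#'   covering the model's feature windows, or a precomputed samples x
#'   features NRPM matrix (set `is_nrpm = TRUE`).
#' @param members optional integer vector of member indices to average.
#' @param is_nrpm whether `newdata` is already an NRPM feature matrix.
#' @param ncc_class name of the neutral class (default "NCC").
#' @param ... unused.
#' @return a `PredictionResult` data.frame: `sample_id`, one score column per
#'   class, `call`.
#' @export
predict.EnsembleModel <- function(object, newdata, members = NULL,
                                  is_nrpm = FALSE, ncc_class = "NCC", ...) {
  if (!is.null(members) && length(members) == 0) stop("empty member filter")
  idx <- if (is.null(members)) seq_along(object$members) else members
  feats <- if (is_nrpm) as.matrix(newdata)
           else mixture_nrpm(newdata, object$feature_windows)
  acc <- 0
  for (m in idx) acc <- acc + predict(object$members[[m]]$model, feats)
  scores <- acc / length(idx)
  calls <- apply_call_rule(scores, ncc_class)
  res <- data.frame(sample_id = rownames(feats) %||%
                      paste0("sample", seq_len(nrow(feats))),
                    scores, call = calls,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(res) <- NULL
  class(res) <- c("PredictionResult", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the score-to-call rule to a score matrix
#'
#' @param scores samples x classes matrix, rows summing to 1.
#' @param ncc_class neutral class name whose win means UNCLASSIFIED.
#' @return character vector of calls.
#' @export
apply_call_rule <- function(scores, ncc_class = "NCC") {
  apply(scores, 1, function(s) {
    top <- which.max(s)
    cls <- colnames(scores)[top]
    if (s[top] > 0.5 && cls != ncc_class) cls else "UNCLASSIFIED"
  })
}

#' Held-out scores for mixtures
#'
#' For every mixture, averages only the members that used neither of its
#' components for training. Mixtures with no eligible member get NA scores
#' and are listed in the `no_eligible` attribute.
#'
#' @param model an `EnsembleModel`.
#' @param mixtures a `MixtureSet` on the model's window universe.
#' @return list with `scores` (mixtures x classes), `n_eligible` per mixture,
#'   `labels`.
#' @export
heldout_scores <- function(model, mixtures) {
  feats <- mixture_nrpm(mixtures$counts, model$feature_windows)
  member_scores <- lapply(model$members, function(mb)
    predict(mb$model, feats))
  plan <- mixtures$plan
  nmix <- nrow(plan)
  K <- length(model$classes)
  scores <- matrix(NA_real_, nmix, K,
                   dimnames = list(colnames(mixtures$counts), model$classes))
  n_eligible <- integer(nmix)
  used <- lapply(model$members, function(mb)
    c(mb$train_array_ids, mb$train_ncc_ids))
  for (i in seq_len(nmix)) {
    a <- plan$component_a_id[i]; b <- plan$component_b_id[i]
    elig <- which(vapply(used, function(u) !(a %in% u) && !(b %in% u),
                         logical(1)))
    n_eligible[i] <- length(elig)
    if (length(elig)) {
      acc <- 0
      for (m in elig) acc <- acc + member_scores[[m]][i, ]
      scores[i, ] <- acc / length(elig)
    }
  }
  list(scores = scores, n_eligible = n_eligible, labels = mixtures$labels)
}

#' Hand-Till multi-class AUROC
#'
#' M = 2 / (C (C - 1)) * sum over unordered class pairs of
#' (A(i|j) + A(j|i)) / 2, where A(i|j) is the probability that a random
#' class-i sample receives a higher class-i score than a random class-j
#' sample (ties count one half). Equals the usual rank AUROC when C = 2.
#'
#' @param scores samples x classes score matrix (column names = classes).
#' @param labels per-sample true class labels.
#' @return scalar in \[0, 1\].
#' @export
hand_till_auroc <- function(scores, labels) {
  classes <- colnames(scores)
  stopifnot(!is.null(classes))
  present <- unique(labels)
  if (!all(present %in% classes)) stop("labels absent from score columns")
  use <- classes[classes %in% present]
  if (length(use) < 2) stop("need >= 2 classes with samples")
  total <- 0
  npair <- 0
  for (i in seq_along(use)) {
    for (j in seq_along(use)) {
      if (j <= i) next
      a_ij <- pair_auc(scores[labels == use[i], use[i]],
                       scores[labels == use[j], use[i]])
      a_ji <- pair_auc(scores[labels == use[j], use[j]],
                       scores[labels == use[i], use[j]])
      total <- total + (a_ij + a_ji) / 2
      npair <- npair + 1
    }
  }
  total / npair
}

# P(score_pos > score_neg) + 0.5 P(equal), via midranks (Mann-Whitney)
pair_auc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Summarise classifier calls against truth labels
#'
#' Cancer samples (truth != `ncc_class`) are counted as correct (call equals
#' truth), incorrect (a different tumour class was called) or unclassified.
#' Sensitivity is correct / all cancer samples; TOO accuracy is correct /
#' samples with a tumour call; NCC specificity is the fraction of NCC-truth
#' samples left UNCLASSIFIED. A truth label outside the model's class list
#' counts as incorrect only if a tumour call was made.
#'
#' @param predictions a `PredictionResult` (or data.frame with `sample_id`,
#'   `call`).
#' @param truth named character vector or data.frame (`sample_id`, `class`).
#' @param ncc_class neutral class name.
#' @return an `EvaluationSummary` list.
#' @export
evaluate_predictions <- function(predictions, truth, ncc_class = "NCC") {
  if (is.data.frame(truth))
    truth <- stats::setNames(truth$class, truth$sample_id)
  tr <- truth[predictions$sample_id]
  if (anyNA(tr)) stop("missing truth labels")
  call <- predictions$call
  is_ncc <- tr == ncc_class
  cc <- call[!is_ncc]; tt <- tr[!is_ncc]
  n_total <- length(cc)
  n_unclassified <- sum(cc == "UNCLASSIFIED")
  n_correct <- sum(cc == tt)
  n_incorrect <- n_total - n_correct - n_unclassified
  n_called <- n_correct + n_incorrect
  out <- list(
    n_total = n_total, n_correct = n_correct, n_incorrect = n_incorrect,
    n_unclassified = n_unclassified,
    sensitivity = if (n_total) n_correct / n_total else NA_real_,
    too_accuracy = if (n_called) n_correct / n_called else NA_real_,
    unclassified_rate = if (n_total) n_unclassified / n_total else NA_real_,
    incorrect_rate = if (n_total) n_incorrect / n_total else NA_real_,
    prediction_rate = if (n_total) n_called / n_total else NA_real_,
    ncc_specificity = if (any(is_ncc))
      mean(call[is_ncc] == "UNCLASSIFIED") else NA_real_,
    n_ncc = sum(is_ncc))
  class(out) <- "EvaluationSummary"
  out
}

#' @export
print.EvaluationSummary <- function(x, ...) {
  cat(sprintf(
    "samples: %d cancer, %d control\ncorrect %d | incorrect %d | unclassified %d\n",
    x$n_total, x$n_ncc, x$n_correct, x$n_incorrect, x$n_unclassified))
  cat(sprintf("sensitivity %.1f%% | TOO accuracy %.1f%% | unclassified %.1f%%\n",
              100 * x$sensitivity, 100 * x$too_accuracy,
              100 * x$unclassified_rate))
  if (!is.na(x$ncc_specificity))
    cat(sprintf("NCC specificity %.1f%%\n", 100 * x$ncc_specificity))
  invisible(x)
}

#' Fraction of tumour calls agreeing with per-sample accepted diagnoses
#'
#' A call is consistent when it appears in the sample's accepted set (e.g. a
#' confirmed primary or any clinically suspected diagnosis). Samples without
#' a tumour call, or with an empty accepted set, are excluded from the
#' denominator.
#'
#' @param calls character vector of calls (UNCLASSIFIED allowed).
#' @param accepted list (same length) of character vectors of acceptable
#'   classes per sample.
#' @return list `n_evaluable`, `n_consistent`, `consistency`.
#' @export
clinical_consistency <- function(calls, accepted) {
  stopifnot(length(calls) == length(accepted))
  eval_ix <- which(calls != "UNCLASSIFIED" & lengths(accepted) > 0)
  hits <- vapply(eval_ix, function(i) calls[i] %in% accepted[[i]], logical(1))
  list(n_evaluable = length(eval_ix), n_consistent = sum(hits),
       consistency = if (length(eval_ix)) mean(hits) else NA_real_)
}

#' Fraction of tumour calls falling in a set of broad categories
#'
#' @param calls character vector of calls (UNCLASSIFIED excluded from the
#'   denominator).
#' @param category_map named character vector mapping class -> broad category
#'   (classes absent from the map count as outside every category).
#' @param categories character vector of category names of interest.
#' @return list `n_called`, `n_in_category`, `fraction`.
#' @export
broad_category_fraction <- function(calls, category_map, categories) {
  called <- calls[calls != "UNCLASSIFIED"]
  inside <- category_map[called] %in% categories
  list(n_called = length(called), n_in_category = sum(inside),
       fraction = if (length(called)) mean(inside) else NA_real_)
}

#' Save / load an ensemble model as a JSON directory
#'
#' The model directory holds `manifest.json` plus one JSON file per member
#' (tree arrays are plain numeric vectors), so models are portable text.
#'
#' @param model an `EnsembleModel`.
#' @param dir output directory (created if needed).
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(classes = model$classes, feature_windows = model$feature_windows,
         params = model$params, manifest = model$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  for (m in seq_along(model$members)) {
    mb <- model$members[[m]]
    jsonlite::write_json(
      list(train_array_ids = mb$train_array_ids,
           train_ncc_ids = mb$train_ncc_ids, seed = mb$seed,
           classes = mb$model$classes, n_features = mb$model$n_features,
           params = mb$model$params, booster = mb$model$booster),
      file.path(dir, sprintf("member%03d.json", m)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^member[0-9]+\\.json$",
                           full.names = TRUE))
  members <- lapply(files, function(f) {
    j <- jsonlite::read_json(f, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
    booster <- list(trees = lapply(j$booster$trees, function(tr)
      list(feature = as.integer(tr$feature), threshold = tr$threshold,
           left = as.integer(tr$left), right = as.integer(tr$right),
           value = tr$value)),
      n_classes = as.integer(j$booster$n_classes),
      n_rounds = as.integer(j$booster$n_rounds))
    model <- list(booster = booster, classes = j$classes,
                  n_features = j$n_features, feature_names = NULL,
                  params = j$params)
    class(model) <- "gbt_model"
    list(model = model, train_array_ids = j$train_array_ids,
         train_ncc_ids = j$train_ncc_ids, seed = j$seed)
  })
  em <- list(members = members,
             feature_windows = as.integer(man$feature_windows),
             classes = man$classes, params = man$params,
             manifest = man$manifest)
  class(em) <- "EnsembleModel"
  em
}

#' Default class-to-broad-category map
#'
#' Groups classifier classes into the five broad cancer categories most
#' often predicted in cancers of unknown primary: hepato-pancreatobiliary,
#' female genital tract, gastrointestinal, lung and urological. Classes
#' absent from the table belong to no broad category.
#'
#' @return named character vector (class -> category).
#' @export
default_broad_categories <- function() {
  path <- system.file("extdata", "broad_categories.tsv", package = "mbdtoo")
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  stats::setNames(df$category, df$cupid_class)
}
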