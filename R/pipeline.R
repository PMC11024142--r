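#' Default pipeline configuration
#'
#' Desk-scale settings: the synthetic toy world, mixture depth bounds of
#' 1e4-1e5 fragments (published-scale bounds of 1e6-1e7 are impractical on a
#' laptop and carry no extra structure), 10 ensemble members. Any field can
#' be overridden from a YAML file or a named list.
#'
#' @param ... overrides.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = NULL,
    synthetic = list(),                 # synthetic_config() overrides
    library_size = 5e4,                 # fragments per converted array
    mixtures = list(per_class_cap = 10000,
                    tumour_range = c(0.005, 0.10),
                    ncc_range = c(0.15, 0.50),
                    depth_range = c(1e4, 1e5),
                    n_repeats = 10),
    dmr = list(fdr = 0.001, n_top = 250),
    ensemble = list(n_members = 10, trees = 200, row_subsample = 0.5,
                    feature_subsample_frac = 0.10, array_frac = 0.8,
                    ncc_frac = 0.8),
    qc = list(relH_min = 2.5, hf_min = 0.4))
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; unknown keys are an error.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  bad <- setdiff(names(raw), names(base))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  utils::modifyList(base, raw)
}

#' Run the full pipeline on the synthetic toy world
#'
#' Stages, in order: reference/tiling, NCC fragment simulation and counting,
#' over-representation masking, QC gating, array generation and window-beta
#' collapse, calibration table, array-to-count conversion, mixture planning
#' and simulation, DMR selection, ensemble training, held-out scoring and
#' evaluation. Artifacts are written under `config$out_dir` (if set) together
#' with a JSON run manifest sufficient to re-run any stage bit-identically.
#'
#' @param config list from [default_pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML file.
#' @param quiet suppress progress messages.
#' @return invisible list with all stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  t0 <- Sys.time()

  say("[1/9] reference and tiling")
  scfg <- do.call(synthetic_config,
                  utils::modifyList(list(seed = seed), config$synthetic))
  ref <- make_reference(scfg)
  windows <- ref$windows

  say("[2/9] NCC fragments, counting, masking")
  frags_raw <- make_ncc_fragments(scfg, ref)
  frags <- lapply(frags_raw, filter_fragments)
  cm <- assign_counts(frags, windows)
  mask <- find_overrepresented(windows, rowSums(cm$counts))
  windows <- mask_windows(windows, mask)
  cm$windows <- windows

  say("[3/9] NCC beta calibration and QC")
  ncc_nrpm <- nrpm(cm)
  ncc_beta <- calibrate_beta(ncc_nrpm, windows)
  ncc_sim <- make_ncc_counts(scfg, windows)
  panel <- ncc_sim$hyperstable_panel
  qc <- qc_report(frags, ncc_beta, panel, ref$genome,
                  relH_min = config$qc$relH_min, hf_min = config$qc$hf_min)
  keep_ncc <- qc$sample_id[qc$pass]
  if (length(keep_ncc) < 2) stop("stage qc: fewer than 2 NCC samples pass")

  say("[4/9] synthetic arrays and window betas")
  arr <- make_class_arrays(scfg, windows)
  win_beta <- probe_to_window_beta(arr$arrays, windows)

  say("[5/9] calibration table")
  calib <- build_calibration(cm, ncc_beta, windows)

  say("[6/9] array conversion")
  probe_windows <- as.integer(rownames(win_beta))
  profiles <- list()
  for (s in seq_len(ncol(win_beta))) {
    profiles[[colnames(win_beta)[s]]] <-
      convert_array(stats::setNames(win_beta[, s], rownames(win_beta)),
                    calib, windows, config$library_size,
                    seed = seed + 7000 + s)
  }
  for (s in keep_ncc) {
    v <- cm$counts[match(probe_windows, cm$window_ids), s]
    names(v) <- probe_windows
    profiles[[s]] <- v
  }

  say("[7/9] mixtures")
  plan <- plan_mixtures(arr$samples, keep_ncc, seed = seed + 500,
                        per_class_cap = config$mixtures$per_class_cap,
                        tumour_range = config$mixtures$tumour_range,
                        ncc_range = config$mixtures$ncc_range,
                        depth_range = config$mixtures$depth_range,
                        ncc_totals = cm$valid_totals,
                        n_repeats = config$mixtures$n_repeats)
  sub_windows <- windows[match(probe_windows, windows$window_id), ,
                         drop = FALSE]
  mixtures <- simulate_mixtures(plan, profiles, sub_windows)

  say("[8/9] DMR selection")
  catalog <- pairwise_dmrs(win_beta, arr$samples$class,
                           fdr = config$dmr$fdr, n_top = config$dmr$n_top)
  dmr_windows <- dedupe_regions(catalog)
  if (length(dmr_windows) < 2) stop("stage dmr: fewer than 2 DMR windows")

  say("[9/9] ensemble training and held-out evaluation")
  model <- train_ensemble(mixtures, dmr_windows, params = config$ensemble,
                          seed = seed + 900, arrays = arr$samples,
                          nccs = keep_ncc)
  held <- heldout_scores(model, mixtures)
  ok <- held$n_eligible > 0
  auroc <- hand_till_auroc(held$scores[ok, , drop = FALSE], held$labels[ok])
  calls <- apply_call_rule(held$scores[ok, , drop = FALSE])
  preds <- data.frame(sample_id = rownames(held$scores)[ok], call = calls,
                      stringsAsFactors = FALSE)
  summary <- evaluate_predictions(
    preds, stats::setNames(held$labels[ok], rownames(held$scores)[ok]))

  manifest <- list(
    created = format(t0),
    package_version = as.character(utils::packageVersion("mbdtoo")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    n_windows = nrow(windows), n_masked = sum(windows$masked),
    n_ncc = length(keep_ncc), qc = qc,
    n_arrays = nrow(arr$samples), classes = sort(unique(arr$samples$class)),
    n_probe_windows = length(probe_windows),
    n_mixtures = ncol(mixtures$counts),
    n_dmr_windows = length(dmr_windows),
    n_members = length(model$members),
    heldout_auroc = auroc,
    heldout_summary = unclass(summary),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(config = config, windows = windows, mask = mask,
                 ncc_counts = cm, ncc_beta = ncc_beta, qc = qc,
                 arrays = arr, win_beta = win_beta, calibration = calib,
                 mixtures = mixtures, dmr_catalog = catalog,
                 dmr_windows = dmr_windows, model = model,
                 heldout = held, auroc = auroc, summary = summary,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_windows_bed(windows, file.path(config$out_dir, "windows.bed"))
    data.table::fwrite(qc, file.path(config$out_dir, "qc.tsv"), sep = "\t")
    write_matrix_tsv(mixtures$counts,
                     file.path(config$out_dir, "mixture_counts.tsv"))
    data.table::fwrite(mixtures$plan,
                       file.path(config$out_dir, "mixture_plan.tsv"),
                       sep = "\t")
    data.table::fwrite(as.data.frame(catalog),
                       file.path(config$out_dir, "dmr_catalog.tsv"),
                       sep = "\t")
    writeLines(as.character(dmr_windows),
               file.path(config$out_dir, "dmr_windows.txt"))
    arts <- list.files(config$out_dir, full.names = TRUE)
    manifest$artifact_md5 <- as.list(tools::md5sum(
      arts[!grepl("manifest\\.json$", arts)]))
    names(manifest$artifact_md5) <- basename(names(manifest$artifact_md5))
    result$manifest <- manifest
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(result)
}
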