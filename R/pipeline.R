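#' Default pipeline configuration
#'
#' Returns the full nested configuration list consumed by
#' [run_pipeline()]: simulation design parameters, preprocessing settings,
#' MCR settings, classification schemes and ensemble sizes, and statistics
#' options, plus one global seed from which every stage derives its own.
#'
#' @param seed Global integer seed.
#' @return Named list, also obtainable from / serializable to YAML or JSON.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthdata = list(
      enabled = TRUE,
      spectra_per_mouse = 235,
      spectra_per_mouse_sd = 25,
      between_sd = 0.05,
      within_sd = 0.08,
      baseline_scale = 1,
      noise_sd = 0.01,
      external = TRUE
    ),
    preprocess = list(
      crop_lo = 600, crop_hi = 1800,
      poly_order = 5, max_iter = 200, tol = 1e-4,
      median_window = 5
    ),
    mcr = list(k = 5, init = "purest", max_iter = 500, tol = 1e-6,
               min_cosine = 0.7),
    classify = list(
      schemes = c("multiclass", "intravasation", "extravasation", "growth"),
      n_trees = 100, n_balance_iter = 100
    ),
    stats = list(component = "lipid_like", reference_group = "67NR",
                 alpha = 0.05)
  )
}

validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in intersect(names(config), setdiff(names(ref), "seed"))) {
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  merged <- utils::modifyList(ref, config)
  known_schemes <- c("multiclass", "intravasation", "extravasation", "growth")
  bad_scheme <- setdiff(merged$classify$schemes, known_schemes)
  if (length(bad_scheme) > 0) {
    stop("unknown classification scheme(s): ",
         paste(bad_scheme, collapse = ", "))
  }
  merged
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Validated configuration list (unknown keys are rejected).
#' @export
read_config <- function(path) {
  config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(config)
}

pipeline_log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> preprocess -> MCR decomposition ->
#' classification (all configured schemes) -> importance -> statistics, and
#' writes every stage's output plus a manifest (parameters, seeds, content
#' hashes) into `out_dir`, so a run is exactly reproducible from
#' `(config, seed)`.
#'
#' @param config Configuration list (see [default_config()]); validated
#'   before any compute.
#' @param out_dir Output directory (created if needed).
#' @param dataset Optional pre-made [spectra_dataset()]; required when
#'   `config$synthdata$enabled` is `FALSE`.
#' @param external Optional external [spectra_dataset()].
#' @return Invisibly, a list with the principal in-memory results
#'   (`dataset`, `model`, `lomo` per scheme, `importance`, `stats`,
#'   `external_predictions`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run_"),
                         dataset = NULL, external = NULL) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  library <- build_component_library()
  truth <- NULL

  if (isTRUE(config$synthdata$enabled)) {
    sd_cfg <- config$synthdata
    design <- cohort_design(
      between_sd = sd_cfg$between_sd, within_sd = sd_cfg$within_sd,
      spectra_per_mouse = sd_cfg$spectra_per_mouse,
      spectra_per_mouse_sd = sd_cfg$spectra_per_mouse_sd,
      baseline_scale = sd_cfg$baseline_scale, noise_sd = sd_cfg$noise_sd,
      seed = derive_seed(seed, 1L)
    )
    sim <- simulate_cohort(design, library)
    dataset <- sim$dataset
    truth <- sim$truth
    pipeline_log("INFO", "simulated %d spectra x %d channels",
                 nrow(dataset$intensities), length(dataset$wavenumbers))
    if (isTRUE(sd_cfg$external) && is.null(external)) {
      ext <- simulate_external_cohort(default_external_shifts(), library,
                                      design, seed = derive_seed(seed, 2L))
      external <- ext$dataset
      pipeline_log("INFO", "simulated external cohort: %d spectra",
                   nrow(external$intensities))
    }
    write_dataset(dataset, file.path(out_dir, "raw_spectra.tsv"),
                  file.path(out_dir, "raw_meta.tsv"))
  }
  if (is.null(dataset)) {
    stop("no dataset: enable synthdata or pass one explicitly")
  }

  pp <- config$preprocess
  clean <- preprocess_dataset(dataset, pp$crop_lo, pp$crop_hi, pp$poly_order,
                              pp$max_iter, pp$tol, pp$median_window)
  pipeline_log("INFO", "preprocessed %d spectra", nrow(clean$intensities))
  clean_ext <- NULL
  if (!is.null(external)) {
    clean_ext <- preprocess_dataset(external, pp$crop_lo, pp$crop_hi,
                                    pp$poly_order, pp$max_iter, pp$tol,
                                    pp$median_window)
  }

  model <- fit_mcr_als(clean, k = config$mcr$k, init = config$mcr$init,
                       max_iter = config$mcr$max_iter, tol = config$mcr$tol,
                       seed = derive_seed(seed, 3L))
  model <- label_components(model, library,
                            min_cosine = config$mcr$min_cosine)
  pipeline_log("INFO", "MCR-ALS: LOF %.2f%% after %d iterations",
               utils::tail(model$lof_history, 1), length(model$lof_history))
  comp_tsv <- data.frame(wavenumber_cm1 = model$wavenumbers, t(model$S))
  utils::write.table(comp_tsv, file.path(out_dir, "mcr_components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(spectrum_id = rownames(model$C), model$C),
    file.path(out_dir, "mcr_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  lomo <- list()
  metrics <- list()
  for (si in seq_along(config$classify$schemes)) {
    sch_name <- config$classify$schemes[si]
    labeled <- make_labels(clean, label_scheme(sch_name))
    res <- lomo_random_forest(labeled,
                              n_trees = config$classify$n_trees,
                              n_balance_iter = config$classify$n_balance_iter,
                              seed = derive_seed(seed, 10L + si))
    lomo[[sch_name]] <- res
    metrics[[sch_name]] <- confusion_metrics(res)
    pipeline_log("INFO", "LOMO %s: accuracy %.1f%%", sch_name,
                 metrics[[sch_name]]$accuracy)
    utils::write.table(res$mouse,
                       file.path(out_dir, sprintf("lomo_%s.tsv", sch_name)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  labeled_mc <- make_labels(clean, label_scheme("multiclass"))
  imp <- feature_importance(labeled_mc, n_trees = config$classify$n_trees,
                            seed = derive_seed(seed, 20L))
  peaks <- top_peaks(imp)
  utils::write.table(imp, file.path(out_dir, "importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ext_pred <- NULL
  if (!is.null(clean_ext)) {
    ext_pred <- train_full_predict_external(
      labeled_mc, clean_ext,
      n_trees = config$classify$n_trees,
      n_balance_iter = config$classify$n_balance_iter,
      seed = derive_seed(seed, 21L)
    )
    utils::write.table(ext_pred, file.path(out_dir, "external_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  stat_cfg <- config$stats
  stats_out <- compare_scores(score_table(model, clean),
                              component = stat_cfg$component,
                              reference_group = stat_cfg$reference_group,
                              alpha = stat_cfg$alpha)
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    config = config,
    n_spectra = nrow(clean$intensities),
    n_channels = length(clean$wavenumbers),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, truth = truth, clean = clean,
                 model = model, lomo = lomo, metrics = metrics,
                 importance = imp, peaks = peaks,
                 external_predictions = ext_pred, stats = stats_out,
                 manifest = manifest, out_dir = out_dir))
}
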