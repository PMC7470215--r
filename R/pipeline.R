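#' Pipeline run configuration
#'
#' One flat, text-serializable set of parameters covering every stage of
#' the phantom -> preprocess -> feature selection -> classification ->
#' report chain. Every stochastic stage derives its own sub-seed from
#' `seed` and its stage name via [derive_seed()], so enabling or disabling
#' one stage never shifts another stage's random stream.
#'
#' @param seed global integer seed.
#' @param n_samples number of phantom samples (default 4).
#' @param frame_size frame side in pixels (default 256).
#' @param mosaic_rows,mosaic_cols mosaic grid (default 2 x 2).
#' @param axis_step wavenumber sampling step in cm^-1 (default 10).
#' @param noise_sigma detector noise sd in volts (default 0.005).
#' @param biological_cv intra-class tissue heterogeneity CV (default 0.10).
#' @param separation phantom class-contrast dial (default 1).
#' @param illum_corr apply flat-field correction (default TRUE).
#' @param block_size block averaging size (default 4; must divide
#'   `frame_size`).
#' @param rfe_k wavenumbers to keep after RFE (default 4, the sweep
#'   optimum of the original study).
#' @param min_distance RFE distance constraint in cm^-1 (default 40).
#' @param subsample_cap per-class training cap (default 30000).
#' @param rfe_cap per-class cap during RFE ranking (default 1500, a
#'   desk-scale stand-in for the full-cap ranking).
#' @param folds cross-validation folds (default 3, group-aware).
#' @param out_dir output directory (default `"carsdelin_run"`).
#' @param stages character vector of enabled stages, subset of
#'   `c("phantom", "preprocess", "featsel", "classify", "report")`.
#' @return validated list of class `"RunConfig"`.
#' @export
run_config <- function(seed = 1L, n_samples = 4L, frame_size = 256L,
                       mosaic_rows = 2L, mosaic_cols = 2L, axis_step = 10,
                       noise_sigma = 0.005, biological_cv = 0.10,
                       separation = 1,
                       illum_corr = TRUE, block_size = 4L, rfe_k = 4L,
                       min_distance = 40, subsample_cap = 30000L,
                       rfe_cap = 1500L, folds = 3L,
                       out_dir = "carsdelin_run",
                       stages = c("phantom", "preprocess", "featsel",
                                  "classify", "report")) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              frame_size = as.integer(frame_size),
              mosaic_rows = as.integer(mosaic_rows),
              mosaic_cols = as.integer(mosaic_cols),
              axis_step = axis_step, noise_sigma = noise_sigma,
              biological_cv = biological_cv,
              separation = separation, illum_corr = isTRUE(illum_corr),
              block_size = as.integer(block_size),
              rfe_k = as.integer(rfe_k), min_distance = min_distance,
              subsample_cap = as.integer(subsample_cap),
              rfe_cap = as.integer(rfe_cap), folds = as.integer(folds),
              out_dir = out_dir, stages = stages)
  validate_run_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_run_config <- function(cfg) {
  if (cfg$frame_size %% cfg$block_size != 0)
    stop("block_size ", cfg$block_size, " does not divide frame_size ",
         cfg$frame_size)
  if (cfg$n_samples < 1) stop("n_samples must be >= 1")
  bad <- setdiff(cfg$stages, c("phantom", "preprocess", "featsel",
                               "classify", "report"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Write/read a run configuration as plain-text `key = value` lines
#'
#' Round-trips losslessly (numbers at full precision, vectors
#' comma-separated).
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path` / the configuration.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) paste(v, collapse = ",")
    else if (is.logical(v)) ifelse(v, "true", "false")
    else paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
               collapse = ",")
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  defaults <- run_config()
  cfg <- as.list(defaults)
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- strsplit(vals[i], ",")[[1]]
    cfg[[k]] <- if (k %in% c("out_dir", "stages")) v
                else if (all(v %in% c("true", "false"))) v == "true"
                else as.numeric(v)
  }
  do.call(run_config, cfg[names(as.list(defaults))])
}

phantom_config_from_run <- function(cfg, i) {
  phantom_config(frame_size = cfg$frame_size,
                 mosaic_grid = c(cfg$mosaic_rows, cfg$mosaic_cols),
                 axis = default_axis(cfg$axis_step),
                 noise_model = list(sigma = cfg$noise_sigma, signal_coef = 0,
                                    biological_cv = cfg$biological_cv),
                 separation = cfg$separation,
                 sample_id = sprintf("sample%02d", i),
                 seed = derive_seed(cfg$seed, paste0("phantom", i)))
}

preprocess_sample <- function(phantom, cfg) {
  st <- subtract_offset(phantom$stack, phantom$calibration)
  st <- power_calibrate(st, phantom$calibration)
  if (cfg$illum_corr) {
    fld <- estimate_illumination(st)
    st <- correct_illumination(st, fld)
  }
  block_average(stitch(st), phantom$label_map, cfg$block_size)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on freshly generated phantom
#' samples, evaluates the classifier by sample-level (group-aware)
#' cross-validation, writes all artifacts plus a manifest with content
#' digests under `config$out_dir`, and returns the key objects. Identical
#' configurations (including the seed) reproduce identical artifact
#' digests.
#'
#' @param config a [run_config()].
#' @return list of class `"PipelineRun"`: `table`, `feature_set`,
#'   `metrics`, `sample_calls`, `manifest` (invisible artifacts on disk).
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list(), outputs = list())
  table <- NULL; fs <- NULL; metrics <- NULL; calls <- NULL

  if (all(c("phantom", "preprocess") %in% config$stages)) {
    tables <- vector("list", config$n_samples)
    for (i in seq_len(config$n_samples)) {
      ph <- generate_phantom(phantom_config_from_run(config, i))
      tables[[i]] <- preprocess_sample(ph, config)
    }
    table <- do.call(rbind, tables)
    attr(table, "axis") <- attr(tables[[1]], "axis")
    class(table) <- c("SpectrumTable", "data.frame")
    tab_path <- file.path(config$out_dir, "spectrum_table.csv")
    write_spectrum_table(table, tab_path)
    manifest$outputs$spectrum_table <- tab_path
    manifest$stages$phantom <- list(
      n_samples = config$n_samples,
      seeds = vapply(seq_len(config$n_samples), function(i)
        derive_seed(config$seed, paste0("phantom", i)), integer(1)))
    manifest$stages$preprocess <- list(illum_corr = config$illum_corr,
                                       block_size = config$block_size)
  }

  if ("featsel" %in% config$stages) {
    if (is.null(table)) stop("featsel stage needs the preprocess stage")
    rk <- rfe_rank(table, cap = config$rfe_cap,
                   seed = derive_seed(config$seed, "rfe"))
    fs <- apply_distance_constraint(rk, config$rfe_k, config$min_distance)
    fs_path <- file.path(config$out_dir, "feature_set.json")
    write_feature_set(fs, fs_path)
    manifest$outputs$feature_set <- fs_path
    manifest$stages$featsel <- list(rfe_k = config$rfe_k,
                                    min_distance = config$min_distance)
  }

  if ("classify" %in% config$stages) {
    if (is.null(fs)) stop("classify stage needs the featsel stage")
    train <- subsample_training(table, cap = config$subsample_cap,
                                seed = derive_seed(config$seed, "subsample"))
    res <- cv_ensemble_accuracy(train, fs$wavenumbers,
                                folds = config$folds,
                                seed = derive_seed(config$seed, "cv"),
                                group_aware = TRUE,
                                return_predictions = TRUE)
    metrics <- compute_metrics(res$predictions, res$truth)
    calls <- vapply(unique(train$sample_id), function(sid) {
      as.character(call_sample(res$predictions[train$sample_id == sid]))
    }, character(1))
    ens <- train_ensemble(train, fs,
                          default_pair_specs(
                            names(tissue_classes())[sort(unique(train$label))]),
                          seed = derive_seed(config$seed, "train"))
    mod_path <- file.path(config$out_dir, "ensemble.json")
    write_ensemble(ens, mod_path)
    manifest$outputs$ensemble <- mod_path
    manifest$stages$classify <- list(folds = config$folds,
                                     subsample_cap = config$subsample_cap)
  }

  if ("report" %in% config$stages && !is.null(metrics)) {
    met_path <- file.path(config$out_dir, "metrics.json")
    jsonlite::write_json(list(accuracy = metrics$accuracy,
                              sensitivity = metrics$sensitivity,
                              specificity = metrics$specificity,
                              mcc_binary = metrics$mcc_binary,
                              mcc_multiclass = metrics$mcc_multiclass,
                              confusion = metrics$confusion,
                              sample_calls = as.list(calls)),
                         met_path, auto_unbox = TRUE, digits = NA)
    manifest$outputs$metrics <- met_path
  }

  manifest$digests <- as.list(vapply(unlist(manifest$outputs), function(p)
    unname(tools::md5sum(p)), character(1)))
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(structure(list(table = table, feature_set = fs,
                           metrics = metrics, sample_calls = calls,
                           manifest = manifest),
                      class = "PipelineRun"))
}
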