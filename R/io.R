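# Text-based persistence. Frames are written as one CSV per frame (rows =
# pixels in column-major order, one column per channel, channel order
# ascending wavenumber then SHG then TPF) with a JSON sidecar for layout,
# axis and calibration; the label map as a CSV of integer codes. All
# formats round-trip losslessly at full double precision.

#' Write a phantom (stack + label map + calibration) to a directory
#'
#' @param phantom a `"Phantom"` (or list with `stack`, `label_map`,
#'   `calibration`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- phantom$stack
  for (f in seq_along(st$frames)) {
    m <- matrix(st$frames[[f]], ncol = dim(st$frames[[f]])[3])
    colnames(m) <- st$channel_names
    data.table::fwrite(as.data.frame(m),
                       file.path(dir, sprintf("frame_%03d.csv", f)))
  }
  lm <- as.data.frame(unclass(phantom$label_map))
  data.table::fwrite(lm, file.path(dir, "label_map.csv"), col.names = FALSE)
  sidecar <- list(frame_size = st$frame_size,
                  layout = st$layout,
                  axis = as.numeric(st$axis),
                  channel_names = st$channel_names,
                  sample_id = st$sample_id,
                  calibration = list(
                    pump_power = phantom$calibration$pump_power,
                    stokes_power = phantom$calibration$stokes_power,
                    adc_offset = phantom$calibration$adc_offset,
                    detector_gain = phantom$calibration$detector_gain,
                    nu_ref = phantom$calibration$nu_ref))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom directory written by [write_phantom()]
#'
#' @param dir directory path.
#' @return list with `stack`, `label_map`, `calibration`.
#' @export
read_phantom <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                            simplifyVector = TRUE)
  fs <- sc$frame_size
  n_ch <- length(sc$channel_names)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    m <- as.matrix(data.table::fread(f))
    array(as.numeric(m), c(fs, fs, n_ch))
  })
  label_map <- as.matrix(data.table::fread(file.path(dir, "label_map.csv"),
                                           header = FALSE))
  dimnames(label_map) <- NULL
  storage.mode(label_map) <- "integer"
  stack <- structure(list(frames = frames,
                          layout = as.data.frame(sc$layout),
                          axis = wavenumber_axis(sc$axis),
                          channel_names = sc$channel_names,
                          frame_size = fs,
                          sample_id = sc$sample_id),
                     class = "HyperStack")
  calibration <- structure(c(sc$calibration), class = "CalibrationRecord")
  list(stack = stack,
       label_map = structure(label_map, class = c("LabelMap", "matrix")),
       calibration = calibration)
}

#' Write/read a spectrum table as CSV
#'
#' Columns: `sample_id`, `block_row`, `block_col`, `label`, `shg`, `tpf`,
#' then one `cars_<wavenumber>` column per axis point.
#'
#' @param table a `"SpectrumTable"`.
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_spectrum_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_spectrum_table
#' @export
read_spectrum_table <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  attr(out, "axis") <- as.numeric(sub("^cars_", "",
                                      grep("^cars_", names(out), value = TRUE)))
  class(out) <- c("SpectrumTable", "data.frame")
  out
}

#' Serialize a feature set to JSON text
#'
#' @param fs a [feature_set()].
#' @param path output path.
#' @return `path` / the feature set.
#' @export
write_feature_set <- function(fs, path) {
  jsonlite::write_json(unclass(fs), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_set(x$wavenumbers %||% numeric(0),
              isTRUE(x$include_shg), isTRUE(x$include_tpf),
              ranking = x$ranking,
              occurrence_counts = if (!is.null(x$occurrence_counts))
                unlist(x$occurrence_counts),
              exhausted = isTRUE(x$exhausted))
}

#' Persist a trained ensemble as portable JSON text
#'
#' Stores pair specs, feature columns, scaling statistics, weights and
#' metadata; [read_ensemble()] restores a fully functional
#' `"PairwiseEnsemble"`.
#'
#' @param ensemble a `"PairwiseEnsemble"`.
#' @param path output path.
#' @return `path` / the ensemble.
#' @export
write_ensemble <- function(ensemble, path) {
  members <- lapply(ensemble$members, function(m)
    list(spec = as.list(m$spec), columns = m$columns,
         w = as.numeric(m$fit$w), b = m$fit$b,
         levels = m$fit$levels, C = m$fit$C,
         center = as.numeric(m$scaling$center),
         scale = as.numeric(m$scaling$scale)))
  jsonlite::write_json(list(members = members,
                            pair_specs = ensemble$pair_specs,
                            feature_set = unclass(ensemble$feature_set),
                            classes = ensemble$classes,
                            seed = ensemble$seed),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  members <- lapply(x$members, function(m) {
    cols <- unlist(m$columns)
    fit <- structure(list(w = setNames(unlist(m$w), cols), b = m$b,
                          levels = unlist(m$levels), C = m$C,
                          converged = TRUE),
                     class = "linear_svm")
    list(spec = as.data.frame(m$spec), columns = cols, fit = fit,
         scaling = list(center = setNames(unlist(m$center), cols),
                        scale = setNames(unlist(m$scale), cols)))
  })
  pair_specs <- do.call(rbind, lapply(x$pair_specs, as.data.frame))
  fs <- x$feature_set
  structure(list(members = members,
                 pair_specs = pair_specs,
                 feature_set = feature_set(unlist(fs$wavenumbers) %||%
                                             numeric(0),
                                           isTRUE(fs$include_shg),
                                           isTRUE(fs$include_tpf)),
                 classes = unlist(x$classes), seed = x$seed),
            class = "PairwiseEnsemble")
}
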