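# Acquisition correction chain: ADC offset subtraction, beam-power
# calibration, polynomial flat-field estimation/correction, stitching,
# and 4x4 block averaging into a spectrum table.

cars_channel_idx <- function(stack) seq_along(stack$axis)
mod_channel_idx <- function(stack) length(stack$axis) + 1:2

map_frames <- function(stack, fun) {
  stack$frames <- lapply(stack$frames, fun)
  stack
}

#' Subtract the constant ADC offset
#'
#' Every channel of every frame is reduced by the recorded ADC offset
#' (about 50 mV on the instrument). Negative results are retained — noise
#' statistics must survive the correction chain; clipping happens only at
#' rendering.
#'
#' @param stack a `"HyperStack"`.
#' @param calibration a `"CalibrationRecord"` (field `adc_offset`, volts).
#' @return the corrected stack.
#' @export
subtract_offset <- function(stack, calibration) {
  off <- calibration$adc_offset
  if (!is.finite(off)) stop("adc_offset must be finite")
  map_frames(stack, function(fr) fr - off)
}

#' Calibrate intensities against beam powers
#'
#' CARS intensity scales quadratically with pump power and linearly with
#' Stokes power, so the channel at wavenumber nu is divided by
#' `pump(nu)^2 * stokes`; the SHG and TPF channels (pump-only processes)
#' are divided by `pump(nu_ref)^2`. Per-channel detector gains, when
#' recorded, are divided out as well. The result is independent of input
#' power: consistently rescaling powers and raw intensities leaves it
#' unchanged. Apply after [subtract_offset()].
#'
#' @param stack a `"HyperStack"` (offset already subtracted).
#' @param calibration a `"CalibrationRecord"` with `pump_power` (one per
#'   wavenumber), `stokes_power`, optional `detector_gain`, `nu_ref`.
#' @param nu_ref reference wavenumber for SHG/TPF excitation; default the
#'   record's `nu_ref`, else 2850.
#' @param exponents `c(pump, stokes)` power-law exponents, default `c(2, 1)`.
#' @return the calibrated stack.
#' @export
power_calibrate <- function(stack, calibration,
                            nu_ref = calibration$nu_ref %||% 2850,
                            exponents = c(2, 1)) {
  pump <- calibration$pump_power
  stokes <- calibration$stokes_power
  if (length(pump) != length(stack$axis))
    stop("need one pump power per wavenumber")
  if (any(pump <= 0) || stokes <= 0) stop("beam powers must be positive")
  i_ref <- nearest_index(stack$axis, nu_ref)
  div <- c(pump^exponents[1] * stokes^exponents[2],
           rep(pump[i_ref]^exponents[1], 2))
  gain <- calibration$detector_gain %||% rep(1, length(div))
  if (any(gain <= 0)) stop("detector gains must be positive")
  div <- div * gain
  map_frames(stack, function(fr) {
    fr <- fr / rep(div, each = dim(fr)[1] * dim(fr)[2])
    fr
  })
}

#' Estimate the illumination (flat-field) shape
#'
#' Averages the per-pixel intensity over all frames of the stack (CARS
#' channels by default — SHG/TPF have structurally different spatial
#' statistics) and smooths the average by a least-squares fit of a
#' fourth-order two-dimensional polynomial. The fitted field is normalized
#' to unit mean.
#'
#' @param stack a `"HyperStack"`.
#' @param channels `"cars"` (default), `"all"`, or integer channel indices.
#' @param degree polynomial total order (default 4).
#' @return object of class `"IlluminationField"`: `field` (matrix, unit
#'   mean), `coefficients`, `degree`.
#' @export
estimate_illumination <- function(stack, channels = "cars", degree = 4) {
  if (length(stack$frames) < 1) stop("need at least one frame")
  idx <- if (identical(channels, "cars")) cars_channel_idx(stack)
         else if (identical(channels, "all")) seq_along(stack$channel_names)
         else as.integer(channels)
  fs <- dim(stack$frames[[1]])[1:2]
  acc <- matrix(0, fs[1], fs[2])
  for (fr in stack$frames)
    acc <- acc + rowMeans(fr[, , idx, drop = FALSE], dims = 2)
  acc <- acc / length(stack$frames)
  if (all(acc == 0)) stop("degenerate fit: all-zero mean image")
  cc <- frame_coords(fs[1], fs[2])
  X <- poly2d_design(cc$u, cc$v, degree)
  fit <- lm.fit(X, as.numeric(acc))
  fld <- matrix(X %*% fit$coefficients, fs[1], fs[2])
  mu <- mean(fld)
  if (!is.finite(mu) || mu <= 0) stop("degenerate fit: non-positive mean field")
  structure(list(field = fld / mu,
                 coefficients = setNames(fit$coefficients / mu, colnames(X)),
                 degree = degree),
            class = "IlluminationField")
}

#' Divide frames by the illumination field
#'
#' The field is floored at `floor_frac` of its maximum before division so
#' that fitted polynomials approaching zero at frame corners cannot blow
#' up the corrected intensities. Applied identically to every frame and
#' channel.
#'
#' @param stack a `"HyperStack"`.
#' @param field an `"IlluminationField"` (or plain matrix) matching the
#'   frame dimensions.
#' @param floor_frac flooring fraction of the field maximum (default 0.05).
#' @return the corrected stack.
#' @export
correct_illumination <- function(stack, field, floor_frac = 0.05) {
  f <- if (inherits(field, "IlluminationField")) field$field else field
  fs <- dim(stack$frames[[1]])[1:2]
  if (!all(dim(f) == fs)) stop("field dimensions do not match frames")
  f <- pmax(f, floor_frac * max(f))
  map_frames(stack, function(fr) fr / as.numeric(f))
}

#' Stitch frames into a mosaic
#'
#' Frames are placed abutting on their grid positions — no overlap, no
#' blending (seams from residual shading are expected and are what the
#' flat-field correction suppresses).
#'
#' @param stack a `"HyperStack"` whose layout tiles a full rectangle.
#' @return object of class `"MosaicStack"`: `data` array
#'   `[rows*frame, cols*frame, channels]`, plus `axis`, `channel_names`,
#'   `sample_id`.
#' @export
stitch <- function(stack) {
  lay <- stack$layout
  R <- max(lay$row); C <- max(lay$col)
  want <- expand.grid(row = seq_len(R), col = seq_len(C))
  have <- paste(lay$row, lay$col)
  gaps <- setdiff(paste(want$row, want$col), have)
  if (length(gaps))
    stop("missing frame(s) at grid position(s): ", paste(gaps, collapse = "; "))
  fs <- stack$frame_size
  n_ch <- dim(stack$frames[[1]])[3]
  big <- array(NA_real_, c(R * fs, C * fs, n_ch))
  for (f in seq_len(nrow(lay))) {
    r0 <- (lay$row[f] - 1) * fs
    c0 <- (lay$col[f] - 1) * fs
    big[r0 + seq_len(fs), c0 + seq_len(fs), ] <- stack$frames[[f]]
  }
  structure(list(data = big, axis = stack$axis,
                 channel_names = stack$channel_names,
                 sample_id = stack$sample_id),
            class = "MosaicStack")
}

block_mean_matrix <- function(m, bs) {
  gr <- (seq_len(nrow(m)) - 1L) %/% bs
  gc <- (seq_len(ncol(m)) - 1L) %/% bs
  t(rowsum(t(rowsum(m, gr, reorder = TRUE)), gc, reorder = TRUE)) / bs^2
}

#' Average the mosaic into 4x4-pixel spectra
#'
#' Reduces noise by averaging non-overlapping `block_size` x `block_size`
#' pixel blocks (3.7 x 3.7 um at the default pitch) into one spectrum per
#' block. A block is retained iff at least `min_annotated_frac` of its
#' pixels are annotated and at least `purity_frac` of the annotated pixels
#' share one label, which becomes the block label; all other blocks are
#' dropped.
#'
#' @param mosaic a `"MosaicStack"`.
#' @param label_map integer label matrix on the stitched canvas
#'   (0 = unannotated).
#' @param block_size pixels per block side (default 4).
#' @param min_annotated_frac minimum annotated fraction (default 0.75, i.e.
#'   12 of 16 pixels at the default block size).
#' @param purity_frac minimum fraction of annotated pixels sharing the
#'   majority label (default 0.75).
#' @return a `"SpectrumTable"`: data.frame with columns `sample_id`,
#'   `block_row`, `block_col` (0-based block-grid origin coordinates),
#'   `label`, `shg`, `tpf`, then one `cars_<wavenumber>` column per axis
#'   point; the axis is attached as attribute `"axis"`.
#' @export
block_average <- function(mosaic, label_map, block_size = 4,
                          min_annotated_frac = 0.75, purity_frac = 0.75) {
  d <- dim(mosaic$data)
  if (d[1] %% block_size != 0 || d[2] %% block_size != 0)
    stop("mosaic dimensions must be divisible by block_size")
  if (!all(dim(label_map) == d[1:2]))
    stop("label_map dimensions do not match the mosaic")
  bs <- block_size
  nbr <- d[1] %/% bs; nbc <- d[2] %/% bs
  n_ch <- d[3]
  means <- matrix(NA_real_, nbr * nbc, n_ch)
  for (ch in seq_len(n_ch))
    means[, ch] <- as.numeric(block_mean_matrix(mosaic$data[, , ch], bs))
  counts <- sapply(0:5, function(k)
    as.numeric(block_mean_matrix((unclass(label_map) == k) * 1, bs)) * bs^2)
  annotated <- rowSums(counts[, -1, drop = FALSE])
  maj_n <- apply(counts[, -1, drop = FALSE], 1, max)
  maj_lab <- max.col(counts[, -1, drop = FALSE], ties.method = "first")
  keep <- annotated >= min_annotated_frac * bs^2 &
          maj_n >= purity_frac * pmax(annotated, 1)
  br <- rep(seq_len(nbr) - 1L, times = nbc)
  bc <- rep(seq_len(nbc) - 1L, each = nbr)
  n_wn <- length(mosaic$axis)
  out <- data.frame(sample_id = mosaic$sample_id,
                    block_row = br[keep], block_col = bc[keep],
                    label = maj_lab[keep],
                    shg = means[keep, n_wn + 1],
                    tpf = means[keep, n_wn + 2])
  cars <- means[keep, seq_len(n_wn), drop = FALSE]
  colnames(cars) <- sprintf("cars_%g", as.numeric(mosaic$axis))
  out <- cbind(out, as.data.frame(cars))
  attr(out, "axis") <- as.numeric(mosaic$axis)
  class(out) <- c("SpectrumTable", "data.frame")
  out
}

#' Wavenumbers available in a spectrum table
#'
#' @param table a `"SpectrumTable"`.
#' @return numeric vector of wavenumbers, parsed from the `cars_*` columns.
#' @export
table_wavenumbers <- function(table) {
  nm <- grep("^cars_", names(table), value = TRUE)
  as.numeric(sub("^cars_", "", nm))
}

cars_colname <- function(wn) sprintf("cars_%g", wn)
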