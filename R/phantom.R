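#' Default per-class SHG/TPF intensity distributions
#'
#' Log-normal parameters (`meanlog`, `sdlog`) for the detector-volt
#' intensities of the SHG and TPF channels, per tissue class. Chosen to
#' reproduce the qualitative class-conditional structure of breast tissue:
#' fat emits neither SHG nor TPF (background level only); connective tissue
#' dominates SHG (collagen), with the healthy class carrying more
#' low-intensity mass; cancer cells show a heavier high-intensity TPF tail
#' than healthy cells; the two connective classes are similar in TPF.
#'
#' @return data.frame with one row per class: `shg_meanlog`, `shg_sdlog`,
#'   `tpf_meanlog`, `tpf_sdlog`.
#' @export
default_shg_tpf_params <- function() {
  data.frame(
    row.names = names(tissue_classes()),
    shg_meanlog = log(c(0.002, 0.012, 0.20, 0.010, 0.15)),
    shg_sdlog   = c(0.30, 0.50, 0.60, 0.50, 0.80),
    tpf_meanlog = log(c(0.002, 0.25, 0.11, 0.05, 0.10)),
    tpf_sdlog   = c(0.30, 0.50, 0.50, 0.40, 0.50))
}

#' Default frame vignetting polynomial
#'
#' Radially symmetric order-4 shading `1 - 0.45 r^2 + 0.10 r^4` with
#' `r^2 = (u^2 + v^2)/2` on normalized frame coordinates, i.e. unity at the
#' frame center and 0.65 at the corners: the bright-center / dim-edge
#' pattern of a stitched mosaic.
#'
#' @return named coefficient list on the `u^i v^j` basis (total order <= 4).
#' @export
default_shading_coefficients <- function() {
  list(u0v0 = 1, u2v0 = -0.225, u0v2 = -0.225,
       u4v0 = 0.025, u2v2 = 0.05, u0v4 = 0.025)
}

#' Phantom configuration
#'
#' Describes a synthetic multimodal acquisition: mosaic geometry, class
#' region geometry, per-frame vignetting, beam powers, ADC offset, detector
#' noise and class-conditional channel statistics.
#'
#' @param frame_size pixels per frame side (default 256; must be divisible
#'   by the downstream block size 4).
#' @param mosaic_grid frames as `c(rows, cols)` (default `c(2, 2)`).
#' @param pixel_pitch micrometers per pixel (default 0.91).
#' @param axis wavenumber axis (default [default_axis()] at 10 cm^-1 step).
#' @param classes tissue classes present (default all five).
#' @param region_geometry list: `n_blobs` smoothed random blobs per class,
#'   `blob_sigma` blob scale in pixels, `unannotated_frac` fraction of the
#'   canvas left unannotated (weakest-field pixels).
#' @param shading_coefficients named polynomial coefficients (order <= 4)
#'   for the multiplicative per-frame shading; `NULL` disables shading
#'   (flat field of 1).
#' @param adc_offset constant ADC offset in volts (default 0.050).
#' @param power_series list: `pump` nominal pump power, `stokes` Stokes
#'   power, `fluctuation` relative per-wavenumber pump fluctuation
#'   amplitude (uniform, default 0.05), `nu_ref` reference wavenumber for
#'   SHG/TPF excitation (default 2850).
#' @param noise_model list: `sigma` additive Gaussian detector noise sd in
#'   volts (default 0.005); `signal_coef` optional relative
#'   signal-dependent noise (default 0, off); `biological_cv` coefficient
#'   of variation of a multiplicative, spatially patchy (4 px cells)
#'   log-normal scale on the CARS signal, emulating intra-class tissue
#'   heterogeneity -- the within-class spread real class-mean spectra show
#'   (default 0.10; set 0 for a noiseless instrument).
#' @param shg_tpf_distributions per-class log-normal parameters, as from
#'   [default_shg_tpf_params()].
#' @param band_params named list of per-class CARS band parameters
#'   (defaults from [default_band_params()]).
#' @param separation class-contrast dial in `[0, 1]`: 1 keeps the stated
#'   class templates/distributions, 0 collapses every class onto their
#'   common mean (no class signal at all).
#' @param sample_id character sample identifier.
#' @param seed integer seed; the phantom is a deterministic function of the
#'   configuration including this seed.
#' @return validated list of class `"PhantomConfig"`.
#' @export
phantom_config <- function(frame_size = 256,
                           mosaic_grid = c(2, 2),
                           pixel_pitch = 0.91,
                           axis = default_axis(),
                           classes = names(tissue_classes()),
                           region_geometry = list(n_blobs = 3,
                                                  blob_sigma = 60,
                                                  unannotated_frac = 0.08),
                           shading_coefficients = default_shading_coefficients(),
                           adc_offset = 0.050,
                           power_series = list(pump = 1, stokes = 1,
                                               fluctuation = 0.05,
                                               nu_ref = 2850),
                           noise_model = list(sigma = 0.005, signal_coef = 0,
                                              biological_cv = 0.10),
                           shg_tpf_distributions = default_shg_tpf_params(),
                           band_params = NULL,
                           separation = 1,
                           sample_id = "phantom01",
                           seed = 1L) {
  if (frame_size %% 4 != 0)
    stop("frame_size must be divisible by the block size 4")
  stopifnot(length(mosaic_grid) == 2, all(mosaic_grid >= 1))
  axis <- wavenumber_axis(axis)
  if (!all(classes %in% names(tissue_classes())))
    stop("unknown class in 'classes'")
  if (length(classes) < 1) stop("at least one class required")
  if (separation < 0 || separation > 1) stop("separation must be in [0, 1]")
  power_series$fluctuation <- power_series$fluctuation %||% 0
  power_series$nu_ref <- power_series$nu_ref %||% 2850
  if (power_series$pump <= 0 || power_series$stokes <= 0)
    stop("beam powers must be positive")
  noise_model$sigma <- noise_model$sigma %||% 0
  noise_model$signal_coef <- noise_model$signal_coef %||% 0
  noise_model$biological_cv <- noise_model$biological_cv %||% 0
  if (noise_model$biological_cv < 0) stop("biological_cv must be >= 0")
  region_geometry$n_blobs <- region_geometry$n_blobs %||% 3
  region_geometry$blob_sigma <- region_geometry$blob_sigma %||% 60
  region_geometry$unannotated_frac <- region_geometry$unannotated_frac %||% 0
  if (is.null(band_params))
    band_params <- lapply(setNames(nm = classes), default_band_params)
  if (!is.null(shading_coefficients)) {
    fld <- eval_poly2d_field(shading_coefficients, frame_size, frame_size)
    if (any(fld <= 0)) stop("shading field must be strictly positive")
  }
  # cancer templates must sit below their healthy counterpart in
  # water/fat ratio (I at ~3150 over I at ~2845)
  wf <- function(cl) {
    y <- eval_template(build_template(cl, axis, band_params[[cl]]))
    y[nearest_index(axis, 3150)] / y[nearest_index(axis, 2845)]
  }
  for (pair in list(c("cancer_cells", "healthy_cells"),
                    c("cancer_connective", "healthy_connective")))
    if (all(pair %in% classes) && wf(pair[1]) >= wf(pair[2]))
      stop("water/fat ratio of ", pair[1],
           " template must be below that of ", pair[2])
  structure(list(frame_size = as.integer(frame_size),
                 mosaic_grid = as.integer(mosaic_grid),
                 pixel_pitch = pixel_pitch, axis = axis, classes = classes,
                 region_geometry = region_geometry,
                 shading_coefficients = shading_coefficients,
                 adc_offset = adc_offset, power_series = power_series,
                 noise_model = noise_model,
                 shg_tpf_distributions = shg_tpf_distributions,
                 band_params = band_params, separation = separation,
                 sample_id = sample_id, seed = as.integer(seed)),
            class = "PhantomConfig")
}

# Smoothed-blob label canvas: each class gets one dominant anchor bump
# (amplitude 1.5, the global maximum) plus n_blobs - 1 weaker bumps; the
# per-pixel label is the argmax class field and the weakest fraction of
# pixels is left unannotated (code 0). The anchor guarantees every
# configured class appears.
generate_label_map <- function(config) {
  H <- config$frame_size * config$mosaic_grid[1]
  W <- config$frame_size * config$mosaic_grid[2]
  g <- config$region_geometry
  xs <- rep(seq_len(W), each = H)
  ys <- rep(seq_len(H), times = W)
  codes <- tissue_classes()[config$classes]
  best_val <- matrix(-Inf, H, W)
  best_lab <- matrix(0L, H, W)
  for (cl in config$classes) {
    n <- max(1L, as.integer(g$n_blobs))
    cx <- runif(n, 1, W); cy <- runif(n, 1, H)
    amp <- c(1.5, if (n > 1) runif(n - 1, 0.6, 1.2))
    sig <- g$blob_sigma * runif(n, 0.7, 1.4)
    fld <- matrix(0, H, W)
    for (b in seq_len(n)) {
      d2 <- (xs - cx[b])^2 + (ys - cy[b])^2
      fld <- pmax(fld, matrix(amp[b] * exp(-d2 / (2 * sig[b]^2)), H, W))
    }
    upd <- fld > best_val
    best_val[upd] <- fld[upd]
    best_lab[upd] <- codes[[cl]]
  }
  if (g$unannotated_frac > 0) {
    thr <- quantile(best_val, g$unannotated_frac)
    best_lab[best_val <= thr] <- 0L
  }
  structure(best_lab, class = c("LabelMap", "matrix"))
}

# Class spectra and SHG/TPF parameters at the configured separation:
# linear blend between the class value and the mean over present classes.
blended_class_model <- function(config) {
  n_wn <- length(config$axis)
  codes <- tissue_classes()
  spectra <- matrix(0, 6, n_wn)   # row k+1 = class code k; row 1 = code 0
  present <- config$classes
  tm <- matrix(NA_real_, length(present), n_wn)
  for (i in seq_along(present))
    tm[i, ] <- eval_template(build_template(present[i], config$axis,
                                            config$band_params[[present[i]]]))
  grand <- colMeans(tm)
  s <- config$separation
  for (i in seq_along(present))
    spectra[codes[[present[i]]] + 1, ] <- (1 - s) * grand + s * tm[i, ]
  spectra[1, ] <- grand
  st <- config$shg_tpf_distributions
  pooled <- colMeans(st[present, , drop = FALSE])
  stb <- st
  for (cl in present)
    stb[cl, ] <- (1 - s) * pooled + s * unlist(st[cl, ])
  stb <- rbind(unannotated = pooled, stb)   # row 1 = code 0
  stb <- stb[c(1, match(names(codes), rownames(st)) + 1), ]
  rownames(stb) <- c("unannotated", names(codes))
  list(spectra = spectra, shg_tpf = as.matrix(stb))
}

#' Generate a synthetic multimodal phantom
#'
#' Builds a labeled hyperspectral CARS + SHG + TPF mosaic with the
#' acquisition artifacts the correction chain targets. The raw CARS
#' intensity at an annotated pixel is
#' `shading(x, y) * pump(nu)^2 * stokes * template(class, nu) + adc_offset
#' + noise`; SHG and TPF intensities are per-pixel log-normal draws from
#' the class-conditional distributions, excited at the reference
#' wavenumber's pump power. Unannotated pixels carry the mean tissue
#' spectrum. The output is a deterministic function of the configuration.
#'
#' @param config a [phantom_config()].
#' @return list of class `"Phantom"` with elements `stack` (a
#'   `"HyperStack"`: per-frame `[y, x, channel]` arrays, channel order
#'   ascending wavenumber then SHG then TPF), `label_map` (stitched-canvas
#'   integer matrix, 0 = unannotated) and `calibration` (a
#'   `"CalibrationRecord"` with the true powers and offset).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  with_seed(config$seed, {
    fs <- config$frame_size
    n_wn <- length(config$axis)
    n_ch <- n_wn + 2L
    rows <- config$mosaic_grid[1]; cols <- config$mosaic_grid[2]

    label_map <- generate_label_map(config)
    model <- blended_class_model(config)

    ps <- config$power_series
    pump <- ps$pump * (1 + ps$fluctuation * runif(n_wn, -1, 1))
    i_ref <- nearest_index(config$axis, ps$nu_ref)
    pf_cars <- pump^2 * ps$stokes
    pf_mod <- pump[i_ref]^2

    shade <- if (is.null(config$shading_coefficients)) matrix(1, fs, fs)
             else eval_poly2d_field(config$shading_coefficients, fs, fs)

    channel_names <- c(sprintf("cars_%g", as.numeric(config$axis)),
                       "shg", "tpf")
    nm <- config$noise_model
    frames <- vector("list", rows * cols)
    layout <- data.frame(frame = seq_len(rows * cols),
                         row = rep(seq_len(rows), each = cols),
                         col = rep(seq_len(cols), times = rows))
    n_px <- fs * fs
    for (f in seq_len(rows * cols)) {
      r0 <- (layout$row[f] - 1) * fs
      c0 <- (layout$col[f] - 1) * fs
      lab <- label_map[r0 + seq_len(fs), c0 + seq_len(fs)]
      lab_v <- as.integer(lab)
      sig <- model$spectra[lab_v + 1L, , drop = FALSE]       # n_px x n_wn
      if (nm$biological_cv > 0) {
        # patchy tissue heterogeneity: one log-normal scale per 4x4-px
        # cell (mean 1), multiplying the whole CARS spectrum of the cell
        sdl <- sqrt(log(1 + nm$biological_cv^2))
        ncell <- fs %/% 4L
        z <- matrix(rnorm(ncell^2), ncell, ncell)
        gam <- exp(-sdl^2 / 2 + sdl * z)[rep(seq_len(ncell), each = 4),
                                         rep(seq_len(ncell), each = 4)]
        sig <- sig * as.numeric(gam)
      }
      sig <- sig * rep(pf_cars, each = n_px) * as.numeric(shade)
      shg <- rlnorm(n_px, model$shg_tpf[lab_v + 1L, "shg_meanlog"],
                    model$shg_tpf[lab_v + 1L, "shg_sdlog"]) *
             pf_mod * as.numeric(shade)
      tpf <- rlnorm(n_px, model$shg_tpf[lab_v + 1L, "tpf_meanlog"],
                    model$shg_tpf[lab_v + 1L, "tpf_sdlog"]) *
             pf_mod * as.numeric(shade)
      raw <- cbind(sig, shg, tpf) + config$adc_offset
      if (nm$sigma > 0 || nm$signal_coef > 0) {
        sdm <- nm$sigma + nm$signal_coef * abs(raw)
        raw <- raw + rnorm(length(raw)) * sdm
      }
      frames[[f]] <- array(raw, dim = c(fs, fs, n_ch))
    }

    stack <- structure(list(frames = frames, layout = layout,
                            axis = config$axis,
                            channel_names = channel_names,
                            frame_size = fs,
                            sample_id = config$sample_id),
                       class = "HyperStack")
    calibration <- structure(list(pump_power = pump,
                                  stokes_power = ps$stokes,
                                  adc_offset = config$adc_offset,
                                  detector_gain = rep(1, n_ch),
                                  nu_ref = ps$nu_ref),
                             class = "CalibrationRecord")
    structure(list(stack = stack, label_map = label_map,
                   calibration = calibration, config = config),
              class = "Phantom")
  })
}

#' @export
print.HyperStack <- function(x, ...) {
  cat("HyperStack:", length(x$frames), "frame(s) of",
      x$frame_size, "x", x$frame_size, "px,",
      length(x$axis), "CARS channels + SHG + TPF\n")
  cat("  grid:", max(x$layout$row), "x", max(x$layout$col),
      " sample:", x$sample_id, "\n")
  invisible(x)
}
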