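#' Tissue classes and their integer codes
#'
#' Code 0 is reserved for unannotated pixels in label maps.
#'
#' @return named integer vector mapping class name to code 1..5.
#' @export
tissue_classes <- function() {
  c(fat = 1L, cancer_cells = 2L, cancer_connective = 3L,
    healthy_cells = 4L, healthy_connective = 5L)
}

#' Default CARS band parameters per tissue class
#'
#' Gaussian band models on the high-wavenumber window. Amplitudes are
#' detector volts at band center; widths are FWHM in cm^-1. The parameter
#' choices encode the qualitative spectroscopy of breast tissue: fat is
#' dominated by the CH2 stretch at 2850 cm^-1; cell and connective classes
#' carry the protein CH3 band near 2930 cm^-1 plus a broad OH (water) band
#' near 3150 cm^-1, with the water contribution lower in the cancerous
#' classes than in their healthy counterparts (lower water/fat ratio).
#'
#' @param tissue_class one of `names(tissue_classes())`.
#' @return list with `band_centers`, `band_widths`, `band_amplitudes`,
#'   `baseline`.
#' @export
default_band_params <- function(tissue_class) {
  tbl <- list(
    fat = list(centers = c(2850, 2930, 3150),
               widths = c(50, 60, 120),
               amps = c(1.00, 0.25, 0.05), baseline = 0.01),
    cancer_cells = list(centers = c(2850, 2930, 3150),
                        widths = c(55, 70, 130),
                        amps = c(0.32, 0.60, 0.15), baseline = 0.01),
    cancer_connective = list(centers = c(2850, 2930, 3150),
                             widths = c(55, 75, 130),
                             amps = c(0.28, 0.52, 0.17), baseline = 0.01),
    healthy_cells = list(centers = c(2850, 2930, 3150),
                         widths = c(55, 70, 130),
                         amps = c(0.30, 0.55, 0.28), baseline = 0.01),
    healthy_connective = list(centers = c(2850, 2930, 3150),
                              widths = c(55, 75, 130),
                              amps = c(0.26, 0.48, 0.30), baseline = 0.01))
  if (!tissue_class %in% names(tbl))
    stop("unknown tissue class: ", tissue_class)
  tbl[[tissue_class]]
}

#' Build a class spectral template
#'
#' A template is a sum of Gaussian bands plus a constant baseline,
#' evaluated on a wavenumber axis. For the fat class the template maximum
#' over the axis must fall in 2840--2860 cm^-1 (the CH2 stretch).
#'
#' @param tissue_class one of `names(tissue_classes())`.
#' @param axis a [wavenumber_axis()].
#' @param params band parameter list as from [default_band_params()];
#'   fields `centers`, `widths` (FWHM), `amps`, `baseline`.
#' @return object of class `"SpectralTemplate"` with the parameters and the
#'   class name.
#' @export
build_template <- function(tissue_class, axis,
                           params = default_band_params(tissue_class)) {
  if (!tissue_class %in% names(tissue_classes()))
    stop("unknown tissue class: ", tissue_class)
  axis <- wavenumber_axis(axis)
  stopifnot(length(params$centers) >= 1,
            length(params$widths) == length(params$centers),
            length(params$amps) == length(params$centers))
  if (any(params$amps < 0)) stop("band amplitudes must be >= 0")
  if (any(params$widths <= 0)) stop("band widths must be > 0")
  tmpl <- structure(list(tissue_class = tissue_class,
                         band_centers = as.numeric(params$centers),
                         band_widths = as.numeric(params$widths),
                         band_amplitudes = as.numeric(params$amps),
                         baseline = as.numeric(params$baseline %||% 0),
                         axis = axis),
                    class = "SpectralTemplate")
  y <- eval_template(tmpl, axis)
  if (any(!is.finite(y)) || any(y < 0))
    stop("evaluated template must be finite and non-negative")
  if (tissue_class == "fat") {
    peak <- as.numeric(axis)[which.max(y)]
    if (peak < 2840 || peak > 2860)
      stop("fat template maximum must lie within 2840-2860 cm^-1, got ", peak)
  }
  tmpl
}

#' Evaluate a spectral template on an axis
#'
#' @param template a `"SpectralTemplate"`.
#' @param axis wavenumber axis (defaults to the template's own axis).
#' @return numeric intensity vector, one value per axis point.
#' @export
eval_template <- function(template, axis = template$axis) {
  x <- as.numeric(axis)
  y <- rep(template$baseline, length(x))
  for (i in seq_along(template$band_centers)) {
    w <- template$band_widths[i]
    # Gaussian with FWHM w: exp(-4 ln2 (x - c)^2 / w^2)
    y <- y + template$band_amplitudes[i] *
      exp(-4 * log(2) * (x - template$band_centers[i])^2 / w^2)
  }
  y
}
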