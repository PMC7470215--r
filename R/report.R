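# Metrics, spectral summaries, histograms and rendering.

#' Classification metrics
#'
#' Builds the 5-class confusion matrix (truth on rows) and derives:
#' overall accuracy; sensitivity, specificity and binary Matthews
#' correlation on the cancer-vs-healthy collapse (cancer cells + cancer
#' connective positive, healthy cells + healthy connective negative,
#' records involving fat excluded — fat is neither margin state); and the
#' multiclass Matthews correlation over all five classes.
#'
#' @param predictions,truth equal-length integer vectors of class codes
#'   in 1..5.
#' @return object of class `"MetricsReport"`: `accuracy`, `sensitivity`,
#'   `specificity`, `mcc_binary`, `mcc_multiclass`, `confusion` (5x5
#'   counts), `confusion_row_normalized` (all-zero rows flagged via
#'   attribute `"zero_rows"`).
#' @export
compute_metrics <- function(predictions, truth) {
  predictions <- as.integer(predictions)
  truth <- as.integer(truth)
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  if (any(!predictions %in% 1:5) || any(!truth %in% 1:5))
    stop("class codes must lie in 1..5")
  cls <- names(tissue_classes())
  confusion <- matrix(0L, 5, 5, dimnames = list(truth = cls, predicted = cls))
  for (i in seq_along(truth))
    confusion[truth[i], predictions[i]] <- confusion[truth[i], predictions[i]] + 1L
  rs <- rowSums(confusion)
  zero_rows <- rs == 0
  norm <- confusion / ifelse(rs == 0, 1, rs)
  attr(norm, "zero_rows") <- zero_rows
  accuracy <- sum(diag(confusion)) / length(truth)

  # cancer-vs-healthy collapse, fat excluded on either side
  keep <- truth != 1L & predictions != 1L
  tp <- sum(truth[keep] %in% 2:3 & predictions[keep] %in% 2:3)
  tn <- sum(truth[keep] %in% 4:5 & predictions[keep] %in% 4:5)
  fp <- sum(truth[keep] %in% 4:5 & predictions[keep] %in% 2:3)
  fn <- sum(truth[keep] %in% 2:3 & predictions[keep] %in% 4:5)
  sens_spec_counts <- c(tp, fp, fn, tn)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc_b <- if (denom > 0) (tp * tn - fp * fn) / denom else 0

  structure(list(accuracy = accuracy, sensitivity = sens,
                 specificity = spec, mcc_binary = mcc_b,
                 mcc_multiclass = mcc_multiclass(confusion),
                 confusion = confusion,
                 confusion_row_normalized = norm,
                 binary_counts = setNames(sens_spec_counts,
                                          c("tp", "fp", "fn", "tn"))),
            class = "MetricsReport")
}

#' Multiclass Matthews correlation coefficient
#'
#' K-class generalization computed from the confusion matrix `C` (truth on
#' rows): `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2))(s^2 - sum(t_k^2)))`
#' with `c = trace(C)`, `s = n`, `t_k` true and `p_k` predicted counts.
#' Defined as 0 when a denominator factor vanishes.
#'
#' @param confusion square count matrix, truth on rows.
#' @return value in `[-1, 1]`.
#' @export
mcc_multiclass <- function(confusion) {
  confusion <- as.matrix(confusion)
  storage.mode(confusion) <- "double"   # counts can overflow integer products
  s <- sum(confusion)
  c0 <- sum(diag(confusion))
  t_k <- rowSums(confusion)
  p_k <- colSums(confusion)
  num <- c0 * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

#' Per-class mean and standard-deviation spectra
#'
#' @param table a `"SpectrumTable"`.
#' @return list of class `"SpectralSummary"`: `axis`, `mean` and `sd`
#'   matrices (class x wavenumber, classes present only), `n` per class.
#'   Classes with a single record get sd 0 and are flagged in
#'   `single_record`.
#' @export
summarize_spectra <- function(table) {
  if (nrow(table) == 0) stop("empty table")
  wns <- table_wavenumbers(table)
  cols <- cars_colname(wns)
  labs <- sort(unique(table$label))
  cls <- names(tissue_classes())[labs]
  mu <- sdv <- matrix(NA_real_, length(labs), length(wns),
                      dimnames = list(cls, cols))
  n <- setNames(integer(length(labs)), cls)
  for (i in seq_along(labs)) {
    sub <- as.matrix(table[table$label == labs[i], cols, drop = FALSE])
    mu[i, ] <- colMeans(sub)
    sdv[i, ] <- if (nrow(sub) > 1) apply(sub, 2, sd) else 0
    n[i] <- nrow(sub)
  }
  structure(list(axis = wns, mean = mu, sd = sdv, n = n,
                 single_record = n == 1L),
            class = "SpectralSummary")
}

#' Water/fat ratio of a spectrum
#'
#' Intensity at the axis point nearest 3150 cm^-1 (OH stretch, water)
#' divided by the intensity nearest 2845 cm^-1 (CH2 stretch, lipid).
#' Lower in cancerous than in healthy tissue.
#'
#' @param spectrum numeric intensity vector on `axis`.
#' @param axis wavenumber axis.
#' @return the ratio; `NA` with attribute `undefined = TRUE` when the
#'   denominator is not positive.
#' @export
water_fat_ratio <- function(spectrum, axis) {
  stopifnot(length(spectrum) == length(axis))
  num <- spectrum[nearest_index(axis, 3150)]
  den <- spectrum[nearest_index(axis, 2845)]
  if (!is.finite(den) || den <= 0)
    return(structure(NA_real_, undefined = TRUE))
  num / den
}

#' Class-conditional SHG/TPF intensity histograms
#'
#' Relative-frequency histograms of the SHG and TPF block intensities per
#' class on one shared bin axis, so the two modalities are directly
#' comparable. Fat is excluded (it produces neither SHG nor TPF). Empty
#' classes are omitted and flagged.
#'
#' @param table a `"SpectrumTable"`.
#' @param bins number of shared bins (default 64).
#' @param upper upper pooled quantile for the bin range (default 0.995).
#' @return list of class `"IntensityHistograms"`: `breaks`, `shg` and
#'   `tpf` (class x bin relative-frequency matrices, rows sum to 1),
#'   `omitted` class names.
#' @export
intensity_histograms <- function(table, bins = 64, upper = 0.995) {
  keep <- table$label != 1L
  cls_codes <- 2:5
  cls <- names(tissue_classes())[cls_codes]
  vals <- c(table$shg[keep], table$tpf[keep])
  if (length(vals) == 0) stop("no non-fat records")
  lo <- min(0, min(vals))
  hi <- as.numeric(quantile(vals, upper))
  if (hi <= lo) hi <- lo + 1e-12
  breaks <- seq(lo, hi, length.out = bins + 1)
  binify <- function(v) {
    v <- pmin(pmax(v, lo), hi)
    idx <- pmin(findInterval(v, breaks, rightmost.closed = TRUE), bins)
    tabulate(idx, nbins = bins) / length(v)
  }
  shg <- tpf <- matrix(NA_real_, length(cls), bins,
                       dimnames = list(cls, NULL))
  omitted <- character(0)
  for (i in seq_along(cls_codes)) {
    rows <- table$label == cls_codes[i]
    if (!any(rows)) { omitted <- c(omitted, cls[i]); next }
    shg[i, ] <- binify(table$shg[rows])
    tpf[i, ] <- binify(table$tpf[rows])
  }
  structure(list(breaks = breaks,
                 shg = shg[!cls %in% omitted, , drop = FALSE],
                 tpf = tpf[!cls %in% omitted, , drop = FALSE],
                 omitted = omitted),
            class = "IntensityHistograms")
}

#' Class-map palette
#'
#' Fixed rendering palette: yellow fat, violet cancer cells, light blue
#' cancer connective tissue, green healthy cells, orange healthy
#' connective tissue; black for unclassified.
#'
#' @return 6 x 3 RGB matrix in `[0, 1]`, rows named by code 0..5.
#' @export
class_palette <- function() {
  pal <- rbind(unclassified = c(0, 0, 0),
               fat = c(255, 255, 0),
               cancer_cells = c(148, 0, 211),
               cancer_connective = c(135, 206, 250),
               healthy_cells = c(0, 170, 0),
               healthy_connective = c(255, 165, 0)) / 255
  colnames(pal) <- c("r", "g", "b")
  pal
}

#' Render a class map to an RGB image
#'
#' @param class_map integer matrix of class codes 0..5 (0 = unclassified),
#'   or a `"PixelClassMap"` (rendered on its block grid).
#' @return `[H, W, 3]` RGB array in `[0, 1]` with the palette attached as
#'   attribute `"palette"`.
#' @export
render_class_map <- function(class_map) {
  if (inherits(class_map, "PixelClassMap"))
    class_map <- class_map_matrix(class_map)
  m <- as.matrix(unclass(class_map))
  if (length(m) == 0) stop("empty class map")
  if (any(!m %in% 0:5)) stop("class codes must lie in 0..5")
  pal <- class_palette()
  img <- array(NA_real_, c(nrow(m), ncol(m), 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[m + 1L, ch], nrow(m), ncol(m))
  attr(img, "palette") <- pal
  img
}

#' Arrange block predictions on the block grid
#'
#' @param pixel_map a `"PixelClassMap"`.
#' @return integer matrix over the bounding block grid; blocks without a
#'   prediction are 0.
#' @export
class_map_matrix <- function(pixel_map) {
  r <- pixel_map$block_row; c <- pixel_map$block_col
  if (is.null(r) || is.null(c)) stop("pixel map carries no block coordinates")
  m <- matrix(0L, max(r) + 1L, max(c) + 1L)
  m[cbind(r + 1L, c + 1L)] <- pixel_map$predictions
  m
}

#' Decode a rendered class map back to codes
#'
#' @param img RGB array produced by [render_class_map()].
#' @return integer code matrix.
#' @export
decode_class_map <- function(img) {
  pal <- class_palette()
  H <- dim(img)[1]; W <- dim(img)[2]
  flat <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
                as.numeric(img[, , 3]))
  code <- apply(flat, 1, function(px) {
    d <- colSums((t(pal) - px)^2)
    which.min(d) - 1L
  })
  matrix(as.integer(code), H, W)
}

#' False-color composite of the three modalities
#'
#' CARS at 2850 cm^-1 (lipid) in blue, SHG (collagen) in red, TPF
#' (cells/elastin) in green, each stretched between its own percentile
#' bounds and clipped to `[0, 1]`.
#'
#' @param mosaic a `"MosaicStack"`.
#' @param percentiles normalization stretch (default 1st--99th).
#' @return `[H, W, 3]` RGB array in `[0, 1]`.
#' @export
render_composite <- function(mosaic, percentiles = c(0.01, 0.99)) {
  stretch <- function(m) {
    q <- quantile(m, percentiles, na.rm = TRUE)
    if (q[2] <= q[1]) return(m * 0)
    pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
  }
  i2850 <- nearest_index(mosaic$axis, 2850)
  n_wn <- length(mosaic$axis)
  img <- array(0, c(dim(mosaic$data)[1:2], 3))
  img[, , 1] <- stretch(mosaic$data[, , n_wn + 1])   # SHG -> red
  img[, , 2] <- stretch(mosaic$data[, , n_wn + 2])   # TPF -> green
  img[, , 3] <- stretch(mosaic$data[, , i2850])      # CARS 2850 -> blue
  img
}

#' Write an RGB array as a plain-text PPM (P3) image
#'
#' @param img `[H, W, 3]` array in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  H <- dim(img)[1]; W <- dim(img)[2]
  v <- round(pmin(pmax(img, 0), 1) * 255)
  # one pixel per line, row-major
  px <- matrix(NA_real_, H * W, 3)
  for (ch in 1:3) px[, ch] <- as.numeric(t(v[, , ch]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(W, H), "255"), con)
  writeLines(paste(px[, 1], px[, 2], px[, 3]), con)
  invisible(path)
}
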