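# Helpers to build small stacks/mosaics by hand.
make_stack <- function(frames, axis, layout = NULL, sample_id = "s1") {
  n <- length(frames)
  if (is.null(layout))
    layout <- data.frame(frame = seq_len(n), row = 1L, col = seq_len(n))
  structure(list(frames = frames, layout = layout,
                 axis = wavenumber_axis(axis),
                 channel_names = c(sprintf("cars_%g", as.numeric(axis)),
                                   "shg", "tpf"),
                 frame_size = dim(frames[[1]])[1], sample_id = sample_id),
            class = "HyperStack")
}

make_calib <- function(axis, pump = 1, stokes = 1, offset = 0) {
  structure(list(pump_power = rep_len(pump, length(axis)),
                 stokes_power = stokes, adc_offset = offset,
                 detector_gain = rep(1, length(axis) + 2), nu_ref = 2850),
            class = "CalibrationRecord")
}

test_that("offset subtraction is exact, identity-safe, and never clips", {
  ax <- c(2700, 2900, 3100)
  fr <- array(0.050, c(8, 8, 5))
  st <- make_stack(list(fr), ax)
  out <- subtract_offset(st, make_calib(ax, offset = 0.050))
  expect_true(all(out$frames[[1]] == 0))
  out0 <- subtract_offset(st, make_calib(ax, offset = 0))
  expect_identical(out0$frames, st$frames)
  neg <- subtract_offset(make_stack(list(array(0.040, c(8, 8, 5))), ax),
                         make_calib(ax, offset = 0.050))
  expect_true(all(abs(neg$frames[[1]] - (-0.010)) < 1e-15))
})

test_that("power calibration honours the pump-squared contract", {
  ax <- c(2700, 2900, 3100)
  set.seed(4)
  fr <- array(runif(8 * 8 * 5), c(8, 8, 5))
  st <- make_stack(list(fr), ax)
  expect_identical(power_calibrate(st, make_calib(ax))$frames, st$frames)

  # doubling pump power at one wavenumber while quadrupling that raw
  # channel leaves the calibrated output unchanged (a non-reference
  # wavenumber, so the SHG/TPF divisor is untouched)
  cal2 <- make_calib(ax); cal2$pump_power[1] <- 2
  fr2 <- fr; fr2[, , 1] <- 4 * fr[, , 1]
  expect_equal(power_calibrate(make_stack(list(fr2), ax), cal2)$frames,
               power_calibrate(st, make_calib(ax))$frames)

  bad <- make_calib(ax); bad$pump_power[1] <- 0
  expect_error(power_calibrate(st, bad), "positive")
})

test_that("staged offset + power calibration matches the closed form", {
  ax <- seq(2700, 3200, by = 100)
  set.seed(8)
  n_wn <- length(ax)
  pump <- runif(n_wn, 0.5, 1.5); stokes <- 0.8; off <- 0.05
  fr <- array(runif(16 * 16 * (n_wn + 2)), c(16, 16, n_wn + 2))
  cal <- make_calib(ax); cal$pump_power <- pump; cal$stokes_power <- stokes
  cal$adc_offset <- off
  staged <- power_calibrate(subtract_offset(make_stack(list(fr), ax), cal),
                            cal)$frames[[1]]
  i_ref <- nearest_index(ax, 2850)
  div <- c(pump^2 * stokes, rep(pump[i_ref]^2, 2))
  closed <- (fr - off) / rep(div, each = 16 * 16)
  expect_identical(staged, closed)   # bit-for-bit
})

test_that("noiseless phantom calibrates back to shading x template", {
  cfg <- tiny_phantom_config(noise_sigma = 0, biological_cv = 0, seed = 9,
                             adc_offset = 0.05,
                             power_series = list(pump = 1.2, stokes = 0.7,
                                                 fluctuation = 0.1,
                                                 nu_ref = 2850))
  ph <- generate_phantom(cfg)
  st <- power_calibrate(subtract_offset(ph$stack, ph$calibration),
                        ph$calibration)
  shade <- eval_poly2d_field <- carsdelin:::eval_poly2d_field(
    default_shading_coefficients(), cfg$frame_size, cfg$frame_size)
  lab <- unclass(ph$label_map)
  n_wn <- length(cfg$axis)
  idx <- which(lab == tissue_classes()[["fat"]])[1]
  px <- arrayInd(idx, dim(lab))
  tmpl <- eval_template(build_template("fat", cfg$axis))
  expect_equal(as.numeric(st$frames[[1]][px[1], px[2], seq_len(n_wn)]),
               tmpl * shade[px[1], px[2]], tolerance = 1e-12)
})

test_that("illumination estimation recovers planted fields", {
  ax <- c(2700, 2900, 3100)
  # constant frames -> unit field
  st <- make_stack(list(array(3, c(32, 32, 5)), array(5, c(32, 32, 5))), ax)
  fld <- estimate_illumination(st)
  expect_equal(fld$field, matrix(1, 32, 32), tolerance = 1e-9)

  # planted order-4 shading, noiseless -> < 1% max relative error
  shade <- carsdelin:::eval_poly2d_field(default_shading_coefficients(),
                                         32, 32)
  frames <- lapply(c(2, 3, 4), function(a)
    array(rep(a * as.numeric(shade), 5), c(32, 32, 5)))
  fld <- estimate_illumination(make_stack(frames, ax,
    layout = data.frame(frame = 1:3, row = 1L, col = 1:3)))
  rel <- abs(fld$field / (shade / mean(shade)) - 1)
  expect_lt(max(rel), 0.01)

  # planted order-2 vignette + 5% noise over 25 frames -> < 5% everywhere
  set.seed(12)
  v2 <- carsdelin:::eval_poly2d_field(list(u0v0 = 1, u2v0 = -0.2,
                                           u0v2 = -0.2), 32, 32)
  frames <- lapply(1:25, function(i) {
    base <- rep(as.numeric(v2), 5)
    array(base * (1 + rnorm(length(base), 0, 0.05)), c(32, 32, 5))
  })
  fld <- estimate_illumination(make_stack(frames, ax,
    layout = data.frame(frame = 1:25, row = 1L, col = 1:25)))
  expect_lt(max(abs(fld$field / (v2 / mean(v2)) - 1)), 0.05)

  expect_error(estimate_illumination(
    make_stack(list(array(0, c(8, 8, 5))), ax)), "all-zero")
})

test_that("illumination correction inverts planted shading", {
  ax <- c(2700, 2900, 3100)
  set.seed(5)
  fr <- array(runif(32 * 32 * 5, 1, 2), c(32, 32, 5))
  st <- make_stack(list(fr), ax)
  expect_equal(correct_illumination(st, matrix(1, 32, 32))$frames, st$frames)

  shade <- carsdelin:::eval_poly2d_field(default_shading_coefficients(),
                                         32, 32)
  shaded <- make_stack(list(fr * as.numeric(shade)), ax)
  # exact inversion when the true field is supplied (floor not hit:
  # min(shade) = 0.65 > 5% of max)
  rec <- correct_illumination(shaded, shade)
  expect_equal(rec$frames[[1]], fr, tolerance = 1e-12)
  expect_error(correct_illumination(st, matrix(1, 8, 8)), "dimensions")
})

test_that("flat-fielding cuts within-class variation by >= 3x", {
  # detector-noise-only phantom: the statistic isolates the shading
  # contribution; with intrinsic tissue heterogeneity (biological_cv > 0)
  # the residual CV floor is biological, not instrumental
  cfg <- tiny_phantom_config(seed = 21, grid = c(2, 2), frame_size = 64,
                             biological_cv = 0)
  ph <- generate_phantom(cfg)
  st <- power_calibrate(subtract_offset(ph$stack, ph$calibration),
                        ph$calibration)
  corr <- correct_illumination(st, estimate_illumination(st))
  i2930 <- nearest_index(cfg$axis, 2930)
  cv_of <- function(stack) {
    mos <- stitch(stack)
    v <- mos$data[, , i2930][unclass(ph$label_map) ==
                               tissue_classes()[["healthy_connective"]]]
    sd(v) / mean(v)
  }
  expect_gt(cv_of(st) / cv_of(corr), 3)
})

test_that("stitching places frames verbatim and flags gaps", {
  ax <- c(2700, 2900, 3100)
  f1 <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  st1 <- make_stack(list(f1), ax,
                    layout = data.frame(frame = 1, row = 1L, col = 1L))
  expect_identical(stitch(st1)$data, f1)

  frames <- lapply(1:4, function(i) array(i + rnorm(16 * 16 * 5),
                                          c(16, 16, 5)))
  lay <- data.frame(frame = 1:4, row = c(1L, 1L, 2L, 2L),
                    col = c(1L, 2L, 1L, 2L))
  mos <- stitch(make_stack(frames, ax, layout = lay))
  expect_equal(dim(mos$data), c(32, 32, 5))
  expect_identical(mos$data[17:32, 1:16, ], frames[[3]])

  expect_error(stitch(make_stack(frames[1:3], ax, layout = lay[1:3, ])),
               "missing frame")
})

test_that("uncorrected per-frame shading shows up as seam contrast", {
  # a tilted shading makes abutting frame edges differ (a radially
  # symmetric vignette is equal on both sides of a seam by symmetry)
  cfg <- tiny_phantom_config(seed = 31, grid = c(1, 2), frame_size = 64,
                             noise_sigma = 0.001,
                             shading = list(u0v0 = 1, u1v0 = 0.25,
                                            u2v0 = -0.15, u0v2 = -0.15))
  ph <- generate_phantom(cfg)
  st <- power_calibrate(subtract_offset(ph$stack, ph$calibration),
                        ph$calibration)
  mos <- stitch(st)
  i2930 <- nearest_index(cfg$axis, 2930)
  img <- mos$data[, , i2930]
  seam <- mean(abs(img[, 64] - img[, 65]))            # across the seam
  within <- mean(abs(img[, 30] - img[, 31]))          # interior neighbours
  expect_gt(seam, 2 * within)
  corr <- stitch(correct_illumination(st, estimate_illumination(st)))
  img2 <- corr$data[, , i2930]
  expect_lt(mean(abs(img2[, 64] - img2[, 65])), seam / 2)
})

test_that("block averaging: counts, means, and label recount", {
  ax <- c(2700, 2900, 3100)
  # 256 x 256 single-label constant mosaic -> 4096 blocks, spectra verbatim
  s <- c(1, 2, 3, 0.5, 0.25)
  mos <- structure(list(data = array(rep(s, each = 256 * 256),
                                     c(256, 256, 5)),
                        axis = wavenumber_axis(ax),
                        channel_names = c(sprintf("cars_%g", ax), "shg", "tpf"),
                        sample_id = "s1"), class = "MosaicStack")
  labm <- matrix(2L, 256, 256)
  tab <- block_average(mos, labm)
  expect_equal(nrow(tab), 4096)
  expect_true(all(tab$label == 2L))
  expect_equal(unname(as.numeric(tab[1, sprintf("cars_%g", ax)])), s[1:3])
  expect_equal(tab$shg[1], 0.5)
  expect_false(any(duplicated(tab[, c("block_row", "block_col")])))

  expect_error(block_average(mos, labm, block_size = 3), "divisible")

  # purity rule against a brute-force recount on a phantom
  cfg <- tiny_phantom_config(seed = 17, frame_size = 32)
  ph <- generate_phantom(cfg)
  tab2 <- block_average(stitch(ph$stack), ph$label_map)
  lab <- unclass(ph$label_map)
  for (r in seq_len(nrow(tab2))) {
    blk <- lab[tab2$block_row[r] * 4 + 1:4, tab2$block_col[r] * 4 + 1:4]
    ann <- blk[blk != 0]
    expect_gte(length(ann), 12)
    cnt <- table(ann)
    expect_equal(as.integer(names(cnt)[which.max(cnt)]), tab2$label[r])
    expect_gte(max(cnt) / length(ann), 0.75)
  }
  # dropped blocks really fail annotation or purity
  all_blocks <- expand.grid(br = 0:(nrow(lab) / 4 - 1),
                            bc = 0:(ncol(lab) / 4 - 1))
  kept <- paste(tab2$block_row, tab2$block_col)
  dropped <- all_blocks[!paste(all_blocks$br, all_blocks$bc) %in% kept, ]
  for (r in seq_len(nrow(dropped))) {
    blk <- lab[dropped$br[r] * 4 + 1:4, dropped$bc[r] * 4 + 1:4]
    ann <- blk[blk != 0]
    ok <- length(ann) >= 12 && max(table(ann)) / length(ann) >= 0.75
    expect_false(ok)
  }
})

test_that("end-to-end identity: unit instrument table equals raw block means", {
  cfg <- identity_phantom_config(seed = 13, frame_size = 32)
  ph <- generate_phantom(cfg)
  st <- power_calibrate(subtract_offset(ph$stack, ph$calibration),
                        ph$calibration)
  tab <- block_average(stitch(st), ph$label_map)
  raw_tab <- block_average(stitch(ph$stack), ph$label_map)
  expect_equal(tab, raw_tab)
})
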