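# Shared fixtures: tiny phantom configurations, hand-built spectrum tables
# and an independent SVM oracle (direct primal minimization) used to verify
# the dual coordinate-descent solver and the RFE weight aggregation.

tiny_phantom_config <- function(frame_size = 64, grid = c(1, 1), seed = 7,
                                noise_sigma = 0.005, biological_cv = 0.10,
                                separation = 1,
                                shading = default_shading_coefficients(),
                                classes = names(tissue_classes()),
                                axis = default_axis(20), ...) {
  phantom_config(frame_size = frame_size, mosaic_grid = grid, axis = axis,
                 classes = classes,
                 region_geometry = list(n_blobs = 2, blob_sigma = 20,
                                        unannotated_frac = 0.08),
                 shading_coefficients = shading,
                 noise_model = list(sigma = noise_sigma, signal_coef = 0,
                                    biological_cv = biological_cv),
                 separation = separation, seed = seed, ...)
}

# Identity instrument: no stochastic intensity terms, flat shading, zero
# offset, unit powers.
identity_phantom_config <- function(noise_sigma = 0, ...) {
  tiny_phantom_config(shading = NULL, noise_sigma = noise_sigma,
                      biological_cv = 0, adc_offset = 0,
                      power_series = list(pump = 1, stokes = 1,
                                          fluctuation = 0, nu_ref = 2850),
                      ...)
}

# Spectrum table built directly from class means + iid Gaussian noise;
# bypasses the imaging chain so featsel/classify tests control separability.
make_toy_table <- function(n_per_class, class_means, wavenumbers,
                           noise = 0.1, shg_means = NULL, tpf_means = NULL,
                           seed = 1, sample_ids = "s1") {
  set.seed(seed)
  labs <- as.integer(rownames(class_means))
  rows <- lapply(seq_along(labs), function(i) {
    x <- matrix(rep(class_means[i, ], each = n_per_class),
                n_per_class) + rnorm(n_per_class * ncol(class_means), 0, noise)
    colnames(x) <- sprintf("cars_%g", wavenumbers)
    data.frame(sample_id = rep_len(sample_ids, n_per_class),
               block_row = seq_len(n_per_class) - 1L,
               block_col = i - 1L, label = labs[i],
               shg = (if (is.null(shg_means)) 0.1 else shg_means[i]) +
                 rnorm(n_per_class, 0, noise / 2),
               tpf = (if (is.null(tpf_means)) 0.1 else tpf_means[i]) +
                 rnorm(n_per_class, 0, noise / 2),
               x, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "axis") <- wavenumbers
  class(out) <- c("SpectrumTable", "data.frame")
  out
}

# Independent oracle: minimize the primal squared-hinge objective
#   0.5 (||w||^2 + b^2) + C sum_i max(0, 1 - y_i (w'x_i + b))^2
# directly with L-BFGS-B (the bias is regularized, exactly as in the
# augmented-feature formulation the dual solver uses). Shares no code with
# the dual solver.
oracle_svm <- function(x, y, C = 1) {
  x <- as.matrix(x); n <- nrow(x); p <- ncol(x)
  obj <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    xi <- pmax(0, 1 - y * (x %*% w + b))
    0.5 * (sum(w^2) + b^2) + C * sum(xi^2)
  }
  grad <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    xi <- pmax(0, 1 - y * (drop(x %*% w) + b))
    gw <- w - 2 * C * colSums(x * (y * xi))
    gb <- b - 2 * C * sum(y * xi)
    c(gw, gb)
  }
  fit <- optim(rep(0, p + 1), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 2000, factr = 1e4))
  list(w = fit$par[1:p], b = fit$par[p + 1], value = fit$value)
}

# Oracle aggregate squared weight per feature over all pairwise SVMs,
# recomputed from scratch on z-scored features.
oracle_aggregate_weights <- function(table, wavenumbers, C = 1) {
  cols <- sprintf("cars_%g", wavenumbers)
  x <- scale(as.matrix(table[, cols, drop = FALSE]))
  x[is.na(x)] <- 0
  classes <- sort(unique(table$label))
  agg <- numeric(length(cols))
  for (p in utils::combn(classes, 2, simplify = FALSE)) {
    rows <- table$label %in% p
    y <- ifelse(table$label[rows] == p[2], 1, -1)
    agg <- agg + oracle_svm(x[rows, , drop = FALSE], y, C)$w^2
  }
  setNames(agg, cols)
}
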