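# Bivariate polynomial basis of total order <= degree on normalized frame
# coordinates u, v in [-1, 1]. Shared by the phantom's planted shading and
# the illumination-estimation fit so that "order-4 shading" means the same
# thing on both sides.

poly2d_terms <- function(degree = 4) {
  out <- NULL
  for (d in 0:degree)
    for (i in d:0) out <- rbind(out, c(i = i, j = d - i))
  rownames(out) <- sprintf("u%dv%d", out[, "i"], out[, "j"])
  out
}

poly2d_design <- function(u, v, degree = 4) {
  terms <- poly2d_terms(degree)
  m <- matrix(NA_real_, length(u), nrow(terms),
              dimnames = list(NULL, rownames(terms)))
  for (k in seq_len(nrow(terms)))
    m[, k] <- u^terms[k, "i"] * v^terms[k, "j"]
  m
}

# Frame pixel-center coordinates mapped to [-1, 1] x [-1, 1], row-major grid.
frame_coords <- function(nrow_px, ncol_px = nrow_px) {
  u <- (2 * (seq_len(ncol_px) - 0.5) / ncol_px) - 1
  v <- (2 * (seq_len(nrow_px) - 0.5) / nrow_px) - 1
  list(u = rep(u, each = nrow_px), v = rep(v, times = ncol_px))
}

# Evaluate named coefficient vector (names u{i}v{j}) over a frame.
eval_poly2d_field <- function(coefficients, nrow_px, ncol_px = nrow_px,
                              degree = 4) {
  cc <- frame_coords(nrow_px, ncol_px)
  X <- poly2d_design(cc$u, cc$v, degree)
  coef_full <- setNames(numeric(ncol(X)), colnames(X))
  common <- intersect(names(coefficients), names(coef_full))
  if (length(common) != length(coefficients))
    stop("unknown polynomial term(s): ",
         paste(setdiff(names(coefficients), names(coef_full)), collapse = ", "))
  coef_full[common] <- unlist(coefficients)[common]
  matrix(X %*% coef_full, nrow_px, ncol_px)
}
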