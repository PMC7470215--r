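#' The ten pairwise classifier input specifications
#'
#' One binary SVM per unordered pair of the five tissue classes. Each pair
#' sees the selected CARS wavenumbers plus exactly one morphology channel:
#' TPF for the pairs \{cancer cells, fat\}, \{cancer cells, healthy cells\}
#' and \{fat, healthy cells\}; SHG for the remaining seven pairs. Giving
#' every SVM all channels proved detrimental on the original study, hence
#' the per-pair assignment.
#'
#' @param classes class names to restrict to (default all five; pairs with
#'   both members present are kept).
#' @return data.frame with columns `class_a`, `class_b` (names), `code_a`,
#'   `code_b`, `modality` (`"shg"` or `"tpf"`).
#' @export
default_pair_specs <- function(classes = names(tissue_classes())) {
  cls <- names(tissue_classes())
  tpf_pairs <- list(c("cancer_cells", "fat"),
                    c("cancer_cells", "healthy_cells"),
                    c("fat", "healthy_cells"))
  pairs <- t(combn(cls, 2))
  modality <- apply(pairs, 1, function(p) {
    hit <- any(vapply(tpf_pairs, function(q) setequal(p, q), logical(1)))
    if (hit) "tpf" else "shg"
  })
  out <- data.frame(class_a = pairs[, 1], class_b = pairs[, 2],
                    code_a = tissue_classes()[pairs[, 1]],
                    code_b = tissue_classes()[pairs[, 2]],
                    modality = modality, row.names = NULL)
  out[out$class_a %in% classes & out$class_b %in% classes, , drop = FALSE]
}

#' Class-balanced training subsampling
#'
#' Classes listed in `always_full` (by default fat and healthy cells, the
#' scarce classes) keep all their records; every other class is uniformly
#' subsampled without replacement to at most `cap` records (default
#' 30,000).
#'
#' @param table a `"SpectrumTable"`.
#' @param cap maximum records per subsampled class.
#' @param always_full class names never subsampled.
#' @param seed integer seed; selections are reproducible.
#' @return the subsampled table (row order: original order within class,
#'   classes in code order).
#' @export
subsample_training <- function(table, cap = 30000,
                               always_full = c("fat", "healthy_cells"),
                               seed = 1L) {
  stopifnot(cap >= 1)
  codes <- tissue_classes()
  full_codes <- codes[intersect(always_full, names(codes))]
  keep <- integer(0)
  with_seed(seed, {
    for (k in sort(unique(table$label))) {
      idx <- which(table$label == k)
      if (length(idx) == 0) {
        warning("empty class ", k, " omitted")
        next
      }
      if (!(k %in% full_codes) && length(idx) > cap)
        idx <- sort(sample(idx, cap))
      keep <- c(keep, idx)
    }
  })
  table[keep, , drop = FALSE]
}

build_feature_matrix <- function(table, wavenumbers, modality = NULL) {
  cols <- character(0)
  if (length(wavenumbers)) {
    cols <- cars_colname(wavenumbers)
    missing <- setdiff(cols, names(table))
    if (length(missing))
      stop("feature column(s) absent from table: ",
           paste(missing, collapse = ", "))
  }
  if (!is.null(modality)) cols <- c(cols, modality)
  as.matrix(table[, cols, drop = FALSE])
}

#' Train the pairwise SVM ensemble
#'
#' One linear SVM per pair spec, trained only on that pair's two classes,
#' on the feature set's CARS wavenumbers plus the pair's modality channel
#' (per [default_pair_specs()]). Features are z-scored with statistics of
#' the full training table, stored in the ensemble and re-applied at
#' prediction.
#'
#' @param table a `"SpectrumTable"` of training records.
#' @param feature_set a [feature_set()] (or list with `wavenumbers`,
#'   `include_shg`, `include_tpf`).
#' @param pair_specs pair table as from [default_pair_specs()].
#' @param svm_params list; `C` (default 1), `tol`, `max_iter`.
#' @param seed integer seed forwarded to the SVM solver.
#' @return object of class `"PairwiseEnsemble"`.
#' @export
train_ensemble <- function(table, feature_set,
                           pair_specs = default_pair_specs(),
                           svm_params = list(), seed = 1L) {
  need <- sort(unique(c(pair_specs$code_a, pair_specs$code_b)))
  for (k in need) {
    if (sum(table$label == k) < 2)
      stop("class ", names(tissue_classes())[k],
           " has fewer than 2 training records")
  }
  wns <- feature_set$wavenumbers
  use_shg <- isTRUE(feature_set$include_shg %||% TRUE)
  use_tpf <- isTRUE(feature_set$include_tpf %||% TRUE)
  all_cols <- c(if (length(wns)) cars_colname(wns),
                if (use_shg) "shg", if (use_tpf) "tpf")
  if (length(all_cols) == 0) stop("empty feature set")
  missing <- setdiff(all_cols, names(table))
  if (length(missing))
    stop("feature column(s) absent from table: ",
         paste(missing, collapse = ", "))
  scaling <- feature_scaling(table[, all_cols, drop = FALSE])
  C <- svm_params$C %||% 1
  tol <- svm_params$tol %||% 1e-4
  max_iter <- svm_params$max_iter %||% 200
  members <- vector("list", nrow(pair_specs))
  for (i in seq_len(nrow(pair_specs))) {
    sp <- pair_specs[i, ]
    mod_col <- switch(sp$modality,
                      shg = if (use_shg) "shg",
                      tpf = if (use_tpf) "tpf",
                      stop("unknown modality: ", sp$modality))
    cols <- c(if (length(wns)) cars_colname(wns), mod_col)
    if (length(cols) == 0) stop("pair ", sp$class_a, "/", sp$class_b,
                                " has no features")
    rows <- table$label %in% c(sp$code_a, sp$code_b)
    sub_scaling <- list(center = scaling$center[cols],
                        scale = scaling$scale[cols])
    x <- apply_scaling(table[rows, cols, drop = FALSE], sub_scaling)
    fit <- linear_svm(x, table$label[rows], C = C, positive = sp$code_a,
                      tol = tol, max_iter = max_iter,
                      seed = derive_seed(seed, paste0("pair", i)))
    members[[i]] <- list(spec = sp, columns = cols, fit = fit,
                         scaling = sub_scaling)
  }
  structure(list(members = members, pair_specs = pair_specs,
                 feature_set = feature_set, scaling = scaling,
                 classes = need, seed = seed),
            class = "PairwiseEnsemble")
}

#' Majority-vote block prediction
#'
#' Every ensemble member votes for one of its two classes; a block's
#' prediction is the class with the most votes. Ties are broken by the
#' summed signed decision-function values accumulated per class (margin
#' information already computed), which is deterministic.
#'
#' @param ensemble a `"PairwiseEnsemble"`.
#' @param table a `"SpectrumTable"` with the ensemble's feature columns.
#' @return object of class `"PixelClassMap"`: `predictions` (integer class
#'   codes aligned to table rows), `votes` (n x 5 tally matrix),
#'   `margins`, plus the block coordinates and sample ids.
#' @export
predict_blocks <- function(ensemble, table) {
  n <- nrow(table)
  votes <- matrix(0L, n, 5, dimnames = list(NULL, names(tissue_classes())))
  margins <- matrix(0, n, 5, dimnames = dimnames(votes))
  for (m in ensemble$members) {
    x <- apply_scaling(table[, m$columns, drop = FALSE], m$scaling)
    d <- decision_values(m$fit, x)   # > 0 means class_a
    a <- m$spec$code_a; b <- m$spec$code_b
    votes[, a] <- votes[, a] + (d > 0)
    votes[, b] <- votes[, b] + (d <= 0)
    margins[, a] <- margins[, a] + d
    margins[, b] <- margins[, b] - d
  }
  top <- apply(votes, 1, max)
  pred <- integer(n)
  for (i in seq_len(n)) {
    tied <- which(votes[i, ] == top[i])
    pred[i] <- if (length(tied) == 1) tied
               else tied[which.max(margins[i, tied])]
  }
  structure(list(predictions = pred, votes = votes, margins = margins,
                 block_row = table$block_row, block_col = table$block_col,
                 sample_id = table$sample_id),
            class = "PixelClassMap")
}

#' Per-sample cancer/healthy call
#'
#' Sums blocks predicted as cancerous (cancer cells + cancer connective)
#' and healthy (healthy cells + healthy connective); fat blocks are
#' excluded. The larger count wins; an exact tie is called `"cancer"`
#' (the clinically conservative choice). A map containing only fat or
#' unclassified blocks is `"indeterminate"`.
#'
#' @param class_map a `"PixelClassMap"`, or an integer vector/matrix of
#'   predicted class codes.
#' @return `"cancer"`, `"healthy"`, or `"indeterminate"`, with attribute
#'   `counts`.
#' @export
call_sample <- function(class_map) {
  pred <- if (inherits(class_map, "PixelClassMap")) class_map$predictions
          else as.integer(class_map)
  if (length(pred) == 0) stop("empty class map")
  cancer <- sum(pred %in% c(2L, 3L))
  healthy <- sum(pred %in% c(4L, 5L))
  call <- if (cancer == 0 && healthy == 0) "indeterminate"
          else if (cancer >= healthy) "cancer" else "healthy"
  structure(call, counts = c(cancer = cancer, healthy = healthy,
                             fat = sum(pred == 1L)))
}
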