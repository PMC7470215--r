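#' Feature set container
#'
#' @param wavenumbers selected CARS wavenumbers (cm^-1).
#' @param include_shg,include_tpf whether the morphology channels are
#'   offered to the ensemble (per-pair usage still follows the pair specs).
#' @param ranking full feature ranking the set was read from, if any.
#' @param occurrence_counts named per-wavenumber tallies (SFS only).
#' @param exhausted `TRUE` when a distance-constrained read-out could not
#'   reach the requested size.
#' @return list of class `"FeatureSet"`.
#' @export
feature_set <- function(wavenumbers, include_shg = TRUE, include_tpf = TRUE,
                        ranking = NULL, occurrence_counts = NULL,
                        exhausted = FALSE) {
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 include_shg = include_shg, include_tpf = include_tpf,
                 ranking = ranking, occurrence_counts = occurrence_counts,
                 exhausted = exhausted),
            class = "FeatureSet")
}

# Fold assignment: stratified by label, or group-aware by sample id so
# blocks from one sample never span train and test.
make_folds <- function(table, k, seed, group_aware = FALSE) {
  n <- nrow(table)
  fold <- integer(n)
  with_seed(seed, {
    if (group_aware) {
      ids <- unique(table$sample_id)
      if (length(ids) < k) k <- length(ids)
      fid <- setNames(sample(rep(seq_len(k), length.out = length(ids))), ids)
      fold <- as.integer(fid[as.character(table$sample_id)])
    } else {
      for (lab in unique(table$label)) {
        idx <- which(table$label == lab)
        fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
    }
  })
  fold
}

# Cross-validated pooled accuracy of the pairwise ensemble restricted to
# the given wavenumbers (the "accuracy of an SVM classifier" criterion;
# a single SVM when only two classes are present).
cv_ensemble_accuracy <- function(table, wavenumbers, include_shg = TRUE,
                                 include_tpf = TRUE, folds = 5, seed = 1L,
                                 svm_params = list(), group_aware = FALSE,
                                 return_predictions = FALSE) {
  classes <- names(tissue_classes())[sort(unique(table$label))]
  specs <- default_pair_specs(classes)
  fs <- feature_set(wavenumbers, include_shg, include_tpf)
  fold <- make_folds(table, folds, seed, group_aware)
  pred <- integer(nrow(table))
  for (f in sort(unique(fold))) {
    tr <- table[fold != f, , drop = FALSE]
    te <- table[fold == f, , drop = FALSE]
    # a pair is trainable only when both classes have >= 2 records in
    # this training fold (small group-aware folds can starve a class)
    cnt <- table(factor(tr$label, levels = 1:5))
    tr_classes <- names(tissue_classes())[cnt >= 2]
    ens <- train_ensemble(tr, fs, default_pair_specs(tr_classes),
                          svm_params, seed = derive_seed(seed, paste0("cv", f)))
    pred[fold == f] <- predict_blocks(ens, te)$predictions
  }
  acc <- mean(pred == table$label)
  if (return_predictions) list(accuracy = acc, predictions = pred,
                               truth = table$label, fold = fold)
  else acc
}

# Aggregate squared linear-SVM weights per feature over all pairwise
# classifiers (the multiclass extension of weight-based ranking).
aggregate_pair_weights <- function(table, wavenumbers, svm_params, seed) {
  classes <- sort(unique(table$label))
  if (length(classes) < 2) stop("need at least 2 classes")
  cols <- cars_colname(wavenumbers)
  scaling <- feature_scaling(table[, cols, drop = FALSE])
  x <- apply_scaling(table[, cols, drop = FALSE], scaling)
  C <- svm_params$C %||% 1
  tol <- svm_params$tol %||% 1e-4
  max_iter <- svm_params$max_iter %||% 200
  agg <- setNames(numeric(length(wavenumbers)), cols)
  pairs <- t(combn(classes, 2))
  for (i in seq_len(nrow(pairs))) {
    rows <- table$label %in% pairs[i, ]
    fit <- linear_svm(x[rows, , drop = FALSE], table$label[rows],
                      C = C, positive = pairs[i, 2], tol = tol,
                      max_iter = max_iter,
                      seed = derive_seed(seed, paste0("rfe_pair", i)))
    agg <- agg + fit$w^2
  }
  agg
}

#' Multiclass SVM recursive feature elimination
#'
#' Repeatedly trains all pairwise linear SVMs on the remaining CARS
#' wavenumbers (z-scored), scores each wavenumber by the sum over the
#' binary classifiers of its squared weight, and eliminates the
#' lowest-scoring one, until a single feature remains. The ranking is the
#' reverse elimination order (best first). Deterministic given the seed;
#' randomness enters only through optional class subsampling.
#'
#' @param table a `"SpectrumTable"` with at least two classes and two
#'   CARS features.
#' @param svm_params list; `C` (default 1), `tol`, `max_iter`; requesting a
#'   non-linear kernel is unsupported.
#' @param cap optional per-class subsample cap applied once up front via
#'   [subsample_training()].
#' @param seed integer seed.
#' @return list of class `"RFERanking"`: `ranking` (wavenumbers, best
#'   first), `elimination_order`, `scores` (aggregate weight at
#'   elimination time).
#' @export
rfe_rank <- function(table, svm_params = list(), cap = NULL, seed = 1L) {
  if (!is.null(svm_params$kernel) && svm_params$kernel != "linear")
    stop("unsupported kernel for RFE: ", svm_params$kernel,
         " (weight-based elimination needs a linear kernel)")
  if (length(unique(table$label)) < 2)
    stop("RFE requires at least 2 classes")
  wns <- table_wavenumbers(table)
  if (length(wns) < 1) stop("table has no CARS features")
  if (length(wns) == 1)
    return(structure(list(ranking = wns, elimination_order = numeric(0),
                          scores = numeric(0)), class = "RFERanking"))
  if (!is.null(cap))
    table <- subsample_training(table, cap = cap,
                                seed = derive_seed(seed, "rfe_subsample"))
  remaining <- wns
  eliminated <- numeric(0)
  scores <- numeric(0)
  while (length(remaining) > 1) {
    agg <- aggregate_pair_weights(table, remaining, svm_params, seed)
    worst <- which.min(agg)
    eliminated <- c(eliminated, remaining[worst])
    scores <- c(scores, agg[worst])
    remaining <- remaining[-worst]
  }
  structure(list(ranking = c(remaining, rev(eliminated)),
                 elimination_order = eliminated,
                 scores = scores),
            class = "RFERanking")
}

#' Greedy distance-constrained read-out of a ranking
#'
#' Walks the ranking from the top, accepting a wavenumber iff it differs
#' by at least `min_distance` from every already-accepted one (Raman peaks
#' in the high-wavenumber window are about 40 cm^-1 wide, so closer
#' features are redundant), until `k` accepted or the ranking is
#' exhausted.
#'
#' @param ranking wavenumber ranking, best first (an `"RFERanking"` or
#'   numeric vector).
#' @param k number of wavenumbers wanted.
#' @param min_distance minimum pairwise distance in cm^-1 (default 40).
#' @param include_shg,include_tpf flags stored on the returned set.
#' @return a [feature_set()]; `exhausted` is `TRUE` (with a warning) when
#'   fewer than `k` could be accepted.
#' @export
apply_distance_constraint <- function(ranking, k, min_distance = 40,
                                      include_shg = TRUE,
                                      include_tpf = TRUE) {
  stopifnot(k >= 1)
  rk <- if (inherits(ranking, "RFERanking")) ranking$ranking
        else as.numeric(ranking)
  accepted <- numeric(0)
  for (wn in rk) {
    if (length(accepted) == k) break
    if (all(abs(wn - accepted) >= min_distance))
      accepted <- c(accepted, wn)
  }
  exhausted <- length(accepted) < k
  if (exhausted)
    warning("only ", length(accepted), " of ", k,
            " wavenumbers satisfy the ", min_distance, " cm^-1 constraint")
  feature_set(accepted, include_shg, include_tpf, ranking = rk,
              exhausted = exhausted)
}

#' Occurrence-voted sequential forward selection
#'
#' Each repeat starts from an empty set and greedily adds the wavenumber
#' that maximizes cross-validated classifier accuracy, until
#' `max_features` are included. Because single greedy runs make local
#' decisions, the selection is repeated (default 20 times, with different
#' fold shuffles) and the final ordering is by occurrence count across
#' repeats, ties broken by mean selection step (earlier is better).
#'
#' @param table a `"SpectrumTable"`.
#' @param max_features features per repeat (default 30; capped with a
#'   warning when the table has fewer).
#' @param repeats number of repeats (default 20).
#' @param svm_params SVM parameter list.
#' @param folds CV folds for the criterion (default 5, stratified).
#' @param seed integer seed; the whole selection is reproducible.
#' @return a [feature_set()] with `occurrence_counts` and the
#'   occurrence-ordered `wavenumbers`.
#' @export
sfs_select <- function(table, max_features = 30, repeats = 20,
                       svm_params = list(), folds = 5, seed = 1L) {
  stopifnot(repeats >= 1)
  wns <- table_wavenumbers(table)
  if (max_features > length(wns)) {
    warning("max_features capped at the ", length(wns), " available features")
    max_features <- length(wns)
  }
  occ <- setNames(numeric(length(wns)), cars_colname(wns))
  step_sum <- setNames(numeric(length(wns)), cars_colname(wns))
  first_order <- NULL
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(seed, paste0("sfs_rep", r))
    selected <- numeric(0)
    candidates <- wns
    for (step in seq_len(max_features)) {
      acc <- vapply(candidates, function(wn)
        cv_ensemble_accuracy(table, c(selected, wn),
                             folds = folds, seed = rseed,
                             svm_params = svm_params), numeric(1))
      best <- candidates[which.max(acc)]
      selected <- c(selected, best)
      candidates <- setdiff(candidates, best)
      occ[cars_colname(best)] <- occ[cars_colname(best)] + 1
      step_sum[cars_colname(best)] <- step_sum[cars_colname(best)] + step
    }
    if (r == 1) first_order <- selected
  }
  mean_step <- ifelse(occ > 0, step_sum / occ, Inf)
  ord <- order(-occ, mean_step)
  chosen <- ord[occ[ord] > 0]
  final <- if (repeats == 1) first_order
           else as.numeric(sub("^cars_", "", names(occ)[chosen]))
  feature_set(final, occurrence_counts = occ,
              ranking = as.numeric(sub("^cars_", "", names(occ)[ord])))
}

#' Performance sweep over the number of CARS wavenumbers
#'
#' For each `k`, reads the top-k distance-constrained feature set off the
#' ranking, cross-validates the pairwise ensemble, and records accuracy,
#' multiclass and binary Matthews correlation, sensitivity and
#' specificity. `k = 0` evaluates the morphology channels alone.
#'
#' @param table a `"SpectrumTable"`.
#' @param ranking wavenumber ranking, best first ([rfe_rank()] output, an
#'   SFS [feature_set()], or a numeric vector).
#' @param k_range integer vector of feature counts (may include 0).
#' @param min_distance distance constraint for the read-out (default 40).
#' @param include_shg,include_tpf morphology flags.
#' @param folds CV folds (default 5).
#' @param group_aware use sample-level folds (default TRUE).
#' @param svm_params SVM parameter list.
#' @param seed integer seed.
#' @return list of class `"FeatureSweep"`: `curve` (data.frame with one
#'   row per k), `best_k` (argmax of MCC).
#' @export
sweep_feature_count <- function(table, ranking, k_range, min_distance = 40,
                                include_shg = TRUE, include_tpf = TRUE,
                                folds = 5, group_aware = TRUE,
                                svm_params = list(), seed = 1L) {
  if (length(k_range) == 0) stop("empty k_range")
  rk <- if (inherits(ranking, "RFERanking")) ranking$ranking
        else if (inherits(ranking, "FeatureSet")) ranking$wavenumbers
        else as.numeric(ranking)
  rows <- lapply(k_range, function(k) {
    wns <- if (k == 0) numeric(0)
           else suppressWarnings(
             apply_distance_constraint(rk, k, min_distance)$wavenumbers)
    res <- cv_ensemble_accuracy(table, wns, include_shg, include_tpf,
                                folds = folds, seed = seed,
                                svm_params = svm_params,
                                group_aware = group_aware,
                                return_predictions = TRUE)
    met <- compute_metrics(res$predictions, res$truth)
    data.frame(k = k, n_features = length(wns),
               accuracy = met$accuracy,
               mcc_multiclass = met$mcc_multiclass,
               mcc_binary = met$mcc_binary,
               sensitivity = met$sensitivity,
               specificity = met$specificity)
  })
  curve <- do.call(rbind, rows)
  structure(list(curve = curve,
                 best_k = curve$k[which.max(curve$mcc_multiclass)]),
            class = "FeatureSweep")
}
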