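two_class_means <- function(delta, wavenumbers) {
  m <- rbind(`2` = c(0, 0, 0)[seq_along(wavenumbers)],
             `4` = delta[seq_along(wavenumbers)])
  colnames(m) <- sprintf("%g", wavenumbers)
  m
}

test_that("RFE eliminates a pure-noise feature before a separating one", {
  wns <- c(2800, 3000)
  tab <- make_toy_table(60, two_class_means(c(0, 2), wns), wns,
                        noise = 0.3, seed = 5)
  rk <- rfe_rank(tab)
  expect_equal(rk$elimination_order[1], 2800)
  expect_equal(rk$ranking[1], 3000)
})

test_that("RFE handles degenerate inputs per contract", {
  wns <- c(2800, 3000)
  tab <- make_toy_table(20, two_class_means(c(1, 1), wns), wns, seed = 1)
  one_class <- tab[tab$label == 2, ]
  expect_error(rfe_rank(one_class), "2 classes")
  expect_error(rfe_rank(tab, svm_params = list(kernel = "rbf")),
               "unsupported kernel")
  single <- tab[, c("sample_id", "block_row", "block_col", "label",
                    "shg", "tpf", "cars_2800")]
  class(single) <- class(tab)
  expect_equal(rfe_rank(single)$ranking, 2800)
})

test_that("first RFE elimination matches the exhaustive oracle", {
  for (trial in 1:5) {
    set.seed(200 + trial)
    wns <- c(2700, 2800, 2900, 3000, 3100)[1:sample(3:5, 1)]
    k <- length(wns)
    n_cls <- sample(2:3, 1)
    means <- matrix(rnorm(n_cls * k, 0, 1), n_cls, k,
                    dimnames = list(as.character(seq_len(n_cls) + 1), NULL))
    tab <- make_toy_table(30, means, wns, noise = 0.5, seed = 300 + trial)
    rk <- rfe_rank(tab, svm_params = list(tol = 1e-8, max_iter = 5000))
    agg <- oracle_aggregate_weights(tab, wns)
    expect_equal(rk$elimination_order[1],
                 as.numeric(sub("cars_", "", names(which.min(agg)))))
  }
})

test_that("distance constraint: forced skip, vacuous case, exhaustion", {
  fsel <- apply_distance_constraint(c(2850, 2860, 2930), k = 2)
  expect_equal(fsel$wavenumbers, c(2850, 2930))
  expect_false(fsel$exhausted)

  expect_equal(apply_distance_constraint(c(2850, 2860, 2930), k = 2,
                                         min_distance = 0)$wavenumbers,
               c(2850, 2860))

  expect_warning(
    fsel3 <- apply_distance_constraint(c(2850, 2860, 2870), k = 3),
    "constraint")
  expect_equal(fsel3$wavenumbers, 2850)
  expect_true(fsel3$exhausted)
})

test_that("emitted constrained sets always pass a brute-force check", {
  set.seed(9)
  for (i in 1:20) {
    rk <- sample(seq(2700, 3200, by = 10), 30)
    k <- sample(1:10, 1)
    fs <- suppressWarnings(apply_distance_constraint(rk, k))
    w <- fs$wavenumbers
    if (length(w) > 1)
      expect_true(all(abs(outer(w, w, "-"))[lower.tri(diag(length(w)))] >= 40))
    expect_lte(length(w), k)
  }
})

test_that("SFS picks a perfectly separating feature first in every repeat", {
  wns <- c(2750, 2850, 2950)
  means <- rbind(`2` = c(0, 0, 8), `4` = c(0, 0.2, -8))
  tab <- make_toy_table(40, means, wns, noise = 0.4, seed = 11)
  fs <- sfs_select(tab, max_features = 2, repeats = 3, folds = 3, seed = 4)
  expect_equal(unname(fs$occurrence_counts["cars_2950"]), 3)
  expect_equal(fs$wavenumbers[1], 2950)

  # repeats = 1: final order is that repeat's selection order
  fs1 <- sfs_select(tab, max_features = 3, repeats = 1, folds = 3, seed = 4)
  expect_equal(fs1$wavenumbers[1], 2950)
  expect_length(fs1$wavenumbers, 3)

  # max_features = 1: exactly one wavenumber per repeat
  fs2 <- sfs_select(tab, max_features = 1, repeats = 2, folds = 3, seed = 4)
  expect_equal(sum(fs2$occurrence_counts), 2)

  expect_warning(sfs_select(tab, max_features = 10, repeats = 1, folds = 3),
                 "capped")
})

test_that("SFS first inclusion equals exhaustive single-feature search", {
  for (trial in 1:3) {
    wns <- c(2700, 2800, 2900, 3000)
    set.seed(400 + trial)
    means <- matrix(rnorm(8, 0, 1.5), 2, 4,
                    dimnames = list(c("2", "4"), NULL))
    tab <- make_toy_table(30, means, wns, noise = 0.8, seed = 500 + trial)
    seed <- 600 + trial
    fs <- sfs_select(tab, max_features = 1, repeats = 1, folds = 3,
                     seed = seed)
    rseed <- derive_seed(seed, "sfs_rep1")
    accs <- vapply(wns, function(wn)
      carsdelin:::cv_ensemble_accuracy(tab, wn, folds = 3, seed = rseed),
      numeric(1))
    expect_equal(fs$wavenumbers[1], wns[which.max(accs)])
  }
})

test_that("feature-count sweep runs, records metrics, and allows k = 0", {
  cfg <- tiny_phantom_config(seed = 23, frame_size = 48)
  ph <- generate_phantom(cfg)
  st <- power_calibrate(subtract_offset(ph$stack, ph$calibration),
                        ph$calibration)
  tab <- block_average(stitch(correct_illumination(
    st, estimate_illumination(st))), ph$label_map)
  tab$sample_id <- rep(c("a", "b"), length.out = nrow(tab))
  rk <- rfe_rank(tab, seed = 1)
  sw <- sweep_feature_count(tab, rk, k_range = c(0, 2, 4), folds = 2,
                            seed = 2)
  expect_equal(sw$curve$k, c(0, 2, 4))
  expect_equal(sw$curve$n_features[1], 0)
  expect_true(all(sw$curve$accuracy >= 0 & sw$curve$accuracy <= 1))
  expect_true(all(abs(sw$curve$mcc_multiclass) <= 1))
  expect_true(sw$best_k %in% sw$curve$k)
  # with informative CARS bands the spectral features must help
  expect_gt(max(sw$curve$accuracy[-1]), sw$curve$accuracy[1])
  expect_error(sweep_feature_count(tab, rk, integer(0)), "empty k_range")
})

test_that("the lipid band dominates fat discrimination", {
  # when the classification problem is fat-vs-cells, the CH2 stretch at
  # 2850 cm^-1 (or its nearest axis neighbour) carries the signal and must
  # rank in the top 3. In the full five-class problem the lipid peak is
  # informative but redundant (fat differs from soft tissue across the
  # whole CH-stretch region), so weight-based RFE top-ranks protein/water
  # wavenumbers instead -- the same behaviour the published wavenumber
  # list shows.
  cfg <- tiny_phantom_config(seed = 29, frame_size = 96,
                             classes = c("fat", "healthy_cells"))
  ph <- generate_phantom(cfg)
  st <- power_calibrate(subtract_offset(ph$stack, ph$calibration),
                        ph$calibration)
  tab <- block_average(stitch(correct_illumination(
    st, estimate_illumination(st))), ph$label_map)
  rk <- rfe_rank(tab, seed = 1)
  expect_true(any(abs(head(rk$ranking, 3) - 2850) <= 20))

  # five-class problem: the constrained 10-wavenumber read-out still
  # covers the CH2 region within the 40 cm^-1 peak width
  cfg5 <- tiny_phantom_config(seed = 29, frame_size = 96)
  ph5 <- generate_phantom(cfg5)
  st5 <- power_calibrate(subtract_offset(ph5$stack, ph5$calibration),
                         ph5$calibration)
  tab5 <- block_average(stitch(correct_illumination(
    st5, estimate_illumination(st5))), ph5$label_map)
  rk5 <- rfe_rank(tab5, seed = 1)
  k10 <- suppressWarnings(apply_distance_constraint(rk5, 10)$wavenumbers)
  expect_true(any(abs(k10 - 2850) <= 40))
})
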