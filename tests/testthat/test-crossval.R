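test_that("fold plans are balanced, disjoint, and cover all indices", {
  p10 <- make_folds(10, 10, seed = 1)
  expect_equal(sort(fold_sizes(p10)), rep(1L, 10))

  # the 160-fold sizing rule: 12,604 examples -> folds of 78 or 79
  p160 <- make_folds(12604, 160, seed = 2)
  expect_true(all(fold_sizes(p160) %in% c(78L, 79L)))
  expect_equal(sum(fold_sizes(p160)), 12604L)

  withr::with_seed(3, {
    for (rep in 1:10) {
      n <- sample(20:200, 1)
      k <- sample(2:10, 1)
      p <- make_folds(n, k, seed = rep)
      expect_equal(sort(unique(p$assignments)), 1:k)
      expect_equal(length(p$assignments), n)
      expect_lte(diff(range(fold_sizes(p))), 1L)
    }
  })
  expect_error(make_folds(5, 10), "k <= n")
})

test_that("train/validation splits are seeded, sized, and disjoint", {
  s <- split_train_validation(1:100, 0.20, seed = 4)
  expect_equal(length(s$validation), 20)
  expect_equal(length(s$train), 80)
  s30 <- split_train_validation(1:100, 0.30, seed = 4)
  expect_equal(length(s30$validation), 30)

  withr::with_seed(5, {
    for (rep in 1:10) {
      idx <- sample(1000, sample(10:50, 1))
      sp <- split_train_validation(idx, runif(1, 0.1, 0.9), seed = rep)
      expect_equal(sort(c(sp$train, sp$validation)), sort(idx))
      expect_length(intersect(sp$train, sp$validation), 0)
    }
  })
  expect_error(split_train_validation(1:3, 0.01), "empty")
})

test_that("cross-validation trains one model per fold, never on its own fold", {
  ds <- make_benchmark(separation = 0.5, n_per_class = 50, seed = 41)
  cv <- crossval_train(ds, hidden = 4, val_fraction = 0.2, k = 5,
                       config = test_config(), seed = 6)
  expect_equal(nrow(cv), 5)
  expect_equal(cv$fold, 1:5)
  plan <- attr(cv, "fold_plan")
  for (i in 1:5) {
    test_idx <- which(plan$assignments == cv$fold[i])
    prov <- cv$model[[i]]$provenance
    expect_length(intersect(prov$train_indices, test_idx), 0)
    expect_length(intersect(prov$val_indices, test_idx), 0)
    expect_length(intersect(prov$train_indices, prov$val_indices), 0)
  }
  # well-separated classes are learned almost perfectly
  expect_gte(mean(cv$accuracy), 0.95)

  # determinism from the master seed
  cv2 <- crossval_train(ds, hidden = 4, val_fraction = 0.2, k = 5,
                        config = test_config(), seed = 6)
  expect_identical(cv$accuracy, cv2$accuracy)
})

test_that("shuffled labels yield chance-level accuracy", {
  ds <- make_benchmark(separation = 0.5, n_per_class = 1000, seed = 43)
  shuffled <- labeled_dataset(ds$features,
                              withr::with_seed(44, sample(ds$labels)),
                              ds$ids)
  cv <- crossval_train(shuffled, hidden = 4, val_fraction = 0.2, k = 5,
                       config = test_config(max_epochs = 15), seed = 7)
  expect_equal(mean(cv$accuracy), 0.5, tolerance = 0.05)
})

test_that("grid search is factorial, deterministic, and tie-breaks small", {
  ds <- make_benchmark(separation = 0.7, n_per_class = 40, seed = 45)
  grid <- grid_search(ds, architectures = list(3L, 9L),
                      val_fractions = c(0.2, 0.3), k = 4,
                      config = test_config(max_epochs = 20), seed = 8)
  expect_equal(nrow(grid), 4)
  expect_setequal(grid$architecture, c("3", "9"))

  # a singleton grid reduces exactly to crossval_train
  g1 <- grid_search(ds, architectures = list(3L), val_fractions = 0.2,
                    k = 4, config = test_config(max_epochs = 20), seed = 8)
  cv <- crossval_train(ds, hidden = 3L, val_fraction = 0.2, k = 4,
                       config = test_config(max_epochs = 20), seed = 8)
  expect_equal(g1$mean_accuracy, mean(cv$accuracy))

  # duplicated grid points give identical rows under the shared seed
  g2 <- grid_search(ds, architectures = list(3L, 3L), val_fractions = 0.2,
                    k = 4, config = test_config(max_epochs = 20), seed = 8)
  expect_equal(g2$mean_accuracy[1], g2$mean_accuracy[2])

  # ties go to the smaller network: on this easy problem both nets are
  # perfect, so the 3-unit net must win over the 9-unit one
  if (grid$mean_accuracy[grid$architecture == "3"][1] ==
      max(grid$mean_accuracy)) {
    best <- grid[attr(grid, "best"), ]
    expect_equal(best$architecture, "3")
  }
})

test_that("voter selection ranks by accuracy with deterministic ties", {
  fake_model <- function(tag) structure(list(tag = tag), class = "mlp_model")
  cv <- tibble::tibble(fold = 1:6,
                       accuracy = c(0.7, 0.9, 0.8, 0.9, 0.6, 0.95),
                       n_test = 10,
                       model = lapply(1:6, fake_model))
  ens <- select_voters(cv, 3)
  expect_equal(ens$folds, c(6, 2, 4))  # 0.95, then the 0.9 tie by fold
  expect_equal(ens$accuracy, c(0.95, 0.9, 0.9))

  # permuting the input rows does not change the selected set
  perm <- cv[c(4, 1, 6, 2, 5, 3), ]
  ens2 <- select_voters(perm, 3)
  expect_equal(ens2$folds, ens$folds)

  expect_equal(select_voters(cv, "all")$size, 6)
  expect_error(select_voters(cv, 0), ">= 1")
  expect_error(select_voters(cv, 7), "available")
})

test_that("mean-output voting follows the >0 / <=0 rule and majority logic", {
  # all members saturated positive -> mean ~1, positive call
  ens_pos <- structure(list(members = lapply(c(0.999999, 0.999999),
                                             constant_model),
                            accuracy = c(1, 1), folds = 1:2, size = 2L,
                            decision_threshold = 0),
                       class = "mlp_ensemble")
  p <- ensemble_predict(ens_pos, matrix(0.5))
  expect_equal(p$mean_output, 1, tolerance = 1e-5)
  expect_equal(p$decision, "positive")

  # outputs {+0.5, -0.5}: mean 0 is a negative call
  ens_zero <- structure(list(members = lapply(c(0.5, -0.5), constant_model),
                             accuracy = c(1, 1), folds = 1:2, size = 2L,
                             decision_threshold = 0),
                        class = "mlp_ensemble")
  pz <- ensemble_predict(ens_zero, matrix(0.5))
  expect_equal(pz$mean_output, 0, tolerance = 1e-12)
  expect_equal(pz$decision, "negative")

  # with saturated +-1 members, mean-sign equals majority vote: enumerate
  # all 2^5 sign patterns
  for (bits in 0:31) {
    signs <- ifelse(bitwAnd(bits, 2^(0:4)) > 0, 1, -1)
    ens <- structure(list(members = lapply(signs * 0.8, constant_model),
                          accuracy = rep(1, 5), folds = 1:5, size = 5L,
                          decision_threshold = 0),
                     class = "mlp_ensemble")
    pm <- ensemble_predict(ens, matrix(0))
    pv <- ensemble_predict(ens, matrix(0), combiner = "majority")
    expect_equal(pm$decision, if (sum(signs) > 0) "positive" else "negative")
    expect_equal(pv$decision, pm$decision)
  }
})

test_that("ensembles round-trip through a directory", {
  ds <- make_benchmark(separation = 0.5, n_per_class = 30, seed = 47)
  cv <- crossval_train(ds, hidden = 3, val_fraction = 0.2, k = 4,
                       config = test_config(max_epochs = 10), seed = 9)
  ens <- select_voters(cv, 3)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  expect_equal(back$size, 3L)
  expect_equal(back$accuracy, ens$accuracy)
  p1 <- ensemble_predict(ens, ds$features)
  p2 <- ensemble_predict(back, ds$features)
  expect_identical(p1$mean_output, p2$mean_output)
})
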