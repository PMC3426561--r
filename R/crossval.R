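#' Random K-fold partition
#'
#' Seeded uniform partition of `n` indices into `k` disjoint folds whose
#' sizes differ by at most one.  With `n = 12604` and `k = 160` the folds
#' hold 78 or 79 examples -- the average phage genome's gene count, which is
#' the sizing rule behind 160-fold cross-validation of the full structural
#' set.
#'
#' @param n number of examples (>= k).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return an object of class `fold_plan`: list with `n`, `k`, `seed`, and
#'   `assignments` (integer vector, fold id per index).
#' @export
make_folds <- function(n, k, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= n (got k = ", k, ", n = ", n, ")")
  base <- rep(seq_len(k), length.out = n)  # balanced sizes
  assignments <- withr::with_seed(seed, sample(base))
  structure(list(n = n, k = k, seed = as.integer(seed),
                 assignments = assignments),
            class = "fold_plan")
}

#' Fold sizes of a plan
#' @param plan a `fold_plan`.
#' @return integer vector of length `k`.
#' @export
fold_sizes <- function(plan) {
  as.integer(table(factor(plan$assignments, levels = seq_len(plan$k))))
}

#' Split indices into training and validation sets
#'
#' Seeded random split; the validation side receives
#' `round(val_fraction * n)` indices.  The tested split ratios follow the
#' usual train:validation grids (95/5, 80/20, 70/30, 60/40, 50/50).
#'
#' @param indices integer vector to split.
#' @param val_fraction fraction assigned to validation, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `validation` index vectors (disjoint,
#'   covering `indices`).
#' @export
split_train_validation <- function(indices, val_fraction, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  n <- length(indices)
  n_val <- round(val_fraction * n)
  if (n_val == 0L || n_val == n) {
    stop("split leaves an empty side (n = ", n,
         ", val_fraction = ", val_fraction, ")")
  }
  val <- withr::with_seed(seed, sample(indices, n_val))
  list(train = setdiff(indices, val), validation = val)
}

sign_accuracy <- function(outputs, labels) {
  pred <- ifelse(outputs > 0, 1, -1)
  mean(pred == labels)
}

#' Train one network per cross-validation fold
#'
#' For each fold: the fold is the test set; the remaining examples are split
#' into training and validation sets; a network with the given hidden
#' architecture is initialized and trained by Levenberg-Marquardt with early
#' stopping; its held-out accuracy is the fraction of test examples whose
#' output sign matches the label (positive iff output > 0).  All randomness
#' derives from `seed`, so a run is reproducible from one integer.
#'
#' @param dataset a `labeled_dataset`.
#' @param hidden integer vector of hidden layer sizes (length 1 or 2).
#' @param val_fraction validation fraction of the non-test examples.
#' @param k number of folds.
#' @param config a [training_config()].
#' @param seed master seed.
#' @return a tibble with columns `fold`, `accuracy`, `n_test`, and a
#'   list-column `model`.
#' @export
crossval_train <- function(dataset, hidden = 40L, val_fraction = 0.3,
                           k = 10L, config = training_config(),
                           seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset$features)
  layer_sizes <- c(ncol(dataset$features), as.integer(hidden), 1L)
  plan <- make_folds(n, k, seed = derive_seed(seed, 1L))
  rows <- vector("list", plan$k)
  for (fold in seq_len(plan$k)) {
    test_idx <- which(plan$assignments == fold)
    rest <- which(plan$assignments != fold)
    if (length(unique(dataset$labels[test_idx])) < 2L) {
      warning("fold ", fold, " contains a single class; accuracy is still ",
              "defined but uninformative")
    }
    split <- split_train_validation(rest, val_fraction,
                                    seed = derive_seed(seed, 1000L + fold))
    model <- init_model(layer_sizes,
                        dataset$features[split$train, , drop = FALSE],
                        seed = derive_seed(seed, 2000L + fold),
                        init = config$init)
    fit <- train_mlp(model,
                     dataset$features[split$train, , drop = FALSE],
                     dataset$labels[split$train],
                     dataset$features[split$validation, , drop = FALSE],
                     dataset$labels[split$validation],
                     config = config)
    fit$model$provenance$test_fold <- fold
    fit$model$provenance$train_indices <- split$train
    fit$model$provenance$val_indices <- split$validation
    out <- forward(fit$model, dataset$features[test_idx, , drop = FALSE])
    rows[[fold]] <- tibble::tibble(
      fold = fold,
      accuracy = sign_accuracy(out, dataset$labels[test_idx]),
      n_test = length(test_idx),
      model = list(fit$model))
  }
  out <- do.call(rbind, rows)
  attr(out, "fold_plan") <- plan
  out
}

#' Grid search over architectures and validation fractions
#'
#' Full factorial evaluation by [crossval_train()], with the same master
#' seed (hence identical folds and splits) for every grid point so
#' comparisons are paired.  The winner is the grid point with the highest
#' mean accuracy; ties go to the smaller network (fewer total hidden units),
#' then to fewer layers, then to the smaller validation fraction.
#'
#' @param dataset a `labeled_dataset`.
#' @param architectures list of hidden-layer size vectors, e.g.
#'   `list(5, 40, c(90, 10))`.
#' @param val_fractions numeric vector of validation fractions.
#' @param k folds.
#' @param config a [training_config()].
#' @param seed master seed.
#' @return a tibble (`architecture`, `hidden_units`, `n_layers`,
#'   `val_fraction`, `mean_accuracy`, `sd_accuracy`) with the winning row
#'   index in `attr(, "best")`.
#' @export
grid_search <- function(dataset, architectures, val_fractions,
                        k = 10L, config = training_config(), seed = 1L) {
  stopifnot(length(architectures) > 0, length(val_fractions) > 0)
  grid <- expand.grid(arch = seq_along(architectures),
                      vf = seq_along(val_fractions))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    hidden <- architectures[[grid$arch[i]]]
    vf <- val_fractions[grid$vf[i]]
    cv <- crossval_train(dataset, hidden = hidden, val_fraction = vf,
                         k = k, config = config, seed = seed)
    tibble::tibble(architecture = paste(hidden, collapse = "x"),
                   hidden_units = sum(hidden),
                   n_layers = length(hidden),
                   val_fraction = vf,
                   mean_accuracy = mean(cv$accuracy),
                   sd_accuracy = stats::sd(cv$accuracy))
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$mean_accuracy, out$hidden_units, out$n_layers,
               out$val_fraction)
  attr(out, "best") <- ord[1]
  out
}
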