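#' Confusion counts at an output threshold
#'
#' An example is called positive when its (mean) output exceeds `threshold`
#' (strictly; an output exactly at the threshold is a negative call, the
#' same `> 0` / `<= 0` rule the voting ensembles use).
#'
#' @param outputs numeric vector of network or ensemble outputs.
#' @param labels vector of +1/-1 truth labels.
#' @param threshold decision threshold (default 0).
#' @return a list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(outputs, labels, threshold = 0) {
  stopifnot(length(outputs) == length(labels))
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1")
  pred_pos <- outputs > threshold
  truth_pos <- labels == 1
  structure(list(tp = sum(pred_pos & truth_pos),
                 fp = sum(pred_pos & !truth_pos),
                 tn = sum(!pred_pos & !truth_pos),
                 fn = sum(!pred_pos & truth_pos)),
            class = "confusion_counts")
}

#' Sensitivity (true positive rate)
#'
#' `TP / (TP + FN)`: the rate at which true structural proteins are called
#' positive.  Undefined (returns `NA` with a warning) when there are no
#' positive examples, so degenerate folds stay visible.
#'
#' @param c a `confusion_counts`.
#' @return a fraction in `[0, 1]`, or `NA`.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) {
    warning("sensitivity undefined: no positive examples")
    return(NA_real_)
  }
  c$tp / (c$tp + c$fn)
}

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)`: the rate at which non-structural proteins are called
#' negative.  Undefined (`NA` with a warning) when there are no negatives.
#'
#' @param c a `confusion_counts`.
#' @return a fraction in `[0, 1]`, or `NA`.
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0) {
    warning("specificity undefined: no negative examples")
    return(NA_real_)
  }
  c$tn / (c$tn + c$fp)
}

#' Overall accuracy
#'
#' `(TP + TN) / (TP + FP + TN + FN)` -- the correct classification
#' frequency.
#'
#' @param c a `confusion_counts`.
#' @return a fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  total <- c$tp + c$fp + c$tn + c$fn
  if (total == 0) stop("no examples")
  (c$tp + c$tn) / total
}

fold_metrics <- function(cv, dataset, plan_assignments) {
  # per-fold metrics from each model's own test fold
  rows <- lapply(seq_len(nrow(cv)), function(i) {
    idx <- which(plan_assignments == cv$fold[i])
    out <- forward(cv$model[[i]], dataset$features[idx, , drop = FALSE])
    cc <- confusion(out, dataset$labels[idx])
    tibble::tibble(accuracy = accuracy(cc),
                   sensitivity = suppressWarnings(sensitivity(cc)),
                   specificity = suppressWarnings(specificity(cc)))
  })
  do.call(rbind, rows)
}

#' Sweep the negative:positive class ratio
#'
#' For each ratio and each pI setting, builds a dataset at that ratio,
#' trains `k` voting networks by cross-validation, and reports the mean and
#' standard error of accuracy, sensitivity, and specificity over the
#' networks' held-out folds.  Raising the share of negative examples makes
#' the networks call "negative" more often, so along the ratio axis
#' sensitivity falls while specificity rises.
#'
#' @param positives,negatives tibbles of cleaned sequence records.
#' @param ratios numeric vector of negatives-per-positive ratios (the grid
#'   of interest is 1, 2, 3, 4, 6.6, 22).
#' @param include_pi logical vector of pI settings to sweep (default both).
#' @param hidden hidden layer sizes for the voting networks.
#' @param k number of voting networks (folds).
#' @param val_fraction validation fraction.
#' @param config a [training_config()].
#' @param seed master seed.
#' @param eval_positives,eval_negatives optional record tibbles forming a
#'   common test set: when given, every ratio's networks are scored against
#'   this one set (the way a fixed curated test set isolates the effect of
#'   the training ratio); when omitted, each network is scored on its own
#'   held-out fold, whose class balance follows the ratio.
#' @return a tibble with one row per (ratio, include_pi): metric means and
#'   standard errors over the k networks.
#' @export
ratio_sweep <- function(positives, negatives, ratios = c(1, 2, 4),
                        include_pi = c(FALSE, TRUE), hidden = 10L,
                        k = 10L, val_fraction = 0.3,
                        config = training_config(), seed = 1L,
                        eval_positives = NULL, eval_negatives = NULL) {
  common_eval <- !is.null(eval_positives) && !is.null(eval_negatives)
  grid <- expand.grid(ratio = ratios, pi = include_pi)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$ratio[i]
    ds <- build_dataset(positives, negatives, ratio = r,
                        include_pi = grid$pi[i],
                        seed = derive_seed(seed, 10L + i))
    cv <- crossval_train(ds, hidden = hidden, val_fraction = val_fraction,
                         k = k, config = config,
                         seed = derive_seed(seed, 100L + i))
    plan <- attr(cv, "fold_plan")
    m <- if (common_eval) {
      eval_x <- rbind(featurize(eval_positives, include_pi = grid$pi[i]),
                      featurize(eval_negatives, include_pi = grid$pi[i]))
      eval_y <- c(rep(1, nrow(eval_positives)),
                  rep(-1, nrow(eval_negatives)))
      do.call(rbind, lapply(cv$model, function(mod) {
        cc <- confusion(forward(mod, eval_x), eval_y)
        tibble::tibble(accuracy = accuracy(cc),
                       sensitivity = suppressWarnings(sensitivity(cc)),
                       specificity = suppressWarnings(specificity(cc)))
      }))
    } else fold_metrics(cv, ds, plan$assignments)
    se <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    tibble::tibble(ratio = r, include_pi = grid$pi[i],
                   accuracy = mean(m$accuracy, na.rm = TRUE),
                   accuracy_se = se(m$accuracy),
                   sensitivity = mean(m$sensitivity, na.rm = TRUE),
                   sensitivity_se = se(m$sensitivity),
                   specificity = mean(m$specificity, na.rm = TRUE),
                   specificity_se = se(m$specificity))
  })
  do.call(rbind, rows)
}

#' Subsampling confidence bands for positive-prediction accuracy
#'
#' Over a pool of true-positive examples' ensemble outputs, the accuracy at
#' threshold `t` is the fraction of pool outputs `>= t`.  The pool is
#' subsampled `n_boot` times, each time taking a seeded random `fraction`
#' of it without replacement; the band at each threshold is the min-max of
#' the subsample accuracies after trimming `(1 - level) / 2` from each tail
#' (with 1000 draws at the 99% level, exactly 5 dropped per side).
#'
#' @param outputs ensemble mean outputs of the true-positive pool.
#' @param thresholds output thresholds (default the 0.0-0.9 grid).
#' @param n_boot number of subsamples.
#' @param fraction subsample fraction (without replacement).
#' @param level confidence level.
#' @param seed integer seed.
#' @return a tibble with `threshold`, `estimate` (full-pool accuracy),
#'   `ci_low`, `ci_high`, `n_boot`, `fraction`, `level`, `seed`.
#' @export
bootstrap_bands <- function(outputs, thresholds = seq(0, 0.9, by = 0.1),
                            n_boot = 1000L, fraction = 0.8, level = 0.99,
                            seed = 1L) {
  n <- length(outputs)
  if (n < 5L) stop("true-positive pool too small (need >= 5, have ", n, ")")
  stopifnot(fraction > 0, fraction < 1, level > 0, level < 1)
  m <- floor(fraction * n)
  n_trim <- round(n_boot * (1 - level) / 2)
  hits <- outer(outputs, thresholds, `>=`)  # n x T indicator
  draws <- withr::with_seed(seed, {
    replicate(n_boot, sample.int(n, m), simplify = FALSE)
  })
  acc <- vapply(draws, function(idx) colMeans(hits[idx, , drop = FALSE]),
                numeric(length(thresholds)))
  acc <- if (is.null(dim(acc))) matrix(acc, ncol = 1) else t(acc)
  rows <- lapply(seq_along(thresholds), function(j) {
    sorted <- sort(acc[, j])
    kept <- sorted[(n_trim + 1L):(n_boot - n_trim)]
    tibble::tibble(threshold = thresholds[j],
                   estimate = mean(hits[, j]),
                   ci_low = min(kept), ci_high = max(kept),
                   n_boot = as.integer(n_boot), fraction = fraction,
                   level = level, seed = as.integer(seed))
  })
  do.call(rbind, rows)
}

#' Label an output with its confidence band
#'
#' Given a bands table from [bootstrap_bands()], returns for each output the
#' highest threshold it reaches and that band's accuracy interval, as a
#' human-readable string (e.g. `">=0.6: 71-76% accurate"`); outputs below
#' the lowest threshold get `"below bands"`.
#'
#' @param outputs numeric ensemble outputs.
#' @param bands tibble from [bootstrap_bands()].
#' @return character vector of band labels.
#' @export
band_label <- function(outputs, bands) {
  vapply(outputs, function(o) {
    reached <- bands$threshold[o >= bands$threshold]
    if (length(reached) == 0L) return("below bands")
    t <- max(reached)
    row <- bands[bands$threshold == t, ]
    sprintf(">=%.1f: %.0f-%.0f%% accurate", t,
            100 * row$ci_low, 100 * row$ci_high)
  }, character(1))
}
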