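#' Run the voting-network benchmark protocol on a curated sequence set
#'
#' The standard evaluation protocol for a curated positive/negative pair:
#' build a labeled dataset at the requested class ratio, train `k` networks
#' by K-fold cross-validation (each fold's network initialized and split
#' independently from the master seed), and report the mean held-out
#' accuracy of the `k` voting networks.  Repeating over several master
#' seeds gives the spread of the protocol itself.
#'
#' @param positives,negatives tibbles of cleaned sequence records, or paths
#'   to FASTA files (read and cleaned with the drop-residue policy).
#' @param hidden hidden layer sizes (e.g. `40` for capsid-style networks,
#'   `10` for tail-style, `90` for all-structural).
#' @param val_fraction validation share of the non-test examples (e.g. 0.3
#'   for a 70:30 train:validation split).
#' @param ratio negatives per positive.
#' @param include_pi append the pI feature?
#' @param k number of folds / voting networks.
#' @param config a [training_config()].
#' @param seeds integer vector of master seeds.
#' @return a tibble with one row per seed (`seed`, `mean_accuracy`,
#'   `sd_accuracy`) and the grand mean in `attr(, "mean_accuracy")`.
#' @export
benchmark_protocol <- function(positives, negatives, hidden = 40L,
                               val_fraction = 0.3, ratio = 1,
                               include_pi = FALSE, k = 10L,
                               config = training_config(),
                               seeds = 1:5) {
  if (is.character(positives)) {
    positives <- clean_records(read_fasta(positives))
  }
  if (is.character(negatives)) {
    negatives <- clean_records(read_fasta(negatives))
  }
  rows <- lapply(seeds, function(s) {
    ds <- build_dataset(positives, negatives, ratio = ratio,
                        include_pi = include_pi,
                        seed = derive_seed(s, 7L))
    cv <- crossval_train(ds, hidden = hidden, val_fraction = val_fraction,
                         k = k, config = config, seed = s)
    tibble::tibble(seed = s, mean_accuracy = mean(cv$accuracy),
                   sd_accuracy = stats::sd(cv$accuracy))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_accuracy") <- mean(out$mean_accuracy)
  out
}

#' Sweep voting-ensemble size
#'
#' Given cross-validation results, evaluates top-N voting ensembles of the
#' given sizes on an evaluation dataset and reports accuracy, sensitivity,
#' and specificity per size.  The sizes of interest are 1, the odd ladder
#' 5-141, and all available networks.
#'
#' @param cv_results tibble from [crossval_train()].
#' @param eval_dataset a `labeled_dataset` to score.
#' @param sizes integer vector of ensemble sizes (values exceeding the
#'   number of available networks are dropped).
#' @return a tibble with `size`, `accuracy`, `sensitivity`, `specificity`.
#' @export
ensemble_size_sweep <- function(cv_results, eval_dataset,
                                sizes = c(1, 5, 11, 21, 41, 61, 81, 101,
                                          121, 141)) {
  sizes <- sizes[sizes <= nrow(cv_results)]
  rows <- lapply(sizes, function(s) {
    ens <- select_voters(cv_results, s)
    pred <- ensemble_predict(ens, eval_dataset$features)
    cc <- confusion(pred$mean_output, eval_dataset$labels)
    tibble::tibble(size = s,
                   accuracy = accuracy(cc),
                   sensitivity = suppressWarnings(sensitivity(cc)),
                   specificity = suppressWarnings(specificity(cc)))
  })
  do.call(rbind, rows)
}
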