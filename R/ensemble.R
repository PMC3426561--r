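#' Select the top-N networks for a voting ensemble
#'
#' Networks are ranked by held-out accuracy, descending, with ties broken by
#' fold index (ascending) so the selection is deterministic and invariant to
#' input order.  Ensemble sizes of interest are odd (1, 5, 11, ..., 141) or
#' "all"; odd sizes avoid voting ties when member outputs saturate at +-1.
#'
#' @param cv_results tibble from [crossval_train()] (columns `fold`,
#'   `accuracy`, `model`).
#' @param size number of voters, or `"all"`.
#' @return an object of class `mlp_ensemble`: list with `members`,
#'   `accuracy`, `folds`, `size`, `decision_threshold = 0`.
#' @export
select_voters <- function(cv_results, size = 5L) {
  if (identical(size, "all")) size <- nrow(cv_results)
  size <- as.integer(size)
  if (size < 1L) stop("ensemble size must be >= 1")
  if (size > nrow(cv_results)) {
    stop("requested ", size, " voters but only ", nrow(cv_results),
         " models are available")
  }
  ord <- order(-cv_results$accuracy, cv_results$fold)
  pick <- ord[seq_len(size)]
  structure(list(members = cv_results$model[pick],
                 accuracy = cv_results$accuracy[pick],
                 folds = cv_results$fold[pick],
                 size = size,
                 decision_threshold = 0),
            class = "mlp_ensemble")
}

#' @export
print.mlp_ensemble <- function(x, ...) {
  cat("<mlp_ensemble> ", x$size, " voters; member accuracies ",
      sprintf("%.3f", min(x$accuracy)), "-",
      sprintf("%.3f", max(x$accuracy)), "\n", sep = "")
  invisible(x)
}

#' Ensemble prediction by mean output
#'
#' Every member network scores the input; the ensemble output is the mean.
#' A mean output > 0 is a positive call (the composition looks like a
#' structural protein); <= 0 is negative.  Majority voting over the member
#' signs is available as an alternative combiner and agrees with the mean
#' rule whenever member outputs saturate near +-1.
#'
#' @param ensemble an `mlp_ensemble`.
#' @param x feature vector or matrix on the raw scale.
#' @param combiner `"mean"` (reference) or `"majority"`.
#' @return a tibble with `mean_output` and `decision`
#'   (`"positive"`/`"negative"`); the per-member output matrix is attached
#'   as `attr(, "member_outputs")`.
#' @export
ensemble_predict <- function(ensemble, x, combiner = c("mean", "majority")) {
  combiner <- match.arg(combiner)
  stopifnot(inherits(ensemble, "mlp_ensemble"))
  outputs <- vapply(ensemble$members, function(m) forward(m, x),
                    numeric(NROW(if (is.null(dim(x))) t(x) else x)))
  if (is.null(dim(outputs))) outputs <- matrix(outputs, nrow = 1)
  mean_out <- rowMeans(outputs)
  positive <- if (combiner == "mean") {
    mean_out > ensemble$decision_threshold
  } else {
    rowMeans(outputs > 0) > 0.5
  }
  res <- tibble::tibble(mean_output = mean_out,
                        decision = ifelse(positive, "positive", "negative"))
  attr(res, "member_outputs") <- outputs
  res
}

#' Save an ensemble as a directory of model files
#'
#' Writes one JSON model file per member plus a `manifest.json` recording
#' order, per-member accuracy, and fold of origin.
#'
#' @param ensemble an `mlp_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("member_%03d.json", seq_len(ensemble$size))
  for (i in seq_len(ensemble$size)) {
    save_model(ensemble$members[[i]], file.path(dir, files[i]))
  }
  manifest <- list(format = "vironet-ensemble",
                   version = MODEL_FORMAT_VERSION,
                   size = ensemble$size,
                   files = files,
                   accuracy = ensemble$accuracy,
                   folds = ensemble$folds,
                   decision_threshold = ensemble$decision_threshold)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Load an ensemble saved by [save_ensemble()]
#'
#' @param dir ensemble directory.
#' @return an `mlp_ensemble`.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "vironet-ensemble")) {
    stop("not a vironet ensemble directory: ", dir)
  }
  members <- lapply(file.path(dir, manifest$files), load_model)
  structure(list(members = members,
                 accuracy = as.numeric(manifest$accuracy),
                 folds = as.integer(manifest$folds),
                 size = as.integer(manifest$size),
                 decision_threshold = manifest$decision_threshold),
            class = "mlp_ensemble")
}
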