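#' Keyword rule sets for building labeled training sets
#'
#' A rule set holds the lowercase phrases used to triage annotated records
#' into positives, discards, and negative candidates, plus the minimum
#' sequence length for the class.  Matching is plain case-insensitive
#' substring matching; there is no stemming, so the lists are literal and
#' user-editable.  Three rule sets are built in:
#'
#' * `"structural"`: any virion component (capsid, tape measure, portal,
#'   tail, fiber, baseplate, connector, neck, collar); minimum length 200.
#' * `"capsid"`: major capsid proteins; records mentioning "tail" are
#'   excluded from the positive class; minimum length 300.
#' * `"tail"`: tail apparatus proteins; records mentioning "head" or
#'   "capsid" are excluded from the positive class; minimum length 150.
#'
#' The uninformative lists (hypothetical, putative, probable, ...) mirror
#' common GenBank annotation noise; the structural exclusion list
#' (cellular-organism keywords) is a reconstruction of an illustrative list
#' and is deliberately short.
#'
#' @param class `"structural"`, `"capsid"`, or `"tail"`.
#' @param positive,exclusion,uninformative optional character vectors
#'   overriding the built-in lists (lowercase phrases).
#' @param min_length optional override of the length threshold (residues).
#' @return an object of class `keyword_rules`.
#' @export
keyword_rules <- function(class = c("structural", "capsid", "tail"),
                          positive = NULL, exclusion = NULL,
                          uninformative = NULL, min_length = NULL) {
  class <- match.arg(class)
  base_uninformative <- c("hypothetical protein", "unnamed", "probable",
                          "putative", "similar to")
  rules <- switch(class,
    structural = list(
      positive = c("capsid", "tape measure", "portal", "tail", "fiber",
                   "baseplate", "connector", "neck", "collar"),
      exclusion = c("bacteria", "human", "mouse"),
      uninformative = base_uninformative,
      min_length = 200L),
    capsid = list(
      positive = c("major capsid"),
      exclusion = c("tail"),
      uninformative = c(base_uninformative, "unknown",
                        "conceptual translation", "conceptual",
                        "capsid-like", "presumed", "precursor", "possible",
                        "synthetic construct", "hypothetical", "predicted",
                        "implied", "assumed", "provisional",
                        "uncharacterized"),
      min_length = 300L),
    tail = list(
      positive = c("tail"),
      exclusion = c("head", "capsid"),
      uninformative = c(base_uninformative, "unknown",
                        "conceptual translation", "conceptual", "presumed",
                        "precursor", "possible", "synthetic construct",
                        "hypothetical", "predicted", "implied", "assumed",
                        "provisional", "uncharacterized"),
      min_length = 150L))
  if (!is.null(positive)) rules$positive <- tolower(positive)
  if (!is.null(exclusion)) rules$exclusion <- tolower(exclusion)
  if (!is.null(uninformative)) rules$uninformative <- tolower(uninformative)
  if (!is.null(min_length)) rules$min_length <- as.integer(min_length)
  stopifnot(length(rules$positive) > 0, rules$min_length >= 1L)
  rules$class <- class
  structure(rules, class = "keyword_rules")
}

match_any <- function(text, phrases) {
  any(vapply(phrases, function(p) grepl(p, text, fixed = TRUE), logical(1)))
}

#' Triage one annotation string against a rule set
#'
#' Precedence: an uninformative phrase discards the record; an exclusion
#' phrase discards it (exclusions route structural-class records out of the
#' positive pool and, for the capsid/tail sets, correspond to the
#' cross-class removals); a positive phrase makes it a positive; anything
#' else is a negative *candidate* -- it only enters a negative set when
#' drawn from a declared negative pool, never silently.
#'
#' @param description free-text annotation (possibly empty).
#' @param rules a [keyword_rules()] object.
#' @return one of `"positive"`, `"discard"`, `"negative-candidate"`.
#' @export
classify_annotation <- function(description, rules) {
  stopifnot(inherits(rules, "keyword_rules"))
  if (length(description) != 1L || is.na(description)) description <- ""
  text <- tolower(description)
  if (match_any(text, rules$uninformative)) return("discard")
  if (match_any(text, rules$exclusion)) return("discard")
  if (match_any(text, rules$positive)) return("positive")
  "negative-candidate"
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Filter records by the rule set's length threshold
#'
#' The threshold is inclusive: a record is kept when its cleaned length is
#' at least `min_length` residues.
#'
#' @param records a tibble of cleaned sequence records.
#' @param rules a [keyword_rules()] object.
#' @return the records meeting the threshold.
#' @export
apply_length_filter <- function(records, rules) {
  records[nchar(records$residues) >= rules$min_length, , drop = FALSE]
}

#' Curate an annotated record set into positive and negative pools
#'
#' Applies [classify_annotation()] to every record, drops discards, and
#' length-filters both pools.  Records classified `"negative-candidate"` are
#' only returned as negatives when `negative_pool = TRUE` (i.e., the input
#' was downloaded as a negative query); otherwise they are dropped.
#'
#' @param records annotated, cleaned sequence records.
#' @param rules a [keyword_rules()] object.
#' @param negative_pool is this record set a declared negative pool?
#' @return a list with tibbles `positive` and `negative`.
#' @export
curate_records <- function(records, rules, negative_pool = FALSE) {
  verdict <- vapply(records$description, classify_annotation, character(1),
                    rules = rules, USE.NAMES = FALSE)
  pos <- apply_length_filter(records[verdict == "positive", , drop = FALSE],
                             rules)
  neg <- records[verdict == "negative-candidate", , drop = FALSE]
  neg <- if (negative_pool) apply_length_filter(neg, rules) else neg[0, ]
  list(positive = pos, negative = neg)
}

#' Assemble a labeled dataset at a chosen class ratio
#'
#' All positives are kept and labeled +1; `floor(ratio * n_pos)` negatives
#' are sampled without replacement (seeded) and labeled -1.  Both classes
#' are featurized with [featurize()].  Ratios of interest follow the class
#' frequencies seen in practice: 1:1 through 4:1, plus the lambda-genome
#' tail (6.6:1) and capsid (22:1) frequencies.
#'
#' @param positives,negatives tibbles of cleaned sequence records.
#' @param ratio negatives per positive (> 0).
#' @param include_pi append the pI feature?
#' @param seed integer seed for the negative sample.
#' @param table [pka_table()] for the pI feature.
#' @return an object of class `labeled_dataset`: a list with `features`
#'   (matrix), `labels` (+1/-1), `ids`, `class_ratio`, and `provenance`.
#' @export
build_dataset <- function(positives, negatives, ratio = 1,
                          include_pi = FALSE, seed = 1L,
                          table = pka_table()) {
  if (ratio <= 0) stop("ratio must be positive")
  n_pos <- nrow(positives)
  if (n_pos == 0L) stop("no positive records")
  n_neg <- floor(ratio * n_pos)
  if (nrow(negatives) < n_neg) {
    stop("insufficient negatives: need ", n_neg, ", have ", nrow(negatives),
         " (short by ", n_neg - nrow(negatives), ")")
  }
  ids <- c(positives$id, negatives$id)
  if (anyDuplicated(ids)) stop("duplicate record ids across classes")
  pick <- withr::with_seed(seed, sample.int(nrow(negatives), n_neg))
  neg <- negatives[pick, , drop = FALSE]
  records <- rbind(positives[, c("id", "description", "residues")],
                   neg[, c("id", "description", "residues")])
  features <- featurize(records, include_pi = include_pi, table = table)
  labels <- c(rep(1, n_pos), rep(-1, n_neg))
  structure(list(
    features = features,
    labels = labels,
    ids = records$id,
    class_ratio = ratio,
    provenance = list(seed = seed, include_pi = include_pi,
                      pka_table = attr(table, "table_name"),
                      n_positive = n_pos, n_negative = n_neg)),
    class = "labeled_dataset")
}

#' Wrap an existing feature matrix and labels as a dataset
#'
#' @param features numeric feature matrix (rows = examples).
#' @param labels vector of +1/-1, one per row.
#' @param ids optional ids; default from rownames or row index.
#' @param provenance optional provenance list.
#' @return a `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, ids = NULL,
                            provenance = list()) {
  stopifnot(nrow(features) == length(labels), all(labels %in% c(-1, 1)))
  ids <- ids %||% rownames(features) %||% as.character(seq_len(nrow(features)))
  n_pos <- sum(labels == 1)
  structure(list(features = features, labels = labels, ids = ids,
                 class_ratio = if (n_pos > 0) sum(labels == -1) / n_pos
                               else NA_real_,
                 provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$features), " examples x ",
      ncol(x$features), " features; ", sum(x$labels == 1), " positive, ",
      sum(x$labels == -1), " negative\n", sep = "")
  invisible(x)
}

#' Subset a labeled dataset by row index
#'
#' @param dataset a `labeled_dataset`.
#' @param idx integer row indices.
#' @return a `labeled_dataset` restricted to `idx`.
#' @export
dataset_subset <- function(dataset, idx) {
  labeled_dataset(dataset$features[idx, , drop = FALSE],
                  dataset$labels[idx], dataset$ids[idx],
                  dataset$provenance)
}
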