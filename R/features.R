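#' Built-in pKa tables for isoelectric-point estimation
#'
#' A pKa table gives the dissociation constants of the ionizable side chains
#' (D, E, C, Y, H, K, R) and of the free N- and C-termini.  Because small
#' differences between published tables move pI estimates by a few tenths of
#' a pH unit, the table is named and carried through to all outputs.  Two
#' tables ship with the package:
#'
#' * `"emboss"` (default): the table used by the EMBOSS `iep` program and by
#'   the classic BioPerl pI calculator.
#' * `"expasy"`: Bjellqvist-style constants as used by the ExPASy
#'   Compute pI tool (N-terminal pKa collapsed to a single value).
#'
#' @param name `"emboss"` or `"expasy"`, or a named numeric vector with
#'   entries `D, E, C, Y, H, K, R, Nterm, Cterm` (all in (0, 14)) to supply a
#'   custom table.
#' @return an object of class `pka_table`: a named numeric vector with a
#'   `table_name` attribute.
#' @export
pka_table <- function(name = "emboss") {
  if (is.numeric(name)) {
    vals <- name
    needed <- c("D", "E", "C", "Y", "H", "K", "R", "Nterm", "Cterm")
    stopifnot(all(needed %in% names(vals)))
    vals <- vals[needed]
    if (any(vals <= 0 | vals >= 14)) stop("pKa values must lie in (0, 14)")
    attr(vals, "table_name") <- "custom"
  } else {
    vals <- switch(match.arg(name, c("emboss", "expasy")),
      emboss = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1, H = 6.5,
                 K = 10.8, R = 12.5, Nterm = 8.6, Cterm = 3.6),
      expasy = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98,
                 K = 10.0, R = 12.0, Nterm = 7.5, Cterm = 3.55))
    attr(vals, "table_name") <- name
  }
  class(vals) <- "pka_table"
  vals
}

#' Amino-acid percent composition
#'
#' The fraction of each of the 20 standard amino acids in a cleaned
#' sequence, times 100, in the fixed alphabetical order of [AA_CODES].
#' Composition is order-insensitive and always sums to 100.
#'
#' @param residues a cleaned amino-acid string (standard codes only).
#' @return a named numeric vector of length 20 summing to 100.
#' @export
aa_composition <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) stop("cannot compute composition of empty sequence")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (!all(chars %in% AA_CODES)) {
    stop("sequence contains non-standard residues; run clean_sequence() first")
  }
  counts <- table(factor(chars, levels = AA_CODES))
  stats::setNames(100 * as.numeric(counts) / length(chars), AA_CODES)
}

# Counts of ionizable groups, termini included (one each per chain)
ionizable_counts <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- function(a) sum(chars == a)
  list(basic  = c(Nterm = 1, K = n("K"), R = n("R"), H = n("H")),
       acidic = c(Cterm = 1, D = n("D"), E = n("E"), C = n("C"), Y = n("Y")))
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch model: each basic group (K, R, H side chains and
#' the N-terminus) contributes `1 / (1 + 10^(pH - pKa))`, each acidic group
#' (D, E, C, Y side chains and the C-terminus) contributes
#' `-1 / (1 + 10^(pKa - pH))`.  The total is strictly decreasing in pH, so
#' it has a unique zero, the isoelectric point.
#'
#' @param residues a cleaned amino-acid string.
#' @param ph pH value(s) in `[0, 14]`; vectorized.
#' @param table a [pka_table()].
#' @return net charge, one value per element of `ph`.
#' @export
net_charge <- function(residues, ph, table = pka_table()) {
  if (any(ph < 0 | ph > 14)) stop("ph must lie in [0, 14]")
  grp <- ionizable_counts(residues)
  pk <- unclass(table)
  charge <- numeric(length(ph))
  for (g in names(grp$basic)) {
    charge <- charge + grp$basic[[g]] / (1 + 10^(ph - pk[[g]]))
  }
  for (g in names(grp$acidic)) {
    charge <- charge - grp$acidic[[g]] / (1 + 10^(pk[[g]] - ph))
  }
  charge
}

#' Isoelectric point by bisection
#'
#' Finds the unique pH in `[0, 14]` at which [net_charge()] is zero, by
#' bisection to a fixed pH tolerance.  Deterministic for a fixed pKa table.
#'
#' @param residues a cleaned amino-acid string.
#' @param table a [pka_table()].
#' @param tol pH tolerance of the bisection (default `1e-3`).
#' @return the pI, a single pH value.
#' @export
isoelectric_point <- function(residues, table = pka_table(), tol = 1e-3) {
  stopifnot(tol > 0)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(residues, mid, table) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Convert sequence records to network input features
#'
#' Each record becomes a row: 20 percent-composition values in [AA_CODES]
#' order, plus the isoelectric point as a 21st column when `include_pi` is
#' `TRUE`.  Row order follows record order; rownames are record ids.
#'
#' @param records a tibble of sequence records (cleaned; see
#'   [clean_records()]).
#' @param include_pi append the pI feature?
#' @param table [pka_table()] used when `include_pi` is `TRUE`.
#' @param tol pI bisection tolerance.
#' @return a numeric matrix with 20 or 21 columns.
#' @export
featurize <- function(records, include_pi = FALSE, table = pka_table(),
                      tol = 1e-3) {
  comp <- t(vapply(records$residues, aa_composition, numeric(20),
                   USE.NAMES = FALSE))
  colnames(comp) <- AA_CODES
  rownames(comp) <- records$id
  if (include_pi) {
    pi_vals <- vapply(records$residues, isoelectric_point, numeric(1),
                      table = table, tol = tol, USE.NAMES = FALSE)
    comp <- cbind(comp, pi = pi_vals)
  }
  comp
}

#' Write a labeled feature table as TSV
#'
#' Columns: `id`, the 20 composition columns, then `pi` and `label` when
#' present.
#'
#' @param features feature matrix from [featurize()].
#' @param path output path.
#' @param label optional vector of +1/-1 labels, recycled to `nrow`.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path, label = NULL) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  if (!is.null(label)) {
    stopifnot(all(label %in% c(-1, 1)))
    df$label <- rep_len(label, nrow(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled feature table written by [write_feature_tsv()]
#'
#' @param path TSV path.
#' @return a list with `features` (matrix) and `labels` (vector or `NULL`).
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- if ("label" %in% names(df)) df$label else NULL
  keep <- setdiff(names(df), c("id", "label"))
  features <- as.matrix(df[, keep, drop = FALSE])
  rownames(features) <- df$id
  list(features = features, labels = labels)
}
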