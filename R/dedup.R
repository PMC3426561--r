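#' Global percent identity between two cleaned sequences
#'
#' Identity is matches / alignment length under a global alignment scored
#' with match 1, mismatch 0, and a linear gap penalty.  The alignment is
#' computed with Biostrings; identity counts columns of the full (gapped)
#' alignment.
#'
#' @param a,b cleaned amino-acid strings.
#' @param gap linear per-position gap cost (default 0.5, between the match
#'   reward and the mismatch score so gaps are used only when they pay for
#'   themselves in matches).
#' @return identity as a fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, gap = 0.5) {
  mat <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = gap,
    type = "global")
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Collapse near-identical sequences at a 90% identity threshold
#'
#' Greedy centroid clustering: records are visited longest-first (ties keep
#' input order); a record joins the first existing cluster whose
#' representative it matches at >= `threshold` global identity, otherwise it
#' founds a new cluster.  The returned representatives are the cluster
#' founders, in their order of founding.  Deterministic for a given input,
#' and idempotent.
#'
#' @param records a tibble of cleaned sequence records.
#' @param threshold identity threshold as a fraction (default 0.9).
#' @param gap linear gap cost passed to [pairwise_identity()].
#' @return the representative records, one per cluster, with a
#'   `cluster_size` column.
#' @export
dedup_90 <- function(records, threshold = 0.9, gap = 0.5) {
  n <- nrow(records)
  if (n == 0L) return(records)
  ord <- order(-nchar(records$residues))  # stable: ties keep input order
  reps <- integer(0)
  sizes <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (j in seq_along(reps)) {
      if (pairwise_identity(records$residues[i],
                            records$residues[reps[j]], gap = gap)
          >= threshold) {
        sizes[j] <- sizes[j] + 1L
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      sizes <- c(sizes, 1L)
    }
  }
  out <- records[reps, , drop = FALSE]
  out$cluster_size <- sizes
  out
}
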