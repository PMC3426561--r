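#' Construct a table of sequence records
#'
#' A sequence record is one protein with an identifier, a free-text
#' annotation, and its residues.  Records are kept in a tibble with columns
#' `id`, `description`, `residues`; all curation and feature extraction
#' functions consume this shape.
#'
#' @param id character vector of non-empty identifiers.
#' @param residues character vector of amino-acid strings (uppercased).
#' @param description free-text annotations; defaults to empty strings.
#' @return a tibble with columns `id`, `description`, `residues`.
#' @export
sequence_records <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (any(!nzchar(id))) stop("all record ids must be non-empty")
  if (anyNA(id) || anyNA(residues)) stop("ids and residues must not be NA")
  tibble::tibble(id = id,
                 description = rep_len(as.character(description), length(id)),
                 residues = residues)
}

#' Read protein sequences from a FASTA file
#'
#' Headers are split at the first whitespace: the first token becomes the
#' record `id`, the remainder (possibly empty) the `description`.  Residues
#' are uppercased but not otherwise altered; run [clean_sequence()] before
#' feature extraction.
#'
#' @param path path to a FASTA file.
#' @return a tibble of sequence records (see [sequence_records()]); an empty
#'   file yields a zero-row tibble with a warning.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("FASTA file '", path, "' is empty; returning zero records")
    return(sequence_records(character(), character()))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA in '", path, "': line ", nonblank[1],
         " precedes any '>' header")
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- sub("^\\S+\\s*", "", headers)
  sequence_records(id = id, residues = as.character(set),
                   description = description)
}

#' Write sequence records to a FASTA file
#'
#' @param records a tibble of sequence records.
#' @param path output path.
#' @param width line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "description", "residues") %in% names(records)))
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Clean a protein sequence to the 20 standard residues
#'
#' Stop characters (`*`) and gaps (`-`, `.`) are always removed.  Ambiguity
#' codes (B, J, Z, X, U, O) are handled per `policy`: `"drop-residue"`
#' (default) deletes them, `"reject"` raises an error naming the first
#' offending position.  Any character outside the standard and ambiguity
#' alphabets is always an error.
#'
#' @param residues a single amino-acid string.
#' @param policy `"drop-residue"` or `"reject"`.
#' @return the cleaned string, containing only the 20 standard codes.
#' @export
clean_sequence <- function(residues, policy = c("drop-residue", "reject")) {
  policy <- match.arg(policy)
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  chars <- chars[!chars %in% c("*", "-", ".")]
  ambiguous <- chars %in% AA_AMBIGUOUS
  unknown <- !(chars %in% AA_CODES) & !ambiguous
  if (any(unknown)) {
    stop("invalid residue character '", chars[which(unknown)[1]],
         "' at position ", which(unknown)[1])
  }
  if (any(ambiguous)) {
    if (policy == "reject") {
      stop("ambiguous residue '", chars[which(ambiguous)[1]],
           "' at position ", which(ambiguous)[1])
    }
    chars <- chars[!ambiguous]
  }
  if (length(chars) == 0L) stop("sequence is empty after cleaning")
  paste(chars, collapse = "")
}

#' Clean every record in a table
#'
#' @param records a tibble of sequence records.
#' @param policy ambiguity policy passed to [clean_sequence()].
#' @return the records with cleaned residues.
#' @export
clean_records <- function(records, policy = "drop-residue") {
  records$residues <- vapply(records$residues, clean_sequence,
                             character(1), policy = policy,
                             USE.NAMES = FALSE)
  records
}
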