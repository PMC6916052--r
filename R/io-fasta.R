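#' Read a FASTA file into a genome table
#'
#' Reads a (multi-record) FASTA file and returns one row per record. Residues
#' are upper-cased and `U` is mapped to `T`, so downstream code only ever sees
#' the alphabet `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` (first whitespace-delimited token of
#'   the header) and `seq`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 toy", "ACGTacgu"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(seqs) == 0) abort(sprintf("empty FASTA: %s", path))
  nm <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(nm))) abort(sprintf("FASTA '%s': record with empty name", path))
  tibble::tibble(
    name = nm,
    seq = unname(normalize_dna(as.character(seqs), where = path))
  )
}

#' Write a genome table to FASTA
#'
#' @param genome Tibble with `name` and `seq` columns.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  stopifnot(all(c("name", "seq") %in% names(genome)))
  set <- Biostrings::BStringSet(genome$seq)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
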