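#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings. `read_fasta()` returns a plain named
#' character vector (accession -> amino-acid sequence): the accession is the
#' header token before the first whitespace, sequences are uppercased and a
#' terminal `*` (stop) is stripped.
#'
#' @param path Path to a FASTA file.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  acc <- sub("\\s.*$", "", names(set))
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0L) {
    stopf("duplicate accession(s) in %s: %s", path, paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  if (any(nchar(seqs) == 0L)) {
    stopf("empty sequence for accession(s): %s",
          paste(acc[nchar(seqs) == 0L], collapse = ", "))
  }
  setNames(seqs, acc)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stopf("`sequences` must be a fully named character vector")
  }
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
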