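# FASTA I/O thin wrappers (Biostrings does the parsing).

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector (names are the first word of each header).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(unlist(seqs))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
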