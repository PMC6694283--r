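#' Read and write sequence files
#'
#' Thin wrappers around Biostrings returning plain named character
#' vectors, the representation the rest of the package works with.
#' `write_fastq` emits constant maximum base qualities, since the exact
#' matcher ignores quality strings.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta`/`read_fastq` a named character vector; writers the
#'   path, invisibly.
#' @name sequence_io
NULL

#' @rdname sequence_io
#' @export
read_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}

#' @rdname sequence_io
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' @rdname sequence_io
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
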