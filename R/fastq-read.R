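#' Construct a FASTQ read
#'
#' A lightweight record holding an identifier, the base string, and the
#' Phred+33 quality string (the only supported quality encoding).
#'
#' @param id nonempty read identifier (without the leading `@`).
#' @param seq base string.
#' @param qual Phred+33 quality string of the same length as `seq`.
#' @return an object of class `fastq_read`.
#' @examples
#' fastq_read("r1", "ACGT", "IIII")
#' @export
fastq_read <- function(id, seq, qual) {
  stopifnot(is.character(id), nzchar(id), is.character(seq), is.character(qual))
  if (nchar(seq) != nchar(qual))
    stop("sequence and quality strings differ in length (", nchar(seq),
         " vs ", nchar(qual), ") for read '", id, "'")
  structure(list(id = id, seq = seq, qual = qual), class = "fastq_read")
}

#' @export
print.fastq_read <- function(x, ...) {
  cat(sprintf("<fastq_read %s: %d bp>\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' @export
length.fastq_read <- function(x) nchar(x$seq)

# cut a read to its first `keep` bases (sequence and quality together)
trim_to <- function(read, keep) {
  keep <- max(0L, min(as.integer(keep), nchar(read$seq)))
  read$seq <- substr(read$seq, 1L, keep)
  read$qual <- substr(read$qual, 1L, keep)
  read
}
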