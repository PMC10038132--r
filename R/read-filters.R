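#' Sliding-window quality trimming
#'
#' A window of `window` bases slides from the front of the read (starts 0, 1,
#' 2, ...; windows at the tail are truncated to the available bases).  At the
#' first window whose mean Phred score falls below `threshold`, the window's
#' first base and everything after it are removed; if no window fails the
#' read is unchanged.
#'
#' @param read a [fastq_read()].
#' @param window window size in bases (default 5).
#' @param threshold mean Phred threshold (default 15).
#' @return the (possibly shortened) read.
#' @export
quality_trim <- function(read, window = 5, threshold = 15) {
  stopifnot(window >= 1, threshold >= 0)
  trim_to(read, cpp_quality_trim_keep(read$qual, as.integer(window), threshold))
}

#' Cut a read at the first ambiguous base
#'
#' @param read a [fastq_read()].
#' @return the read cut just before its first `N` (case-insensitive), or
#'   unchanged if it contains none.
#' @export
n_trim <- function(read) {
  p <- regexpr("[Nn]", read$seq)
  if (p < 0) read else trim_to(read, p - 1L)
}

#' Remove fixed base counts from the read ends
#'
#' @param read a [fastq_read()].
#' @param front,tail number of bases to clip from each end; counts exceeding
#'   the read yield an empty read, not an error.
#' @return the clipped read.
#' @export
hard_clip <- function(read, front = 0, tail = 0) {
  len <- nchar(read$seq)
  from <- min(front, len)
  to <- max(from, len - tail)
  read$seq <- substr(read$seq, from + 1L, to)
  read$qual <- substr(read$qual, from + 1L, to)
  read
}

#' Drop read pairs with a too-short mate
#'
#' Both mates are dropped together when either is shorter than `min_length`.
#'
#' @param r1,r2 [fastq_read()] objects.
#' @param min_length minimum kept length.
#' @return `TRUE` when the pair passes the filter.
#' @export
length_filter <- function(r1, r2, min_length) {
  nchar(r1$seq) >= min_length && nchar(r2$seq) >= min_length
}
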