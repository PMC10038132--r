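#' Pack a DNA sequence into 4-bit codes
#'
#' Encodes a DNA string into a dense stream of 4-bit one-hot codes: A = 0001,
#' C = 0010, G = 0100, T = 1000; IUPAC ambiguity codes are the bitwise OR of
#' their constituents (N = 1111, S = 0110, ...) and the gap `-` is 0000.
#' Base `i` (0-based) occupies nibble `i` of the word stream, so base `2n`
#' sits in the least-significant nibble of the 64-bit word loaded at byte
#' position `n`.  The buffer is "bit-safe": one extra all-zero 64-bit word is
#' appended past the encoded bases, and every bit after base `n_bases - 1` is
#' zero, so word loads near the tail are always legal and read as gaps.
#'
#' @param x a character scalar over the IUPAC alphabet plus `-`
#'   (case-insensitive), or an existing `packed_seq` (returned unchanged).
#' @return an object of class `packed_seq` with fields `words` (64-bit words
#'   as 16-digit hexadecimal strings, least-significant byte = lowest base
#'   indices) and `n_bases`.
#' @examples
#' p <- packed_seq("ACGTN")
#' as.character(p)
#' @export
packed_seq <- function(x) {
  if (inherits(x, "packed_seq")) return(x)
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  cpp_encode(x)
}

#' @export
as.character.packed_seq <- function(x, ...) cpp_decode(x)

#' @export
print.packed_seq <- function(x, ...) {
  cat(sprintf("<packed_seq: %d bases>\n", x$n_bases))
  s <- as.character(x)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' @export
length.packed_seq <- function(x) x$n_bases

#' Extract the 64-bit word at a byte (memory) position
#'
#' The word at memory position `n` represents the 16-mer covering bases
#' `2n..2n+15`; bases past the sequence end read as gaps (0000) thanks to the
#' bit-safe padding.
#'
#' @param x a `packed_seq` or character scalar.
#' @param n non-negative byte position; loads addressing entirely past the
#'   padded buffer are rejected.
#' @return a 16-digit hexadecimal string.
#' @export
word_at <- function(x, n) {
  stopifnot(length(n) == 1L, n >= 0)
  cpp_word_at(packed_seq(x), as.integer(n))
}

#' Head words of a packed sequence
#'
#' Returns `a0`, the word covering bases `0..15`, and `a_minus`, covering
#' bases `1..16`, computed as `(a0 >> 4) | (a1 << 4)` where `a1` is the word
#' at byte position 1.  Together they let a 16-base query head be compared
#' against every offset of a subject using only byte-aligned loads.
#'
#' @param x a `packed_seq` or character scalar with at least one base.
#' @return list with hexadecimal strings `a0` and `a_minus`.
#' @export
head_pair <- function(x) cpp_head_pair(packed_seq(x))

#' Reverse complement
#'
#' For packed sequences the complement of a one-hot nibble is its bit
#' reversal (A <-> T, C <-> G, N and S map to themselves, gap stays gap).
#'
#' @param x a `packed_seq` or a character scalar.
#' @return an object of the same type as `x`.
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

#' @export
reverse_complement.packed_seq <- function(x) cpp_reverse_complement(x)

#' @export
reverse_complement.character <- function(x) {
  vapply(x, function(s) cpp_decode(cpp_reverse_complement(cpp_encode(s))),
         character(1), USE.NAMES = FALSE)
}
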