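#' Mismatch count between two packed 16-mers
#'
#' Computes `K = 16 - popcount(a & b)`, clamped below at 0.  Under the 4-bit
#' one-hot encoding a shared bit at a nibble means the two bases are
#' compatible, so the popcount of the AND counts matching bases; shared
#' ambiguity codes can contribute more than one bit, in which case the
#' mismatch count is underestimated (clamping keeps it non-negative).
#'
#' @param a_word,b_word 16-digit hexadecimal words (as returned by
#'   [word_at()] or [head_pair()]).
#' @return integer mismatch count in `0..16`.
#' @examples
#' w <- word_at("ACGTACGTACGTACGT", 0)
#' mismatch_count(w, w)
#' @export
mismatch_count <- function(a_word, b_word) {
  cpp_mismatch_count(a_word, b_word)
}

#' Scan a query head along a subject
#'
#' Compares the query's 16-base head against every offset `0..len(subject)-1`
#' of the subject: even offsets use the `a0` head word, odd offsets use
#' `a_minus` (so at odd offsets the compared 16-mer is query bases `1..16`).
#' Subject bases past the end read as gaps and count as mismatches, so a
#' query overhanging the subject tail can still match partially.  Queries
#' shorter than 16 bases are gap-padded, and the padding nibbles count as
#' mismatches.  Offset -1 is excluded.
#'
#' The best offset (smallest offset achieving the minimum mismatch count) and
#' its matched-base count are always reported; `found` is `TRUE` only when
#' the minimum mismatch count is at most `k`.
#'
#' @param query,subject `packed_seq` objects or character scalars.
#' @param k mismatch tolerance (default 2).
#' @return list with `found`, `offset` (0-based; -1 when the subject is
#'   empty) and `n_match` (`16 - K` at the best offset).
#' @examples
#' kmer_scan("ACGTACGTACGTACGT", paste0(strrep("T", 20), "ACGTACGTACGTACGT"))
#' @export
kmer_scan <- function(query, subject, k = 2) {
  stopifnot(k >= 0)
  cpp_scan(packed_seq(query), packed_seq(subject), as.integer(k))
}

#' Matched-base count at a single offset
#'
#' Single-position version of [kmer_scan()]: compares the query head 16-mer
#' at the given subject offset and returns the matched-base count without
#' applying any threshold.  Used by the loosened-tolerance re-runs of the
#' four-way matcher.
#'
#' @inheritParams kmer_scan
#' @param offset non-negative 0-based subject offset; offsets past the
#'   subject end compare against gaps.
#' @return integer matched-base count in `0..16`.
#' @export
match_at <- function(query, subject, offset) {
  stopifnot(length(offset) == 1L)
  if (offset < 0) stop("offset must be non-negative")
  cpp_match_at(packed_seq(query), packed_seq(subject), as.integer(offset))
}
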