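#' Predict whether a read pair overlaps
#'
#' Preliminary estimate of whether a pair shares an overlapped region.  When
#' adapters were trimmed and the two remaining lengths are equal, the
#' prediction passes with insert size equal to that length.  When no adapter
#' was trimmed, two additional matches are run: the head of the reverse
#' complement of read 2 against read 1, and the head of the reverse
#' complement of read 1 against read 2, with insert size mapping
#' `s = offset + length(other read)`; the prediction passes only when both
#' matches are found and imply the same insert size.
#'
#' @param r1,r2 [fastq_read()] objects (post adapter trimming).
#' @param trimmed logical: were adapters trimmed for this pair?  May also be
#'   a `trim_verdict`, in which case its `trim` field is used.
#' @param k mismatch tolerance for the prediction matches (default 2, the
#'   adapter-engine default).
#' @return list with `overlap` (logical) and `insert_size` (-1 when no
#'   overlap is predicted).
#' @export
predict_overlap <- function(r1, r2, trimmed, k = 2) {
  if (inherits(trimmed, "trim_verdict")) trimmed <- trimmed$trim
  cpp_predict_overlap(r1$seq, r2$seq, isTRUE(trimmed), as.integer(k))
}

#' Assess a predicted overlap
#'
#' Compares the whole overlapped region base by base: read 1 position `i`
#' against the complement of read 2 position `s - 1 - i`, using the bitwise
#' shared-bit test except that ambiguous N bases are converted to gaps first,
#' so N opposite anything counts as a mismatch.  The assessment passes when
#' the mismatch ratio (mismatches over the overlap length in bases) does not
#' exceed `max_mismatch_ratio`; an empty overlap fails.
#'
#' @param r1,r2 [fastq_read()] objects.
#' @param s the predicted insert size.
#' @param max_mismatch_ratio maximum tolerated mismatch ratio (default 0.28).
#' @return list with `pass` and `mismatch_ratio`.
#' @export
assess_overlap <- function(r1, r2, s, max_mismatch_ratio = 0.28) {
  cpp_assess_overlap(r1$seq, r2$seq, as.integer(s), max_mismatch_ratio)
}

#' Correct disagreeing calls in an overlapped region
#'
#' For each overlapped position where the two reads disagree, both reads
#' receive the call with the higher Phred score (complemented appropriately
#' for read 2), and the winning quality is copied to both positions.  Equal
#' qualities keep read 1's call.  Read lengths never change; after
#' correction the overlapped regions are reverse-complement identical.
#'
#' @param r1,r2 [fastq_read()] objects.
#' @param s the assessed insert size.
#' @return list with corrected `r1`, `r2` and the number of corrected
#'   positions `n_corrected`.
#' @export
correct_overlap <- function(r1, r2, s) {
  res <- cpp_correct_overlap(r1$seq, r1$qual, r2$seq, r2$qual, as.integer(s))
  r1$seq <- res$seq1; r1$qual <- res$qual1
  r2$seq <- res$seq2; r2$qual <- res$qual2
  list(r1 = r1, r2 = r2, n_corrected = res$n_corrected)
}
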