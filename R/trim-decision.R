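#' Reconcile two candidate insert sizes
#'
#' If the two candidates agree on the position, that position is kept with
#' the summed score; otherwise the candidate with the larger score wins (on a
#' score tie the first argument wins).  An absent candidate (`NULL`, or
#' `pos < 0`) acts as an identity element; two absent candidates reconcile to
#' absent.
#'
#' @param a,b candidates as lists with `pos` (insert size) and `score`, or
#'   `NULL` for an absent match.
#' @return list with `pos`, `score` and `present`.
#' @examples
#' reconcile(list(pos = 30, score = 12), list(pos = 30, score = 9))
#' reconcile(list(pos = 30, score = 12), list(pos = 31, score = 9))
#' @export
reconcile <- function(a, b) {
  absent <- function(x) is.null(x) || is.na(x$pos) || x$pos < 0
  if (absent(a) && absent(b)) return(list(pos = -1L, score = 0, present = FALSE))
  if (absent(a)) return(list(pos = b$pos, score = b$score, present = TRUE))
  if (absent(b)) return(list(pos = a$pos, score = a$score, present = TRUE))
  if (a$pos == b$pos)
    return(list(pos = a$pos, score = a$score + b$score, present = TRUE))
  if (b$score > a$score) list(pos = b$pos, score = b$score, present = TRUE)
  else list(pos = a$pos, score = a$score, present = TRUE)
}

#' Decide whether and where to trim a read pair
#'
#' Turns a [four_way_match()] state into a single trim/no-trim verdict:
#'
#' 1. Within each read the adapter and paired-end candidates are reconciled,
#'    then the two reads are reconciled into `(r12_pos, r12_score)`.
#' 2. Low-quality override: when the per-read positions differ and one read's
#'    score exceeds `trim_score` while the other read either cannot supply
#'    any base at that position or its *unfloored* mean 16-mer accuracy there
#'    is below 0.6 (Phred Q < 5), both reads are trimmed at the reconciled
#'    position, bypassing the tail filter.
#' 3. Tail false-positive filter: with the default `"pseudocode"` rule a read
#'    raises the tail flag when both its adapter and paired-end matches fall
#'    in the last `tail_length` bases; the pair is rejected when some read
#'    raises the flag and in no read do the adapter and paired-end candidates
#'    agree.  The `"prose"` rule (adapter in the tail but the paired-end
#'    match not) is available for experimentation.  Absent matches never take
#'    part in tail-membership tests.  The filter only ever converts trim into
#'    no-trim.
#' 4. The pair is trimmed when `r12_score > trim_score` (strict) and the
#'    tail filter did not fire.
#' 5. Before cutting, each read's position is refined by [adjust_position()]
#'    unless the position exceeds the read length minus three (the remaining
#'    adapter would be too short to check).
#'
#' @param state a `pair_match_state` from [four_way_match()].
#' @param r1,r2 the [fastq_read()] objects the state was computed from.
#' @param trim_score score threshold (default 10, strict comparison).
#' @param tail_length tail window for the false-positive filter (default 12).
#' @param tail_rule `"pseudocode"` (default) or `"prose"`; see above.
#' @param adapter1,adapter2 adapter sequences used by the adjacent-1-bp
#'   refinement.
#' @return an object of class `trim_verdict`: `trim`, `insert_size_r1`,
#'   `insert_size_r2` (final kept lengths), `combined_score`, and `reason`
#'   (one of `agreed`, `score-max`, `low-quality-override`,
#'   `rejected-tail-FP`, `below-threshold`).
#' @export
decide_trim <- function(state, r1, r2, trim_score = 10, tail_length = 12,
                        tail_rule = c("pseudocode", "prose"),
                        adapter1 = ADAPTER_R1, adapter2 = ADAPTER_R2) {
  tail_rule <- match.arg(tail_rule)
  stopifnot(inherits(state, "pair_match_state"))
  v <- cpp_decide(unclass(state), r1$seq, r1$qual, r2$seq, r2$qual,
                  adapter1, adapter2, trim_score, as.integer(tail_length),
                  tail_rule == "prose")
  v$reason <- c("agreed", "score-max", "low-quality-override",
                "rejected-tail-FP", "below-threshold")[v$reason]
  class(v) <- "trim_verdict"
  v
}

#' @export
print.trim_verdict <- function(x, ...) {
  cat(sprintf("<trim_verdict: %s (%s), keep r1=%d r2=%d, score=%.2f>\n",
              if (x$trim) "trim" else "no-trim", x$reason,
              x$insert_size_r1, x$insert_size_r2, x$combined_score))
  invisible(x)
}

#' Adjacent-1-bp adapter re-positioning
#'
#' Indels in the read can shift the true adapter start by one base relative
#' to the reconciled insert size.  The adapter's first four bases are
#' compared against the read at candidate starts `s - 1`, `s` and `s + 1`
#' (negative candidates are skipped; out-of-range read bases count as
#' mismatches) and the candidate with the most matched bases is returned.
#' Ties break toward `s`, then toward the smaller offset.
#'
#' @param read a [fastq_read()] (or character sequence).
#' @param adapter the adapter sequence (character or `packed_seq`).
#' @param s candidate insert size; callers skip the adjustment when
#'   `s > length(read) - 3`.
#' @return the adjusted insert size.
#' @export
adjust_position <- function(read, adapter, s) {
  seq <- if (inherits(read, "fastq_read")) read$seq else read
  ad <- if (inherits(adapter, "packed_seq")) as.character(adapter) else adapter
  cpp_adjust_position(seq, ad, as.integer(s))
}

#' Apply a trim verdict to a read pair
#'
#' Cuts both reads to the kept lengths in the verdict (sequence and quality
#' together); a no-trim verdict returns the pair unchanged.
#'
#' @param r1,r2 [fastq_read()] objects.
#' @param verdict a `trim_verdict` from [decide_trim()].
#' @return list with elements `r1` and `r2`.
#' @export
apply_verdict <- function(r1, r2, verdict) {
  if (!verdict$trim) return(list(r1 = r1, r2 = r2))
  list(r1 = trim_to(r1, verdict$insert_size_r1),
       r2 = trim_to(r2, verdict$insert_size_r2))
}
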