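#' Four-way matching of a read pair against adapters and each other
#'
#' Runs the four 16-mer head matches that together locate the adapter in a
#' paired-end read pair:
#'
#' 1. adapter 1 head against read 1, and 2. adapter 2 head against read 2 —
#'    an adapter starting at offset `p` implies an insert size of `p`;
#' 3. read 1 head against the reverse complement of read 2, and 4. read 2
#'    head against the reverse complement of read 1 — a match at offset `o`
#'    implies an insert size of `len(mate) - o`, so a paired-end match can
#'    corroborate an adapter position whenever the insert is no longer than
#'    the mate.
#'
#' The paired-end matches use tolerance `k + 1` when the better adapter match
#' has fewer matched bases than `cutoff`.  Afterwards, if the best of the
#' four matches exceeds `cutoff`, every match below `cutoff` is re-evaluated
#' (threshold-free, realising the loosened `k + 3` re-run) at the single
#' offset implied by the best match's insert size, and replaced when the
#' recount exceeds `cutoff`; negative implied offsets are skipped.
#'
#' Scores follow the quality-weighted model: the adapter-side probability is
#' 1, the read-side probability is the floored mean 16-mer accuracy at the
#' candidate insert size, and paired-end scores carry an extra factor for the
#' mate's head 16-mer.  Matches whose minimum mismatch count exceeded the
#' tolerance carry score 0, but their raw matched-base counts still inform
#' the loosening logic above.
#'
#' @param r1,r2 [fastq_read()] objects.
#' @param adapter1,adapter2 adapter sequences as ACGT strings; adapters
#'   shorter than 16 bases trigger a warning and are gap-padded.
#' @param k mismatch tolerance (default 2).
#' @param cutoff matched-base threshold steering the loosening logic
#'   (default 9).
#' @return an object of class `pair_match_state`: a list with components
#'   `adapter_r1`, `adapter_r2`, `pe_r1`, `pe_r2` (each with `found`, `pos`
#'   — the insert-size candidate —, `n_match`, `score`), plus `k_extra`, `k`
#'   and `cutoff`.
#' @examples
#' r1 <- fastq_read("p/1", paste0(strrep("A", 20), substr(ADAPTER_R1, 1, 33)),
#'                  strrep("I", 53))
#' r2 <- fastq_read("p/2", paste0(strrep("T", 20), substr(ADAPTER_R2, 1, 33)),
#'                  strrep("I", 53))
#' four_way_match(r1, r2, ADAPTER_R1, ADAPTER_R2)
#' @export
four_way_match <- function(r1, r2, adapter1 = ADAPTER_R1, adapter2 = ADAPTER_R2,
                           k = 2, cutoff = 9) {
  stopifnot(inherits(r1, "fastq_read"), inherits(r2, "fastq_read"),
            nchar(r1$seq) > 0, nchar(r2$seq) > 0,
            nchar(adapter1) >= 1, nchar(adapter2) >= 1, k >= 0)
  if (nchar(adapter1) < 16 || nchar(adapter2) < 16)
    warning("adapter shorter than 16 bases: gap-padded head used; ",
            "padding nibbles count as mismatches")
  st <- cpp_four_way(r1$seq, r1$qual, r2$seq, r2$qual,
                     adapter1, adapter2, as.integer(k), as.integer(cutoff))
  st$k <- as.integer(k)
  st$cutoff <- as.integer(cutoff)
  class(st) <- "pair_match_state"
  st
}

#' @export
print.pair_match_state <- function(x, ...) {
  cat("<pair_match_state>\n")
  for (nm in c("adapter_r1", "adapter_r2", "pe_r1", "pe_r2")) {
    m <- x[[nm]]
    cat(sprintf("  %-10s found=%-5s pos=%-4d n_match=%-2d score=%.2f\n",
                nm, m$found, m$pos, m$n_match, m$score))
  }
  cat(sprintf("  k=%d k_extra=%d cutoff=%d\n", x$k, x$k_extra, x$cutoff))
  invisible(x)
}
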