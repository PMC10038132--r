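# Independent, character-level oracles used to validate the bit-packed
# implementation.  These deliberately re-derive the semantics from the code
# table rather than calling any package internals.

ORACLE_CODE <- c("-" = 0L, A = 1L, C = 2L, M = 3L, G = 4L, R = 5L, S = 6L,
                 V = 7L, T = 8L, W = 9L, Y = 10L, H = 11L, K = 12L, D = 13L,
                 B = 14L, N = 15L)
ORACLE_CHAR <- names(ORACLE_CODE)

oracle_codes <- function(s) {
  if (nchar(s) == 0) return(integer(0))
  unname(ORACLE_CODE[strsplit(toupper(s), "")[[1]]])
}

# number of shared bits between two 4-bit codes (popcount of the AND)
oracle_shared_bits <- function(c1, c2) {
  x <- bitwAnd(c1, c2)
  sum(bitwAnd(x, c(1L, 2L, 4L, 8L)) > 0)
}

# the 16-mer the algorithm compares at a given subject offset: even offsets
# use query bases 0..15 vs subject o..o+15; odd offsets use query bases 1..16
# vs subject o+1..o+16.  Out-of-range positions (either side) read as gaps.
oracle_window_mismatches <- function(qc, bc, o) {
  shift <- o %% 2L
  qidx <- shift + 0:15          # 0-based query positions
  bidx <- o + shift + 0:15      # 0-based subject positions
  bits <- 0L
  for (t in 1:16) {
    cq <- if (qidx[t] < length(qc)) qc[qidx[t] + 1L] else 0L
    cb <- if (bidx[t] >= 0 && bidx[t] < length(bc)) bc[bidx[t] + 1L] else 0L
    bits <- bits + oracle_shared_bits(cq, cb)
  }
  max(0L, 16L - bits)
}

# naive full scan: smallest offset achieving the minimum mismatch count
oracle_scan <- function(query, subject, k) {
  qc <- oracle_codes(query)
  bc <- oracle_codes(subject)
  if (length(qc) == 0 || length(bc) == 0)
    return(list(found = FALSE, offset = -1L, n_match = 0L))
  K <- vapply(0:(length(bc) - 1L), function(o)
    oracle_window_mismatches(qc, bc, o), integer(1))
  best <- which.min(K) # first index of the minimum
  list(found = K[best] <= k, offset = best - 1L, n_match = 16L - K[best])
}

oracle_revcomp <- function(s) {
  comp <- c("-" = "-", A = "T", C = "G", M = "K", G = "C", R = "Y", S = "S",
            V = "B", T = "A", W = "W", Y = "R", H = "D", K = "M", D = "H",
            B = "V", N = "N")
  if (nchar(s) == 0) return("")
  paste(rev(unname(comp[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

# expected hexadecimal word for 16 codes (nibble i = base 2n+i)
oracle_word_hex <- function(codes16) {
  codes16 <- c(codes16, rep(0L, 16 - length(codes16)))
  paste(sprintf("%x", rev(codes16)), collapse = "")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n == 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

const_qual <- function(n, q = 30) strrep(intToUtf8(33L + q), n)

make_read <- function(seq, q = 30, id = "r") fastq_read(id, seq, const_qual(nchar(seq), q))
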