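# helpers to fabricate match states for precise decision-rule tests
mk_match <- function(found = FALSE, pos = -1L, n_match = 0L, score = 0) {
  list(found = found, pos = as.integer(pos), n_match = as.integer(n_match),
       score = score)
}
mk_state <- function(a1 = mk_match(), a2 = mk_match(),
                     p1 = mk_match(), p2 = mk_match()) {
  structure(list(adapter_r1 = a1, adapter_r2 = a2, pe_r1 = p1, pe_r2 = p2,
                 k_extra = 0L, k = 2L, cutoff = 9L), class = "pair_match_state")
}
# a 100-bp Q30 read whose bases at `at` onwards are the adapter, so the
# adjacent-1-bp refinement keeps the position where we put it
read_with_adapter <- function(at, adapter, len = 100, q = 30) {
  make_read(substr(paste0(random_dna(at), adapter, random_dna(len)), 1, len), q)
}

test_that("reconcile sums on agreement, takes the max otherwise", {
  r <- reconcile(list(pos = 30, score = 12), list(pos = 30, score = 9))
  expect_equal(r, list(pos = 30, score = 21, present = TRUE))
  r <- reconcile(list(pos = 30, score = 9), list(pos = 31, score = 12))
  expect_equal(r$pos, 31)
  expect_equal(r$score, 12)
  # score tie: the first argument wins
  r <- reconcile(list(pos = 30, score = 9), list(pos = 31, score = 9))
  expect_equal(r$pos, 30)
  # absent operands are identities
  expect_equal(reconcile(NULL, list(pos = 5, score = 3))$pos, 5)
  expect_equal(reconcile(list(pos = 5, score = 3), NULL)$pos, 5)
  expect_equal(reconcile(list(pos = -1, score = 0), NULL)$present, FALSE)
})

test_that("four agreeing matches trim with reason 'agreed'", {
  set.seed(42)
  r1 <- read_with_adapter(30, ADAPTER_R1)
  r2 <- read_with_adapter(30, ADAPTER_R2)
  st <- mk_state(a1 = mk_match(TRUE, 30, 16, 4), a2 = mk_match(TRUE, 30, 16, 4),
                 p1 = mk_match(TRUE, 30, 16, 4), p2 = mk_match(TRUE, 30, 16, 4))
  v <- decide_trim(st, r1, r2)
  expect_true(v$trim)
  expect_equal(v$reason, "agreed")
  expect_equal(v$insert_size_r1, 30L)
  expect_equal(v$insert_size_r2, 30L)
  expect_equal(v$combined_score, 16)
})

test_that("the trim-score comparison is strict", {
  set.seed(43)
  r1 <- read_with_adapter(30, ADAPTER_R1)
  r2 <- read_with_adapter(30, ADAPTER_R2)
  st <- mk_state(a1 = mk_match(TRUE, 30, 16, 5), a2 = mk_match(TRUE, 30, 16, 5))
  v <- decide_trim(st, r1, r2)  # combined score exactly 10
  expect_false(v$trim)
  expect_equal(v$reason, "below-threshold")
  expect_equal(v$insert_size_r1, 100L)  # kept lengths = full reads
  # any more and it trims
  st$adapter_r1$score <- 5.01
  expect_true(decide_trim(st, r1, r2)$trim)
})

test_that("disagreeing reads resolve by score with reason 'score-max'", {
  set.seed(44)
  r1 <- read_with_adapter(30, ADAPTER_R1)
  r2 <- read_with_adapter(30, ADAPTER_R2)
  st <- mk_state(a1 = mk_match(TRUE, 30, 16, 12), a2 = mk_match(TRUE, 40, 12, 5))
  v <- decide_trim(st, r1, r2)
  expect_true(v$trim)
  expect_equal(v$reason, "score-max")
  expect_equal(v$insert_size_r1, 30L)
  expect_equal(v$insert_size_r2, 30L)
})

test_that("low-quality override: a short mate cannot veto a convincing match", {
  set.seed(45)
  r1 <- read_with_adapter(95, ADAPTER_R1)          # 100 bp
  r2 <- make_read(random_dna(90))                  # shorter than the position
  st <- mk_state(a1 = mk_match(TRUE, 95, 16, 12))
  v <- decide_trim(st, r1, r2)
  expect_true(v$trim)
  expect_equal(v$reason, "low-quality-override")
  expect_equal(v$insert_size_r1, 95L)
  expect_equal(v$insert_size_r2, 90L)  # clamped to the mate's length
})

test_that("low-quality override: unfloored mean accuracy below 0.6 at the position", {
  set.seed(46)
  r1 <- read_with_adapter(80, ADAPTER_R1)
  # mate full length but Q0 ('!') from position 80 on: unfloored mean ~ 0
  r2 <- fastq_read("x", random_dna(100),
                   paste0(strrep("I", 80), strrep("!", 20)))
  st <- mk_state(a1 = mk_match(TRUE, 80, 16, 12))
  v <- decide_trim(st, r1, r2)
  expect_true(v$trim)
  expect_equal(v$reason, "low-quality-override")
  # same state, good-quality mate: no override, but score-max still trims
  r2q <- make_read(random_dna(100))
  v2 <- decide_trim(st, r1, r2q)
  expect_true(v2$trim)
  expect_equal(v2$reason, "score-max")
})

test_that("tail false-positive filter rejects disagreeing tail matches", {
  set.seed(47)
  r1 <- read_with_adapter(95, ADAPTER_R1)
  r2 <- read_with_adapter(95, ADAPTER_R2)
  # both r1 matches in the last 12 bases (>= 88) but at different positions;
  # r2's adapter agrees on 95 so the combined score clears the threshold
  st <- mk_state(a1 = mk_match(TRUE, 95, 14, 8), p1 = mk_match(TRUE, 92, 13, 7),
                 a2 = mk_match(TRUE, 95, 14, 8))
  v <- decide_trim(st, r1, r2)
  expect_false(v$trim)
  expect_equal(v$reason, "rejected-tail-FP")
  # adapter/paired-end agreement in either read suppresses the rejection
  st$pe_r2 <- mk_match(TRUE, 95, 13, 7)
  v2 <- decide_trim(st, r1, r2)
  expect_true(v2$trim)
  expect_equal(v2$reason, "agreed")
  # matches outside the tail are never flagged
  st3 <- mk_state(a1 = mk_match(TRUE, 50, 14, 8), p1 = mk_match(TRUE, 47, 13, 7),
                  a2 = mk_match(TRUE, 50, 14, 8))
  r1b <- read_with_adapter(50, ADAPTER_R1)
  r2b <- read_with_adapter(50, ADAPTER_R2)
  expect_true(decide_trim(st3, r1b, r2b)$trim)
})

test_that("the prose tail rule flags adapter-only tail hits", {
  set.seed(48)
  r1 <- read_with_adapter(95, ADAPTER_R1)
  r2 <- make_read(random_dna(100))
  st <- mk_state(a1 = mk_match(TRUE, 95, 14, 12))
  # pseudocode rule: no paired-end match, so the flag cannot raise -> trim
  v <- decide_trim(st, r1, r2)
  expect_true(v$trim)
  # prose rule: adapter in the tail with no tail paired-end match -> reject
  v2 <- decide_trim(st, r1, r2, tail_rule = "prose")
  expect_false(v2$trim)
  expect_equal(v2$reason, "rejected-tail-FP")
})

test_that("no matches at all is a no-trim below-threshold verdict", {
  r1 <- make_read(random_dna(80))
  r2 <- make_read(random_dna(70))
  v <- decide_trim(mk_state(), r1, r2)
  expect_false(v$trim)
  expect_equal(v$reason, "below-threshold")
  expect_equal(v$insert_size_r1, 80L)
  expect_equal(v$insert_size_r2, 70L)
  expect_equal(v$combined_score, 0)
})

test_that("adjust_position recovers 1-bp shifts and prefers s on ties", {
  set.seed(49)
  r <- read_with_adapter(30, ADAPTER_R1)
  expect_equal(adjust_position(r, ADAPTER_R1, 30), 30L)
  expect_equal(adjust_position(r, ADAPTER_R1, 29), 30L)
  expect_equal(adjust_position(r, ADAPTER_R1, 31), 30L)
  # all candidates tie: keep s
  allA <- make_read(strrep("A", 50))
  expect_equal(adjust_position(allA, "AAAACGTACGTACGTA", 20), 20L)
  # s = 0: the negative candidate is skipped, not an error
  expect_true(adjust_position(r, ADAPTER_R1, 0) %in% c(0L, 1L))
})

test_that("apply_verdict cuts sequence and quality together", {
  r1 <- fastq_read("a/1", "ACGTACGTAC", "IIIIIFFFFF")
  r2 <- fastq_read("a/2", "TTTTGGGGCC", "FFFFFIIIII")
  v <- structure(list(trim = TRUE, insert_size_r1 = 4L, insert_size_r2 = 7L,
                      combined_score = 12, reason = "agreed"),
                 class = "trim_verdict")
  out <- apply_verdict(r1, r2, v)
  expect_equal(out$r1$seq, "ACGT")
  expect_equal(out$r1$qual, "IIII")
  expect_equal(out$r2$seq, "TTTTGGG")
  expect_equal(out$r2$qual, "FFFFFII")
  v$trim <- FALSE
  expect_identical(apply_verdict(r1, r2, v)$r1, r1)
})
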