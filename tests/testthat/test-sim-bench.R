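test_that("error_profile validates rates and the baseline scales linearly", {
  p <- error_profile()
  expect_equal(p$sub_rate, 0.001)
  expect_equal(p$ins_rate, 1e-5)
  expect_equal(p$del_rate, 1e-5)
  p5 <- baseline_error_profile(5)
  expect_equal(p5$sub_rate, 0.005)
  expect_equal(p5$ins_rate, 5e-5)
  expect_error(error_profile(sub_rate = -0.1))
  expect_error(error_profile(sub_rate = 1))
})

test_that("error-free simulation reproduces the template construction exactly", {
  set.seed(42)
  zero <- error_profile(0, 0, 0)
  sim <- simulate_read_pair(60, read_length = 100, profile = zero)
  # read 1 = insert + adapter1 + filler; the insert is recoverable from r1
  insert <- substr(sim$r1$seq, 1, 60)
  expect_equal(substr(sim$r1$seq, 61, 93), ADAPTER_R1)
  expect_equal(substr(sim$r2$seq, 1, 60), reverse_complement(insert))
  expect_equal(substr(sim$r2$seq, 61, 93), ADAPTER_R2)
  expect_equal(nchar(sim$r1$seq), 100L)
  expect_equal(nchar(sim$r2$seq), 100L)
  expect_equal(sim$truth$true_trim_pos_r1, 60L)
  expect_equal(sim$truth$true_trim_pos_r2, 60L)
  expect_equal(sim$r1$qual, strrep(intToUtf8(63), 100))  # constant Q30
  # adapter-free: insert at least the read length
  sim2 <- simulate_read_pair(120, read_length = 100, profile = zero)
  expect_equal(sim2$truth$true_trim_pos_r1, 100L)
  expect_equal(sim2$truth$true_trim_pos_r2, 100L)
  # insert exactly the read length: adapter starts right at the read end
  sim3 <- simulate_read_pair(100, read_length = 100, profile = zero)
  expect_equal(sim3$truth$true_trim_pos_r1, 100L)
})

test_that("simulation is a deterministic function of the R RNG seed", {
  set.seed(7)
  a <- simulate_read_pair(50)
  set.seed(7)
  b <- simulate_read_pair(50)
  expect_identical(a, b)
  set.seed(8)
  c <- simulate_read_pair(50)
  expect_false(identical(a$r1$seq, c$r1$seq))
})

test_that("indels shift the true adapter position accordingly", {
  # deletion-only profile with a high rate: the adapter tends to start earlier
  set.seed(43)
  del <- error_profile(0, 0, 0.05)
  pos <- replicate(50, simulate_read_pair(60, profile = del)$truth$true_trim_pos_r1)
  expect_true(all(pos <= 60))
  expect_true(any(pos < 60))
  # insertion-only: the adapter tends to start later
  set.seed(44)
  ins <- error_profile(0, 0.05, 0)
  pos <- replicate(50, simulate_read_pair(60, profile = ins)$truth$true_trim_pos_r1)
  expect_true(all(pos >= 60))
  expect_true(any(pos > 60))
  # substitutions never move it
  set.seed(45)
  sub <- error_profile(0.2, 0, 0)
  pos <- replicate(20, simulate_read_pair(60, profile = sub)$truth$true_trim_pos_r1)
  expect_true(all(pos == 60))
})

test_that("simulate_grid crosses all conditions with stable identifiers", {
  sim <- simulate_grid(profile_multipliers = c(1, 3),
                       adapter_lengths = c(16, 33),
                       insert_sizes = c(70, 110),
                       pairs_per_condition = 5, seed = 42)
  expect_equal(nrow(sim), 2 * 2 * 2 * 5)
  expect_equal(sort(unique(sim$profile_multiplier)), c(1, 3))
  expect_equal(sort(unique(sim$adapter_len)), c(16, 33))
  expect_equal(sim$pair_id[1], "p1xa16i70:1")
  expect_equal(sim$id1[1], "p1xa16i70:1/1")
  expect_true(all(nchar(sim$seq1) == 100))
  expect_true(all(sim$true_trim_pos_r1 >= 0 & sim$true_trim_pos_r1 <= 100))
  # grid reproducibility through the seed argument
  sim2 <- simulate_grid(profile_multipliers = c(1, 3),
                        adapter_lengths = c(16, 33),
                        insert_sizes = c(70, 110),
                        pairs_per_condition = 5, seed = 42)
  expect_identical(sim, sim2)
})

test_that("write_simulated produces matched FASTQ and truth files", {
  d <- withr::local_tempdir()
  sim <- simulate_grid(profile_multipliers = 1, adapter_lengths = 33,
                       insert_sizes = c(80, 110), pairs_per_condition = 10,
                       seed = 43)
  paths <- write_simulated(sim, file.path(d, "sim"))
  pairs <- read_fastq_pairs(paths$r1, paths$r2)
  expect_equal(nrow(pairs), 20L)
  expect_equal(pairs$seq1, sim$seq1)
  truth <- read.delim(paths$truth)
  expect_equal(truth$pair_id, sim$pair_id)
  expect_equal(truth$true_trim_pos_r2, sim$true_trim_pos_r2)
})

test_that("mcc_score handles perfect, inverted, degenerate and large inputs", {
  expect_equal(mcc_score(10, 10, 0, 0), 1)
  expect_equal(mcc_score(0, 0, 10, 10), -1)
  expect_equal(mcc_score(0, 0, 0, 0), 0)
  expect_equal(mcc_score(5, 0, 0, 0), 0)  # zero denominator convention
  # counts large enough to overflow 32-bit intermediate products
  big <- mcc_score(1500000L, 1500000L, 1500L, 1500L)
  expect_true(is.finite(big) && big > 0.99)
})

test_that("evaluate_trimming partitions reads and classifies differences", {
  truth <- data.frame(true_trim_pos_r1 = c(60, 60, 100, 100, 70),
                      true_trim_pos_r2 = c(60, 59, 100, 100, 72))
  # r1: exact, exact, intact, over-trimmed, 1-bp under-trimmed
  # r2: exact, 1-bp over (58 vs 59), intact, intact, multi-bp over
  m <- evaluate_trimming(c(60, 60, 100, 90, 71), c(60, 58, 100, 100, 60), truth)
  expect_equal(m$tp, 3L)   # bearing & exact: r1#1, r1#2, r2#1
  expect_equal(m$fn, 3L)   # bearing & wrong: r1#5, r2#2, r2#5
  expect_equal(m$tn, 3L)   # free & intact
  expect_equal(m$fp, 1L)   # free & touched: r1#4
  expect_equal(m$n_reads, 10L)
  expect_equal(m$accurate, 6L)
  expect_equal(m$over_1bp, 1L)     # r2#2: diff = +1
  expect_equal(m$under_1bp, 1L)    # r1#5: diff = -1
  expect_equal(m$over_multi, 2L)   # r1#4 (+10), r2#5 (+12)
  expect_equal(m$under_multi, 0L)
  expect_equal(m$sensitivity, 3 / 6)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$ppv, 3 / 4)
  expect_equal(m$mcc, mcc_score(3, 3, 1, 3))
})

test_that("evaluate_files scores written output and enforces ID matching", {
  d <- withr::local_tempdir()
  sim <- simulate_grid(profile_multipliers = 1, adapter_lengths = 33,
                       insert_sizes = c(80, 110), pairs_per_condition = 20,
                       seed = 44)
  paths <- write_simulated(sim, file.path(d, "sim"))
  # oracle trimming: cut exactly at the recorded truth
  cut <- sim
  cut$seq1 <- substr(cut$seq1, 1, cut$true_trim_pos_r1)
  cut$qual1 <- substr(cut$qual1, 1, cut$true_trim_pos_r1)
  cut$seq2 <- substr(cut$seq2, 1, cut$true_trim_pos_r2)
  cut$qual2 <- substr(cut$qual2, 1, cut$true_trim_pos_r2)
  t1 <- file.path(d, "t1.fastq"); t2 <- file.path(d, "t2.fastq")
  write_fastq_pairs(cut, t1, t2)
  m <- evaluate_files(t1, t2, paths$truth)
  expect_equal(m$fp + m$fn, 0L)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  # shuffled truth rows no longer match the read IDs
  shuffled <- read.delim(paths$truth)
  shuffled <- shuffled[rev(seq_len(nrow(shuffled))), ]
  st <- file.path(d, "shuffled.tsv")
  write.table(shuffled, st, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(evaluate_files(t1, t2, st), "does not match the truth table")
})
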