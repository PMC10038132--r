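#' Sequencing error profile
#'
#' Per-base substitution, insertion and deletion probabilities used by the
#' read simulator.  The baseline profile (0.1% substitution, 0.001%
#' insertion, 0.001% deletion) follows published Illumina error-rate
#' estimates; [baseline_error_profile()] scales all three rates by an integer
#' multiplier.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities in `[0, 1)`.
#' @return an object of class `error_profile`.
#' @export
error_profile <- function(sub_rate = 0.001, ins_rate = 0.00001,
                          del_rate = 0.00001) {
  stopifnot(sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "error_profile")
}

#' @rdname error_profile
#' @param multiplier scale factor applied to the baseline rates.
#' @export
baseline_error_profile <- function(multiplier = 1) {
  error_profile(0.001 * multiplier, 0.00001 * multiplier, 0.00001 * multiplier)
}

#' Simulate one read pair with adapter read-through
#'
#' Mimics sequencing by synthesis: a random ACGT insert of the given size is
#' drawn; template 1 is `insert + adapter1` and template 2 is
#' `reverse_complement(insert) + adapter2`.  Each template is copied base by
#' base — with `del_rate` the base is skipped, with `ins_rate` a uniform
#' random base is emitted before it, with `sub_rate` it is replaced by a
#' uniform different base — and copying continues with uniform random filler
#' bases after the template until `read_length` bases are emitted.  Qualities
#' are a constant Phred score (the simulator does not model quality decay, so
#' the 0.6/0.75 quality machinery of the trimmer is inert on simulated data
#' unless `quality` is lowered).
#'
#' The truth records where the adapter's first surviving base landed in each
#' final read (`read_length` when no adapter base survives within the read),
#' tracked through indels.  Randomness is governed by R's RNG: call
#' `set.seed()` for reproducibility.
#'
#' @param insert_size length of the simulated DNA fragment (>= 1).
#' @param read_length read length in bases (default 100).
#' @param adapter1,adapter2 adapter sequences.
#' @param profile an [error_profile()].
#' @param quality constant Phred score for all bases (default 30).
#' @return list with `r1`, `r2` ([fastq_read()] objects) and `truth` (fields
#'   `original_insert_size`, `true_trim_pos_r1`, `true_trim_pos_r2`).
#' @export
simulate_read_pair <- function(insert_size, read_length = 100,
                               adapter1 = ADAPTER_R1, adapter2 = ADAPTER_R2,
                               profile = baseline_error_profile(),
                               quality = 30) {
  stopifnot(insert_size >= 1, read_length >= 1)
  sim <- cpp_simulate_batch(as.integer(insert_size), as.integer(read_length),
                            adapter1, adapter2,
                            profile$sub_rate, profile$ins_rate, profile$del_rate)
  q <- strrep(intToUtf8(33L + quality), read_length)
  list(r1 = fastq_read("sim/1", sim$seq1[1], q),
       r2 = fastq_read("sim/2", sim$seq2[1], q),
       truth = list(original_insert_size = insert_size,
                    true_trim_pos_r1 = sim$true_trim_pos_r1[1],
                    true_trim_pos_r2 = sim$true_trim_pos_r2[1]))
}

#' Simulate a full condition grid
#'
#' Crosses error-profile multipliers, adapter lengths (prefixes of the
#' configured adapters) and insert sizes, simulating `pairs_per_condition`
#' pairs per combination.  Defaults reproduce the published benchmark grid:
#' 1-5x baseline profiles, adapter lengths 16/20/24/28/33, even insert sizes
#' 66-120, 100-bp reads, 30,000 pairs per condition; reads with insert sizes
#' 66-98 carry adapter, 100-120 are adapter-free (up to indel effects at
#' 100).  The grid is a pure function of the RNG seed and the configuration.
#'
#' @param profile_multipliers multipliers applied to the baseline error
#'   profile.
#' @param adapter_lengths adapter prefix lengths.
#' @param insert_sizes insert sizes.
#' @param pairs_per_condition pairs simulated per condition combination.
#' @param read_length read length (default 100).
#' @param adapter1,adapter2 full adapter sequences to take prefixes of.
#' @param quality constant Phred score (default 30).
#' @param seed optional seed passed to `set.seed()`; `NULL` leaves the RNG
#'   state alone.
#' @return a `data.frame` with one row per pair: `id1`, `seq1`, `qual1`,
#'   `id2`, `seq2`, `qual2` plus the truth columns `pair_id`, `insert_size`,
#'   `adapter_len`, `profile_multiplier`, `true_trim_pos_r1`,
#'   `true_trim_pos_r2`.
#' @export
simulate_grid <- function(profile_multipliers = 1:5,
                          adapter_lengths = c(16, 20, 24, 28, 33),
                          insert_sizes = seq(66, 120, by = 2),
                          pairs_per_condition = 30000,
                          read_length = 100,
                          adapter1 = ADAPTER_R1, adapter2 = ADAPTER_R2,
                          quality = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- strrep(intToUtf8(33L + quality), read_length)
  blocks <- list()
  bi <- 1L
  for (m in profile_multipliers) {
    prof <- baseline_error_profile(m)
    for (alen in adapter_lengths) {
      a1 <- substr(adapter1, 1, alen)
      a2 <- substr(adapter2, 1, alen)
      for (s in insert_sizes) {
        sim <- cpp_simulate_batch(rep(as.integer(s), pairs_per_condition),
                                  as.integer(read_length), a1, a2,
                                  prof$sub_rate, prof$ins_rate, prof$del_rate)
        pid <- sprintf("p%dxa%di%d:%d", m, alen, s, seq_len(pairs_per_condition))
        blocks[[bi]] <- data.frame(
          pair_id = pid,
          id1 = paste0(pid, "/1"), seq1 = sim$seq1, qual1 = q,
          id2 = paste0(pid, "/2"), seq2 = sim$seq2, qual2 = q,
          insert_size = s, adapter_len = alen, profile_multiplier = m,
          true_trim_pos_r1 = sim$true_trim_pos_r1,
          true_trim_pos_r2 = sim$true_trim_pos_r2,
          stringsAsFactors = FALSE)
        bi <- bi + 1L
      }
    }
  }
  do.call(rbind, blocks)
}

#' Write a simulated grid to FASTQ files and a truth table
#'
#' @param sim a `data.frame` from [simulate_grid()].
#' @param prefix output path prefix; writes `<prefix>_R1.fastq[.gz]`,
#'   `<prefix>_R2.fastq[.gz]` and `<prefix>_truth.tsv`.
#' @param compress gzip the FASTQ outputs (default `FALSE`).
#' @return invisibly, the three paths.
#' @export
write_simulated <- function(sim, prefix, compress = FALSE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_R1", ext)
  p2 <- paste0(prefix, "_R2", ext)
  pt <- paste0(prefix, "_truth.tsv")
  write_fastq_file(sim$id1, sim$seq1, sim$qual1, p1, compress)
  write_fastq_file(sim$id2, sim$seq2, sim$qual2, p2, compress)
  truth <- sim[, c("pair_id", "insert_size", "adapter_len",
                   "profile_multiplier", "true_trim_pos_r1",
                   "true_trim_pos_r2")]
  utils::write.table(truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(r1 = p1, r2 = p2, truth = pt))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FN)(TN+FP))`, with the
#' convention that a zero factor in the denominator yields 0.
#'
#' @param tp,tn,fp,fn confusion-matrix counts.
#' @return the coefficient, in `[-1, 1]`.
#' @examples
#' mcc_score(8, 8, 2, 2)
#' @export
mcc_score <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  d <- (tp + fp) * (tp + fn) * (tn + fn) * (tn + fp)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d)
}

#' Evaluate trimming accuracy against simulated truth
#'
#' Scores every read (two per pair) against the recorded true adapter start:
#' a read counts as trimmed correctly when its trimmed length equals the true
#' position exactly.  Reads are partitioned by adapter presence (true
#' position < read length): adapter-bearing reads are TP when exact and FN
#' otherwise; adapter-free reads are TN when left at full length and FP
#' otherwise.  Signed differences additionally classify reads as accurate,
#' 1-bp over-/under-trimmed, or multi-bp over-/under-trimmed (over = trimmed
#' shorter than the truth).
#'
#' @param trimmed_len_r1,trimmed_len_r2 trimmed read lengths, in truth-table
#'   order.
#' @param truth a `data.frame` with columns `true_trim_pos_r1`,
#'   `true_trim_pos_r2` (e.g. from [simulate_grid()]).
#' @param read_length the simulated read length (default 100).
#' @return an object of class `trim_metrics`: counts `tp`, `tn`, `fp`, `fn`;
#'   rates `ppv`, `sensitivity`, `specificity`, `mcc`; class counts
#'   `accurate`, `over_1bp`, `under_1bp`, `over_multi`, `under_multi`; and
#'   `n_reads`.
#' @export
evaluate_trimming <- function(trimmed_len_r1, trimmed_len_r2, truth,
                              read_length = 100) {
  stopifnot(length(trimmed_len_r1) == nrow(truth),
            length(trimmed_len_r2) == nrow(truth))
  len <- c(trimmed_len_r1, trimmed_len_r2)
  true <- c(truth$true_trim_pos_r1, truth$true_trim_pos_r2)
  bearing <- true < read_length
  exact <- len == true
  tp <- sum(bearing & exact)
  fn <- sum(bearing & !exact)
  tn <- sum(!bearing & len == read_length)
  fp <- sum(!bearing & len != read_length)
  diff <- true - len # positive = over-trimmed (trimmed too much)
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = mcc_score(tp, tn, fp, fn),
    accurate = sum(diff == 0),
    over_1bp = sum(diff == 1), under_1bp = sum(diff == -1),
    over_multi = sum(diff > 1), under_multi = sum(diff < -1),
    n_reads = length(len)), class = "trim_metrics")
}

#' @export
print.trim_metrics <- function(x, ...) {
  cat("<trim_metrics>\n")
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d (n=%d reads)\n",
              x$tp, x$tn, x$fp, x$fn, x$n_reads))
  cat(sprintf("  PPV=%.4f sensitivity=%.4f specificity=%.4f MCC=%.4f\n",
              x$ppv, x$sensitivity, x$specificity, x$mcc))
  cat(sprintf("  accurate=%d over1=%d under1=%d over>1=%d under>1=%d\n",
              x$accurate, x$over_1bp, x$under_1bp, x$over_multi, x$under_multi))
  invisible(x)
}

#' Evaluate trimmed FASTQ files against a truth table
#'
#' Reads the trimmed pair and the truth TSV written by [write_simulated()],
#' matches records to truth rows by identifier (a hard error on any
#' mismatch), and calls [evaluate_trimming()].  Pairs dropped by the length
#' filter are not supported: evaluation expects the read order and IDs to be
#' preserved by the trimmer.
#'
#' @param trimmed1,trimmed2 trimmed FASTQ paths.
#' @param truth_path the truth TSV.
#' @param read_length the simulated read length (default 100).
#' @return a `trim_metrics` object.
#' @export
evaluate_files <- function(trimmed1, trimmed2, truth_path, read_length = 100) {
  pairs <- read_fastq_pairs(trimmed1, trimmed2)
  truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
  if (nrow(pairs) != nrow(truth))
    stop("trimmed output has ", nrow(pairs), " pairs but the truth table has ",
         nrow(truth))
  ids <- normalize_read_id(pairs$id1)
  bad <- which(ids != truth$pair_id)
  if (length(bad))
    stop("read ID does not match the truth table at pair ", bad[1],
         " ('", ids[bad[1]], "' vs '", truth$pair_id[bad[1]], "')")
  evaluate_trimming(nchar(pairs$seq1), nchar(pairs$seq2), truth, read_length)
}
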