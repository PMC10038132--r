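#' Trimming run configuration
#'
#' Collects every tunable of the pipeline with its default.  Stage order is
#' fixed: adapter trimming, consensus calling, quality trimming, N trimming,
#' hard clipping, length filtering.
#'
#' @param adapter1,adapter2 adapter sequences (defaults: the 33-bp Illumina
#'   pair [ADAPTER_R1]/[ADAPTER_R2]).
#' @param k 16-mer mismatch tolerance (default 2).
#' @param cutoff matched-base cutoff for the loosening logic (default 9).
#' @param trim_score trim-score threshold, strict (default 10).
#' @param tail_length tail window of the false-positive filter (default 12).
#' @param tail_rule `"pseudocode"` (default) or `"prose"`; see
#'   [decide_trim()].
#' @param consensus enable overlap consensus calling (default `TRUE`).
#' @param max_mismatch_ratio consensus assessment threshold (default 0.28).
#' @param quality_trim enable sliding-window quality trimming (default
#'   `TRUE`).
#' @param window,quality_threshold quality-trimming window (default 5) and
#'   mean-Phred threshold (default 15).
#' @param n_trim cut reads at the first N (default `FALSE`).
#' @param clip_front,clip_tail hard-clip base counts (default 0).
#' @param min_length drop pairs with either mate shorter than this
#'   (default 0 = keep everything).
#' @param threads accepted for interface compatibility; the implementation is
#'   single-threaded and results are identical at any thread count.
#' @return an object of class `trim_config`.
#' @export
trim_config <- function(adapter1 = ADAPTER_R1, adapter2 = ADAPTER_R2,
                        k = 2, cutoff = 9, trim_score = 10, tail_length = 12,
                        tail_rule = c("pseudocode", "prose"),
                        consensus = TRUE, max_mismatch_ratio = 0.28,
                        quality_trim = TRUE, window = 5, quality_threshold = 15,
                        n_trim = FALSE, clip_front = 0, clip_tail = 0,
                        min_length = 0, threads = 1) {
  tail_rule <- match.arg(tail_rule)
  stopifnot(nchar(adapter1) >= 1, nchar(adapter2) >= 1, k >= 0, cutoff >= 0,
            tail_length >= 0, max_mismatch_ratio >= 0, max_mismatch_ratio <= 1,
            window >= 1, quality_threshold >= 0, clip_front >= 0,
            clip_tail >= 0, min_length >= 0, threads >= 1)
  structure(list(
    adapter1 = adapter1, adapter2 = adapter2,
    k = as.integer(k), cutoff = as.integer(cutoff),
    trim_score = trim_score, tail_length = as.integer(tail_length),
    tail_rule = tail_rule, consensus = isTRUE(consensus),
    max_mismatch_ratio = max_mismatch_ratio,
    quality_trim = isTRUE(quality_trim), window = as.integer(window),
    quality_threshold = quality_threshold, n_trim = isTRUE(n_trim),
    clip_front = as.integer(clip_front), clip_tail = as.integer(clip_tail),
    min_length = as.integer(min_length), threads = as.integer(threads)),
    class = "trim_config")
}

#' @export
print.trim_config <- function(x, ...) {
  cat("<trim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}

#' Trim a batch of read pairs
#'
#' Runs the full pipeline (adapter trimming, optional consensus calling,
#' quality trimming, optional N trimming, hard clipping, length filtering)
#' over parallel vectors of sequences and qualities in one compiled pass.
#'
#' @param pairs a `data.frame` with columns `seq1`, `qual1`, `seq2`, `qual2`
#'   (and optionally `id1`, `id2`), as returned by [read_fastq_pairs()] or
#'   [simulate_grid()].
#' @param config a [trim_config()].
#' @return the input `data.frame` with sequences and qualities replaced by
#'   their trimmed versions and added columns `trimmed`, `insert_size_r1`,
#'   `insert_size_r2`, `combined_score`, `reason`, `consensus_corrected`,
#'   `dropped`.  Dropped pairs are flagged, not removed.
#' @export
trim_pairs <- function(pairs, config = trim_config()) {
  stopifnot(inherits(config, "trim_config"),
            all(c("seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  res <- cpp_trim_batch(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                        config$adapter1, config$adapter2,
                        config$k, config$cutoff, config$trim_score,
                        config$tail_length, config$tail_rule == "prose",
                        config$consensus, config$max_mismatch_ratio,
                        config$quality_trim, config$window,
                        config$quality_threshold, config$n_trim,
                        config$clip_front, config$clip_tail,
                        config$min_length)
  out <- pairs
  out$seq1 <- res$seq1; out$qual1 <- res$qual1
  out$seq2 <- res$seq2; out$qual2 <- res$qual2
  out$trimmed <- res$trimmed
  out$insert_size_r1 <- res$insert_size_r1
  out$insert_size_r2 <- res$insert_size_r2
  out$combined_score <- res$combined_score
  out$reason <- c("agreed", "score-max", "low-quality-override",
                  "rejected-tail-FP", "below-threshold")[res$reason]
  out$consensus_corrected <- res$consensus_corrected
  out$dropped <- res$dropped
  out
}

#' Trim a single read pair through the module interface
#'
#' Composes the exported per-module operations ([four_way_match()],
#' [decide_trim()], [apply_verdict()], [predict_overlap()],
#' [assess_overlap()], [correct_overlap()], [quality_trim()], [n_trim()],
#' [hard_clip()], [length_filter()]) in the fixed stage order.  Equivalent to
#' one row of [trim_pairs()]; mainly useful interactively and for testing the
#' batch path against the module surface.
#'
#' @param r1,r2 [fastq_read()] objects.
#' @param config a [trim_config()].
#' @return list with `r1`, `r2`, `verdict`, `consensus_corrected`, `dropped`.
#' @export
trim_pair <- function(r1, r2, config = trim_config()) {
  st <- four_way_match(r1, r2, config$adapter1, config$adapter2,
                       config$k, config$cutoff)
  v <- decide_trim(st, r1, r2, config$trim_score, config$tail_length,
                   config$tail_rule, config$adapter1, config$adapter2)
  cut <- apply_verdict(r1, r2, v)
  r1 <- cut$r1; r2 <- cut$r2
  corrected <- FALSE
  if (config$consensus) {
    pred <- predict_overlap(r1, r2, v, config$k)
    if (pred$overlap &&
        assess_overlap(r1, r2, pred$insert_size, config$max_mismatch_ratio)$pass) {
      cons <- correct_overlap(r1, r2, pred$insert_size)
      r1 <- cons$r1; r2 <- cons$r2
      corrected <- cons$n_corrected > 0
    }
  }
  if (config$quality_trim) {
    r1 <- quality_trim(r1, config$window, config$quality_threshold)
    r2 <- quality_trim(r2, config$window, config$quality_threshold)
  }
  if (config$n_trim) {
    r1 <- n_trim(r1)
    r2 <- n_trim(r2)
  }
  if (config$clip_front > 0 || config$clip_tail > 0) {
    r1 <- hard_clip(r1, config$clip_front, config$clip_tail)
    r2 <- hard_clip(r2, config$clip_front, config$clip_tail)
  }
  list(r1 = r1, r2 = r2, verdict = v, consensus_corrected = corrected,
       dropped = !length_filter(r1, r2, config$min_length))
}

#' Trim a single-end read (adapter-only convenience mode)
#'
#' Minimal single-end mode: only the adapter scan and the score threshold are
#' used — none of the paired-end machinery applies.  Provided as a
#' convenience, not a benchmarked procedure.
#'
#' @param read a [fastq_read()].
#' @param adapter adapter sequence.
#' @param k mismatch tolerance.
#' @param trim_score score threshold (strict).
#' @return the (possibly trimmed) read.
#' @export
trim_single <- function(read, adapter = ADAPTER_R1, k = 2, trim_score = 10) {
  m <- kmer_scan(adapter, read$seq, k)
  if (!m$found) return(read)
  score <- m$n_match * mean_16mer_prob(read$qual, m$offset)
  if (score > trim_score) trim_to(read, m$offset) else read
}

#' Trim paired FASTQ files
#'
#' File-level front end: reads synchronized pairs, runs [trim_pairs()],
#' drops filtered pairs, writes the outputs and a JSON run summary.
#'
#' @param input1,input2 input FASTQ paths (plain or gzip).
#' @param output1,output2 output FASTQ paths; compressed when ending in
#'   `.gz` (or per `compress`).
#' @param config a [trim_config()].
#' @param compress write gzip outputs (default: inferred from `output1`).
#' @param summary_json optional path for the JSON summary.
#' @return invisibly, the summary list: `pairs_read`, `pairs_trimmed`,
#'   `pairs_consensus_corrected`, `pairs_dropped`, `pairs_written`.
#' @export
trim_fastq <- function(input1, input2, output1, output2,
                       config = trim_config(),
                       compress = grepl("\\.gz$", output1),
                       summary_json = NULL) {
  pairs <- read_fastq_pairs(input1, input2)
  res <- trim_pairs(pairs, config)
  kept <- res[!res$dropped, , drop = FALSE]
  write_fastq_pairs(kept, output1, output2, compress)
  summary <- list(pairs_read = nrow(res),
                  pairs_trimmed = sum(res$trimmed),
                  pairs_consensus_corrected = sum(res$consensus_corrected),
                  pairs_dropped = sum(res$dropped),
                  pairs_written = nrow(kept))
  if (!is.null(summary_json))
    jsonlite::write_json(summary, summary_json, auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
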