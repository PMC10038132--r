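#' Probability that a base call is correct
#'
#' Converts a Phred quality score to the probability that the call is
#' correct: `P = 1 - 10^(-Q/10)`.
#'
#' @param q non-negative Phred score(s).
#' @return probabilities in `[0, 1)`.
#' @examples
#' phred_to_prob(c(0, 10, 30))
#' @export
phred_to_prob <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative")
  1 - 10^(-q / 10)
}

#' Mean 16-mer base accuracy
#'
#' Arithmetic mean of [phred_to_prob()] over the 16 bases starting at `start`
#' (0-based), restricted to in-range bases; windows at the read tail average
#' only the available bases.  With `floored = TRUE` (the default, used by the
#' match scoring) the result is bounded below at 0.75, and a fully
#' out-of-range window returns 0.75.  The unfloored mean (`floored = FALSE`)
#' is what the low-quality override of the decision rules compares against
#' its 0.6 threshold — the floor would otherwise make that comparison
#' unsatisfiable.
#'
#' @param qual a Phred+33 quality string, or an integer vector of Phred
#'   scores.
#' @param start 0-based window start.
#' @param floored apply the 0.75 lower bound (default `TRUE`).
#' @return a probability.
#' @examples
#' mean_16mer_prob(strrep("5", 16), 0)  # all Q20 -> 0.99
#' mean_16mer_prob(strrep("#", 16), 0)  # all Q2 -> floored to 0.75
#' @export
mean_16mer_prob <- function(qual, start, floored = TRUE) {
  stopifnot(start >= 0)
  if (is.character(qual)) {
    return(cpp_mean16(qual, as.integer(start), isTRUE(floored)))
  }
  idx <- seq.int(start + 1, start + 16)
  idx <- idx[idx >= 1 & idx <= length(qual)]
  if (length(idx) == 0) return(if (isTRUE(floored)) 0.75 else 0)
  m <- mean(phred_to_prob(qual[idx]))
  if (isTRUE(floored)) max(m, 0.75) else m
}

#' Quality-weighted match score
#'
#' `S = n_match * p_a * p_b`, the matched-base count of a 16-mer comparison
#' weighted by the mean base accuracies of the two matched regions.  For a
#' user-defined adapter the adapter-side probability is 1.  Scores range from
#' 0 to 16.
#'
#' @param n_match matched bases, `0..16`.
#' @param p_a,p_b mean base accuracies (post-floor, so in `[0.75, 1]`, or
#'   exactly 1 for an adapter).
#' @return the score.
#' @examples
#' match_score(12, 0.99, 1)
#' @export
match_score <- function(n_match, p_a, p_b) {
  stopifnot(n_match >= 0, n_match <= 16, p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  n_match * p_a * p_b
}
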