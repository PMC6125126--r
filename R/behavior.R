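#' Percent time freezing within a scoring window
#'
#' Freezing intervals (immobility except respiration) are clipped to the
#' window, merged, and the union length is expressed as a percentage of the
#' window length. Splitting a bout into abutting sub-intervals does not
#' change the score.
#'
#' @param intervals data.frame (or 2-column matrix) of freezing bouts with
#'   start/end times in seconds (columns `start_s`/`end_s` or the first two
#'   columns).
#' @param window Numeric pair `(start_s, end_s)` of the scoring window.
#' @return Percentage in `[0, 100]`.
#' @export
freezing_percent <- function(intervals, window) {
  if (diff(window) <= 0) stop("zero-length scoring window")
  if (is.null(intervals) || NROW(intervals) == 0) return(0)
  if (is.data.frame(intervals)) {
    s <- intervals$start_s %||% intervals[[1]]
    e <- intervals$end_s %||% intervals[[2]]
  } else {
    s <- intervals[, 1]
    e <- intervals[, 2]
  }
  if (any(e < s)) stop("interval with end < start")
  s <- pmax(s, window[1])
  e <- pmin(e, window[2])
  keep <- e > s
  if (!any(keep)) return(0)
  m <- merge_intervals(s[keep], e[keep])
  100 * sum(m[, "end"] - m[, "start"]) / diff(window)
}

#' Average per-trial scores over two-trial blocks
#'
#' Consecutive non-overlapping pairs of trials are averaged in order; a
#' trailing unpaired trial (the 15th of an extinction session) is excluded
#' and reported via the `dropped` attribute.
#'
#' @param trial_scores Numeric per-trial scores, in trial order.
#' @param block_size Trials per block.
#' @return Numeric vector of block means with attribute `dropped` (number of
#'   excluded trailing trials).
#' @export
block_scores <- function(trial_scores, block_size = 2) {
  n <- length(trial_scores)
  if (n == 0) stop("no trial scores")
  if (n < block_size) stop("fewer trials than one block")
  n_blocks <- n %/% block_size
  used <- trial_scores[seq_len(n_blocks * block_size)]
  out <- colMeans(matrix(used, nrow = block_size))
  attr(out, "dropped") <- n - n_blocks * block_size
  out
}

#' Freezing scores for a session: pretone, per trial and per block
#'
#' The pretone score covers the 30 s window ending at the first tone onset
#' (one value per session); tone scores cover each CS window; block scores
#' average consecutive two-trial pairs.
#'
#' @param intervals Freezing intervals as in [freezing_percent()].
#' @param tone_onsets Tone onset times in seconds.
#' @param tone_duration_s CS duration in seconds.
#' @param block_size Trials per block.
#' @return List with `pretone`, `per_trial`, `per_block`.
#' @export
session_freezing <- function(intervals, tone_onsets, tone_duration_s = 30,
                             block_size = 2) {
  pre <- freezing_percent(intervals, c(tone_onsets[1] - 30, tone_onsets[1]))
  per_trial <- vapply(tone_onsets, function(on) {
    freezing_percent(intervals, c(on, on + tone_duration_s))
  }, numeric(1))
  per_block <- if (length(per_trial) >= block_size) {
    block_scores(per_trial, block_size)
  } else {
    numeric(0)
  }
  list(pretone = pre, per_trial = per_trial, per_block = per_block)
}
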