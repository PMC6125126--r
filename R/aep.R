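#' Extract pip-aligned epochs from a recording
#'
#' Cuts one segment per pip onset of the selected trials, over
#' `window_ms` relative to pip onset, and baseline-corrects each segment by
#' subtracting its own mean over the `baseline_ms` pre-onset window
#' (half-open, `[baseline_ms[1], baseline_ms[2])`). Pips whose window falls
#' outside the recording are dropped; the count is kept in the `dropped`
#' attribute.
#'
#' @param recording A [session_recording()].
#' @param region Channel name, e.g. `"BLA"`.
#' @param trials Trial indices, typically from [select_block_trials()].
#' @param window_ms Epoch window relative to pip onset.
#' @param baseline_ms Baseline-correction window (must lie inside
#'   `window_ms` and end at or before 0).
#' @return Matrix (segments x time) with attributes `time_ms` and `dropped`.
#' @export
epoch_pips <- function(recording, region, trials,
                       window_ms = c(-200, 400), baseline_ms = c(-100, 0)) {
  stopifnot(inherits(recording, "session_recording"))
  if (!region %in% names(recording$channels)) {
    stop("unknown region '", region, "'")
  }
  if (baseline_ms[1] < window_ms[1] || baseline_ms[2] > window_ms[2]) {
    stop("baseline window must lie inside the epoch window")
  }
  x <- recording$channels[[region]]
  rate <- recording$rate
  ev <- recording$events
  pips <- ev$time_s[ev$kind == "pip_onset" & ev$trial_index %in% trials]
  if (length(pips) == 0) stop("no pip events for the requested trials")
  i_rel <- seq.int(round(window_ms[1] / 1000 * rate),
                   round(window_ms[2] / 1000 * rate))
  time_ms <- i_rel / rate * 1000
  bl <- time_ms >= baseline_ms[1] & time_ms < baseline_ms[2]
  segs <- list()
  dropped <- 0L
  for (p in pips) {
    i0 <- round(p * rate) + 1L
    idx <- i0 + i_rel
    if (idx[1] < 1 || idx[length(idx)] > length(x)) {
      dropped <- dropped + 1L
      next
    }
    s <- x[idx]
    segs[[length(segs) + 1L]] <- s - mean(s[bl])
  }
  if (length(segs) == 0) stop("all pip epochs fell outside the recording")
  out <- do.call(rbind, segs)
  attr(out, "time_ms") <- time_ms
  attr(out, "dropped") <- dropped
  attr(out, "region") <- region
  out
}

#' Average pip-aligned segments into an evoked response
#'
#' @param segments Matrix from [epoch_pips()] (segments x time).
#' @return An object of class `evoked_response`: the pointwise mean
#'   waveform, its time axis, and the number of pips averaged.
#' @export
average_aep <- function(segments) {
  if (is.null(dim(segments)) || nrow(segments) < 1) {
    stop("need at least one segment")
  }
  structure(list(waveform = colMeans(segments),
                 time_ms = attr(segments, "time_ms"),
                 n_pips = nrow(segments),
                 region = attr(segments, "region"),
                 amplitude_uv = NA_real_,
                 peak_latency_ms = NA_real_,
                 trough_latency_ms = NA_real_),
            class = "evoked_response")
}

#' Score evoked-potential amplitude as first peak minus first trough
#'
#' Finds the first local maximum after response onset whose topographic
#' prominence exceeds a floor, then the first local minimum after that peak
#' whose prominence also exceeds the floor; the amplitude is the peak value
#' minus the trough value. The default floor is the larger of twice the
#' standard deviation of the pre-onset waveform and a tenth of the
#' peak-to-peak range inside the search window, so residual averaging noise
#' cannot promote a ripple on the response flank to "first peak" while at
#' zero noise any deflection qualifies. A waveform with no qualifying
#' peak/trough raises a `no_deflection` condition, distinct from an
#' amplitude of zero.
#'
#' @param evoked An `evoked_response` (or a list with `waveform` and
#'   `time_ms`).
#' @param search_window_ms Post-onset window searched for the peak.
#' @param prominence_floor Minimum prominence in microvolts; `NULL` uses
#'   `max(2 * sd(pre-onset waveform), 0.1 * range(search window))`.
#' @return The `evoked_response` with `amplitude_uv`, `peak_latency_ms` and
#'   `trough_latency_ms` filled in.
#' @export
score_amplitude <- function(evoked, search_window_ms = c(0, 250),
                            prominence_floor = NULL) {
  w <- evoked$waveform
  t <- evoked$time_ms
  if (search_window_ms[1] < t[1] || search_window_ms[2] > t[length(t)]) {
    stop("waveform does not cover the search window")
  }
  in_win <- which(t >= search_window_ms[1] & t <= search_window_ms[2])
  if (is.null(prominence_floor)) {
    pre <- w[t < 0]
    noise_floor <- if (length(pre) > 1) 2 * stats::sd(pre) else 0
    # the peak additionally has to stand out against the response range so
    # that an averaging-noise ripple on the rising flank cannot be taken as
    # the first peak; the trough may legitimately be shallow
    peak_floor <- max(noise_floor, 0.1 * diff(range(w[in_win])))
    trough_floor <- noise_floor
  } else {
    peak_floor <- trough_floor <- prominence_floor
  }
  peak_i <- first_extremum(w, in_win, peak_floor, maximum = TRUE)
  if (is.na(peak_i)) no_deflection("no qualifying peak in the search window")
  after <- in_win[in_win > peak_i]
  trough_i <- first_extremum(w, after, trough_floor, maximum = FALSE)
  if (is.na(trough_i)) no_deflection("no qualifying trough after the peak")
  evoked$amplitude_uv <- w[peak_i] - w[trough_i]
  evoked$peak_latency_ms <- t[peak_i]
  evoked$trough_latency_ms <- t[trough_i]
  evoked
}

no_deflection <- function(msg) {
  stop(structure(class = c("no_deflection", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# First local extremum (in index order) within `candidates` whose
# topographic prominence exceeds `floor`. Prominence of a maximum at i:
# value minus the higher of the two minima separating it from higher
# terrain (or the window edge) on each side.
first_extremum <- function(w, candidates, floor, maximum = TRUE) {
  s <- if (maximum) w else -w
  n <- length(s)
  for (i in candidates) {
    if (i <= 1 || i >= n) next
    if (!(s[i] >= s[i - 1] && s[i] >= s[i + 1] &&
          (s[i] > s[i - 1] || s[i] > s[i + 1]))) next
    # scan left/right to the nearest strictly higher sample (or edge)
    left <- i - 1
    min_l <- s[left]
    while (left > 1 && s[left] <= s[i]) {
      left <- left - 1
      min_l <- min(min_l, s[left])
    }
    right <- i + 1
    min_r <- s[right]
    while (right < n && s[right] <= s[i]) {
      right <- right + 1
      min_r <- min(min_r, s[right])
    }
    prom <- s[i] - max(min_l, min_r)
    if (prom > floor || (floor == 0 && prom >= 0)) return(i)
  }
  NA_integer_
}

#' Express a value as a percentage of a baseline
#'
#' @param value,baseline Numeric; `baseline` must be positive.
#' @return `100 * value / baseline`.
#' @export
normalize_percent <- function(value, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("baseline must be positive")
  }
  100 * value / baseline
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf("<evoked_response> %s, %d pips, window %g..%g ms\n",
              x$region %||% "?", x$n_pips, x$time_ms[1],
              x$time_ms[length(x$time_ms)]))
  if (!is.na(x$amplitude_uv)) {
    cat(sprintf("  amplitude %.2f uV (peak %.0f ms, trough %.0f ms)\n",
                x$amplitude_uv, x$peak_latency_ms, x$trough_latency_ms))
  }
  invisible(x)
}

#' @export
plot.evoked_response <- function(x, ...) {
  graphics::plot(x$time_ms, x$waveform, type = "l",
                 xlab = "time from pip onset (ms)", ylab = "amplitude (uV)",
                 main = sprintf("AEP (%s, %d pips)", x$region %||% "?",
                                x$n_pips), ...)
  graphics::abline(v = 0, lty = 3)
  if (!is.na(x$amplitude_uv)) {
    graphics::points(c(x$peak_latency_ms, x$trough_latency_ms),
                     x$waveform[match(c(x$peak_latency_ms, x$trough_latency_ms),
                                      x$time_ms)],
                     pch = c(19, 17))
  }
  invisible(x)
}
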