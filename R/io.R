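#' Construct and validate a session recording
#'
#' Container for one animal-session: two equal-length channels in microvolts
#' (named by region), the sampling rate, an ordered event timeline
#' (tone/pip/US onsets), a trial table, and animal metadata. Validation
#' enforces equal channel lengths, non-decreasing event times, and that every
#' trial has exactly `pips_per_tone` pip events inside its
#' `[tone_onset, tone_onset + tone_duration)` window.
#'
#' @param channels Named list of numeric vectors (regions, typically
#'   `dmPFC` and `BLA`), in microvolts.
#' @param rate Sampling rate in Hz.
#' @param events data.frame with columns `time_s`, `kind`
#'   (`tone_onset`/`pip_onset`/`us_onset`) and `trial_index`; sorted on
#'   construction.
#' @param trials data.frame with columns `trial_index`, `session_label`,
#'   `tone_onset_s`.
#' @param animal_id,group Metadata; `group` is `"control"` or `"CIS"`.
#' @param design Optional [session_design()] used for validation (pip count
#'   and tone duration); defaults describe the standard 30-pip, 30-s CS.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(channels, rate, events, trials,
                              animal_id = "unknown", group = "control",
                              design = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) stop("channel length mismatch")
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  if (is.unsorted(events$time_s)) stop("events must be ordered in time")
  if (!all(trials$session_label %in% session_labels())) {
    stop("unknown session_label: ",
         paste(setdiff(unique(trials$session_label), session_labels()),
               collapse = ", "))
  }
  pips_per_tone <- if (!is.null(design)) design$pips_per_tone else 30L
  tone_duration <- if (!is.null(design)) design$tone_duration_s else 30
  pips <- events[events$kind == "pip_onset", , drop = FALSE]
  for (i in seq_len(nrow(trials))) {
    on <- trials$tone_onset_s[i]
    k <- sum(pips$time_s >= on - 1e-9 & pips$time_s < on + tone_duration)
    if (k != pips_per_tone) {
      stop(sprintf("trial %d has %d pip events in its tone window, expected %d",
                   trials$trial_index[i], k, pips_per_tone))
    }
  }
  structure(list(channels = channels, rate = rate, events = events,
                 trials = trials, animal_id = animal_id, group = group,
                 design = design),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<session_recording> %s (%s), %s\n", x$animal_id, x$group,
              x$trials$session_label[1]))
  cat(sprintf("  channels: %s; %d samples @ %g Hz (%.1f s)\n",
              paste(names(x$channels), collapse = ", "), n, x$rate, n / x$rate))
  cat(sprintf("  trials: %d; events: %d\n", nrow(x$trials), nrow(x$events)))
  invisible(x)
}

#' Write a session recording to a directory
#'
#' The on-disk container is a directory of plain-text files: `signals.csv`
#' (one column per channel, formatted so doubles round-trip exactly),
#' `events.csv`, `trials.csv`, and `meta.json` (rate, units, region labels,
#' animal metadata, and the ground-truth manifest when present).
#'
#' @param recording A [session_recording()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(recording, path) {
  stopifnot(inherits(recording, "session_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sig <- vapply(recording$channels, function(ch) sprintf("%.17g", ch),
                character(length(recording$channels[[1]])))
  utils::write.csv(as.data.frame(sig), file.path(path, "signals.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(recording$events, file.path(path, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(recording$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  meta <- list(rate = recording$rate, units = "uV",
               regions = names(recording$channels),
               animal_id = recording$animal_id, group = recording$group,
               ground_truth = recording$ground_truth)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a session recording from a directory
#'
#' Inverse of [write_session()]; re-validates the recording on load. Events
#' are re-sorted, so the stored row order is irrelevant.
#'
#' @param path Directory written by [write_session()].
#' @return A [session_recording()].
#' @export
load_session <- function(path) {
  need <- c("signals.csv", "events.csv", "trials.csv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("session container missing file(s): ", paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  sig <- data.table::fread(file.path(path, "signals.csv"), data.table = FALSE)
  channels <- lapply(sig, as.numeric)
  events <- utils::read.csv(file.path(path, "events.csv"),
                            stringsAsFactors = FALSE)
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  rec <- session_recording(channels = channels, rate = meta$rate,
                           events = events, trials = trials,
                           animal_id = meta$animal_id, group = meta$group)
  if (!is.null(meta$ground_truth) && length(meta$ground_truth)) {
    gt <- meta$ground_truth
    if (!is.null(gt$trials)) gt$trials <- as.data.frame(gt$trials)
    rec$ground_truth <- gt
  }
  rec
}

#' Validate a stored session and print a schema report
#'
#' @param path Session directory.
#' @return `TRUE` invisibly on success; stops with the validation error
#'   otherwise.
#' @export
validate_session <- function(path) {
  rec <- load_session(path)
  cat("session at", path, "is valid:\n")
  print(rec)
  invisible(TRUE)
}

#' Select the analysis trials for a timepoint
#'
#' Evoked measures are computed from two trials per timepoint: the last two
#' trials of tone habituation ("before conditioning"), the first two trials
#' of the fear-recall/extinction session ("fear recall"), and the first two
#' trials of the extinction-recall session ("extinction recall").
#'
#' @param recording A [session_recording()].
#' @param timepoint One of `"before_conditioning"`, `"fear_recall"`,
#'   `"extinction_recall"`.
#' @return Integer vector of two trial indices.
#' @export
select_block_trials <- function(recording,
                                timepoint = c("before_conditioning",
                                              "fear_recall",
                                              "extinction_recall")) {
  timepoint <- match.arg(timepoint)
  wanted <- switch(timepoint,
                   before_conditioning = "tone_habituation",
                   fear_recall = "fear_recall_extinction",
                   extinction_recall = "extinction_recall")
  tr <- recording$trials
  if (!all(tr$session_label == wanted)) {
    stop("recording is not a '", wanted, "' session")
  }
  if (nrow(tr) < 2) stop("fewer than two trials in session")
  idx <- sort(tr$trial_index)
  if (timepoint == "before_conditioning") {
    utils::tail(idx, 2)
  } else {
    utils::head(idx, 2)
  }
}

#' Partition a session's trials into two-trial blocks
#'
#' Blocks of two consecutive trials, in order; a trailing unpaired trial
#' (e.g. the 15th of an extinction session, scored as 7 blocks) is excluded
#' and reported in the `dropped` attribute.
#'
#' @param recording A [session_recording()] (or a trial-index vector).
#' @return data.frame with columns `block_index`, `trial_index`.
#' @export
trial_blocks <- function(recording) {
  idx <- if (inherits(recording, "session_recording")) {
    sort(recording$trials$trial_index)
  } else {
    sort(recording)
  }
  n_blocks <- length(idx) %/% 2L
  if (n_blocks == 0) stop("need at least two trials to form a block")
  used <- idx[seq_len(2L * n_blocks)]
  out <- data.frame(block_index = rep(seq_len(n_blocks), each = 2),
                    trial_index = used)
  attr(out, "dropped") <- setdiff(idx, used)
  out
}
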