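# Event-based scoring: prediction smoothing, event extraction, margin-based
# matching, and the performance measures - sensitivity, false alarm rate per
# 24 recorded hours (FAR24), false alarm rate per standard 8-h night (FARn,
# 23:00-07:00 local, normalized by nightly hours actually recorded), and
# positive predictive value. True negatives are never counted.

#' Smooth a predicted label series
#'
#' Two passes on the 2-s grid, in order: (1) fill any gap of zeros of at most
#' `max_gap_s` flanked by seizure labels; (2) remove orphan runs of seizure
#' labels shorter than `min_run_s`. Gap filling never bridges recording gaps:
#' the series is processed per contiguous chunk of `times`.
#'
#' @param labels Integer 0/1 vector on the 2-s grid.
#' @param times Optional grid times; when given, smoothing respects
#'   contiguity (chunks split where the grid step exceeds 2 s).
#' @param max_gap_s Maximum gap to fill (s), default 30.
#' @param min_run_s Minimum run to keep (s), default 6.
#' @return Smoothed 0/1 vector.
#' @export
smooth_labels <- function(labels, times = NULL, max_gap_s = 30,
                          min_run_s = 6) {
  if (is.null(times)) return(.smooth_chunk(labels, max_gap_s, min_run_s))
  out <- integer(length(labels))
  for (idx in .contiguous_chunks(times))
    out[idx] <- .smooth_chunk(labels[idx], max_gap_s, min_run_s)
  out
}

.contiguous_chunks <- function(times, step = 2) {
  if (!length(times)) return(list())
  brk <- c(0L, which(diff(times) > step + 1e-9), length(times))
  lapply(seq_len(length(brk) - 1L), function(i) (brk[i] + 1L):brk[i + 1L])
}

.smooth_chunk <- function(labels, max_gap_s, min_run_s) {
  x <- as.integer(labels)
  n <- length(x)
  if (n == 0L) return(x)
  # pass 1: fill interior 0-runs of duration <= max_gap_s
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0L && k > 1L && k < length(r$values) &&
        r$lengths[k] * 2 <= max_gap_s)
      x[starts[k]:ends[k]] <- 1L
  }
  # pass 2: remove 1-runs shorter than min_run_s
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == 1L && r$lengths[k] * 2 < min_run_s)
      x[starts[k]:ends[k]] <- 0L
  }
  x
}

#' Extract events from a label series
#'
#' Maximal runs of seizure labels become events `[t_first, t_last + 2)`.
#' Runs shorter than `min_dur_s` are dropped; runs longer than `max_dur_s`
#' are truncated to their first `max_dur_s` seconds and counted once.
#'
#' @param labels 0/1 vector (smoothed).
#' @param times Grid times (epoch s); contiguity is respected.
#' @param min_dur_s,max_dur_s Event duration bounds (s), default 6 and 600.
#' @return Event matrix: two columns `start`, `end`, sorted, non-overlapping.
#' @export
to_events <- function(labels, times, min_dur_s = 6, max_dur_s = 600) {
  evs <- list()
  for (idx in .contiguous_chunks(times)) {
    x <- as.integer(labels[idx])
    t <- times[idx]
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] != 1L) next
      dur <- r$lengths[k] * 2
      if (dur < min_dur_s) next
      s <- t[starts[k]]
      e <- t[ends[k]] + 2
      if (dur > max_dur_s) e <- s + max_dur_s
      evs[[length(evs) + 1L]] <- c(s, e)
    }
  }
  .event_matrix(evs)
}

.event_matrix <- function(evs) {
  if (!length(evs))
    return(matrix(numeric(), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  m <- do.call(rbind, evs)
  colnames(m) <- c("start", "end")
  m[order(m[, 1L]), , drop = FALSE]
}

#' Events from seizure annotations
#'
#' @param annotations A [seizure_annotations()] data frame.
#' @return Event matrix (`start`, `end`).
#' @export
annotation_events <- function(annotations) {
  .event_matrix(lapply(seq_len(nrow(annotations)), function(i)
    c(annotations$onset[i], annotations$offset[i])))
}

#' Match predicted events against ground truth with a margin
#'
#' Each truth event is extended by `margin_s` on both sides (default 2 min);
#' a truth event overlapped by at least one prediction is one true positive,
#' and all predictions overlapping it are absorbed (not false positives).
#' Unmatched truth events are false negatives; predictions overlapping no
#' extended truth event are false positives.
#'
#' @param truth,pred Event matrices (`start`, `end`).
#' @param margin_s Margin (s) before and after each truth event.
#' @return List: `tp`, `fp`, `fn`, `truth_matched` (logical),
#'   `pred_matched` (logical), `fp_events` (matrix of the false-positive
#'   prediction events).
#' @export
match_events <- function(truth, pred, margin_s = 120) {
  nt <- nrow(truth); np <- nrow(pred)
  truth_matched <- logical(nt)
  pred_matched <- logical(np)
  if (nt && np) {
    for (i in seq_len(nt)) {
      a <- truth[i, 1L] - margin_s
      b <- truth[i, 2L] + margin_s
      ov <- pred[, 1L] < b & pred[, 2L] > a
      if (any(ov)) {
        truth_matched[i] <- TRUE
        pred_matched <- pred_matched | ov
      }
    }
  }
  list(tp = sum(truth_matched), fp = sum(!pred_matched),
       fn = sum(!truth_matched), truth_matched = truth_matched,
       pred_matched = pred_matched,
       fp_events = pred[!pred_matched, , drop = FALSE])
}

#' False alarm rate per 24 recorded hours
#'
#' @param fp False-positive event count.
#' @param recording_hours Hours of data actually recorded (> 0).
#' @return `fp * 24 / recording_hours`.
#' @export
far24 <- function(fp, recording_hours) {
  if (recording_hours <= 0) stop("recording_hours must be positive")
  fp * 24 / recording_hours
}

# night windows [23:00, 07:00) local time covering [t0, t1] (epoch s, UTC)
.night_windows <- function(t0, t1, utc_offset_hours, night = c(23, 7)) {
  if (t1 <= t0) return(matrix(numeric(), 0L, 2L))
  off <- utc_offset_hours * 3600
  day0 <- floor((t0 + off) / 86400) - 1
  day1 <- floor((t1 + off) / 86400) + 1
  starts <- (day0:day1) * 86400 + night[1L] * 3600 - off
  dur <- ((night[2L] - night[1L]) %% 24) * 3600
  cbind(start = starts, end = starts + dur)
}

#' Hours recorded during the standard night
#'
#' Total overlap of the recording's segments with local 23:00-07:00 windows;
#' recording gaps contribute zero ("taking into account any data loss").
#'
#' @param segments Matrix/data frame of segment `start`, `end` epoch seconds,
#'   or a [recording()].
#' @param utc_offset_hours Local-time offset (ignored for a recording, which
#'   carries its own).
#' @param night Night window as local hours `c(start, end)`.
#' @return Hours (numeric).
#' @export
nightly_hours <- function(segments, utc_offset_hours = 0, night = c(23, 7)) {
  if (inherits(segments, "mm_recording")) {
    utc_offset_hours <- segments$utc_offset_hours
    segments <- cbind(
      start = vapply(segments$segments, function(s) s$start_time, 0),
      end = vapply(segments$segments, .segment_end, 0))
  }
  segments <- as.matrix(segments)
  if (!nrow(segments)) return(0)
  total <- 0
  for (i in seq_len(nrow(segments))) {
    nw <- .night_windows(segments[i, 1L], segments[i, 2L], utc_offset_hours,
                         night)
    if (!nrow(nw)) next
    ov <- pmax(0, pmin(nw[, 2L], segments[i, 2L]) -
                  pmax(nw[, 1L], segments[i, 1L]))
    total <- total + sum(ov)
  }
  total / 3600
}

#' False alarm rate per standard night
#'
#' Counts false-positive events whose start time falls in the local
#' 23:00-07:00 window and normalizes by the nightly hours actually recorded:
#' `FARn = fp_night * hours_per_night / nightly_hours_recorded` with 8 hours
#' per night. Returns `NA` when there is no nightly coverage.
#'
#' @param fp_events Matrix of false-positive events (`start`, `end`).
#' @param segments Segment intervals or a [recording()] (see
#'   [nightly_hours()]).
#' @param utc_offset_hours Local-time offset.
#' @param night Night window as local hours.
#' @param hours_per_night Standard night length (8).
#' @return List: `farn`, `fp_night`, `nightly_hours_recorded`.
#' @export
farn <- function(fp_events, segments, utc_offset_hours = 0, night = c(23, 7),
                 hours_per_night = 8) {
  nh <- nightly_hours(segments, utc_offset_hours, night)
  if (inherits(segments, "mm_recording"))
    utc_offset_hours <- segments$utc_offset_hours
  n_night <- 0L
  if (nrow(fp_events)) {
    local_h <- ((fp_events[, 1L] / 3600 + utc_offset_hours) %% 24)
    in_night <- if (night[1L] > night[2L])
      local_h >= night[1L] | local_h < night[2L]
    else local_h >= night[1L] & local_h < night[2L]
    n_night <- sum(in_night)
  }
  list(farn = if (nh > 0) n_night * hours_per_night / nh else NA_real_,
       fp_night = n_night, nightly_hours_recorded = nh)
}

#' Write an event set as interval CSV
#'
#' Three columns: `participant_id`, `start`, `end` (epoch seconds).
#'
#' @param events Event matrix (`start`, `end`).
#' @param participant_id Participant identifier recycled over rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, participant_id, path) {
  df <- data.frame(participant_id = rep_len(participant_id,
                                            max(nrow(events), 0L)),
                   start = events[, 1L], end = events[, 2L])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Event-level score report for a prediction
#'
#' Smooths the prediction, extracts events, matches them against the truth
#' events with the margin, and assembles the performance measures.
#'
#' @param pred_labels 0/1 prediction on the 2-s grid.
#' @param times Grid times (epoch s).
#' @param truth_events Event matrix of true seizure intervals.
#' @param recording_hours Recorded hours of the scored span (FAR24
#'   denominator).
#' @param margin_s Matching margin (s).
#' @param night Optional list with `segments` (and `utc_offset_hours`) for
#'   the nightly false alarm rate; `NULL` skips FARn.
#' @param smooth Apply [smooth_labels()] first (default `TRUE`).
#' @return List of class `score_report`: `tp`, `fp`, `fn`, `sensitivity`,
#'   `ppv`, `far24`, `farn`, `fp_night`, `nightly_hours_recorded`,
#'   `recording_hours`, `pred_events`.
#' @export
score_prediction <- function(pred_labels, times, truth_events,
                             recording_hours, margin_s = 120, night = NULL,
                             smooth = TRUE) {
  if (smooth) pred_labels <- smooth_labels(pred_labels, times)
  pred_events <- to_events(pred_labels, times)
  m <- match_events(truth_events, pred_events, margin_s)
  rep <- list(tp = m$tp, fp = m$fp, fn = m$fn,
              sensitivity = if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_,
              ppv = if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0,
              far24 = far24(m$fp, recording_hours),
              farn = NA_real_, fp_night = NA_integer_,
              nightly_hours_recorded = NA_real_,
              recording_hours = recording_hours,
              pred_events = pred_events)
  if (!is.null(night)) {
    fn <- farn(m$fp_events, night$segments,
               utc_offset_hours = night$utc_offset_hours %||% 0)
    rep$farn <- fn$farn
    rep$fp_night <- fn$fp_night
    rep$nightly_hours_recorded <- fn$nightly_hours_recorded
  }
  class(rep) <- "score_report"
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(paste0("<score_report: TP %d, FP %d, FN %d | sensitivity %s, ",
                     "FAR24 %.2f, PPV %.3f>\n"),
              x$tp, x$fp, x$fn,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.2f", x$sensitivity)),
              x$far24, x$ppv))
  invisible(x)
}
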