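#' Construct a time-series channel
#'
#' A channel is one uniformly sampled signal from the wearable: `ACC`
#' (n x 3 matrix, units g), `EDA` (microsiemens), `BVP` (arbitrary units) or
#' `TEMP` (degrees Celsius).
#'
#' @param name One of `"ACC"`, `"EDA"`, `"BVP"`, `"TEMP"`.
#' @param start_time Epoch seconds (UTC) of the first sample.
#' @param sample_rate Sampling rate in Hz, positive.
#' @param samples Numeric vector, or an n x 3 matrix for `ACC`.
#' @return An object of class `ts_channel`.
#' @export
ts_channel <- function(name, start_time, sample_rate, samples) {
  name <- match.arg(name, c("ACC", "EDA", "BVP", "TEMP"))
  stopifnot(is.numeric(start_time), length(start_time) == 1L,
            is.numeric(sample_rate), sample_rate > 0)
  if (name == "ACC") {
    samples <- as.matrix(samples)
    if (ncol(samples) != 3L) stop("ACC samples must have 3 columns")
  } else {
    samples <- as.numeric(samples)
  }
  structure(list(name = name, start_time = as.numeric(start_time),
                 sample_rate = as.numeric(sample_rate), samples = samples),
            class = "ts_channel")
}

.channel_n <- function(ch) if (is.matrix(ch$samples)) nrow(ch$samples) else length(ch$samples)

#' @export
print.ts_channel <- function(x, ...) {
  cat(sprintf("<ts_channel %s: %d samples @ %g Hz, start %.0f (%.2f s)>\n",
              x$name, .channel_n(x), x$sample_rate, x$start_time,
              .channel_n(x) / x$sample_rate))
  invisible(x)
}

#' Construct a recording segment
#'
#' A segment is one contiguous session: all channels start at the same epoch
#' time and have no internal gaps. Device swaps and streaming loss are
#' represented as separate segments in a [recording()]; data are never imputed
#' across the gaps between them.
#'
#' @param channels Named list of [ts_channel()] objects sharing a start time.
#' @return An object of class `mm_segment`.
#' @export
segment <- function(channels) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  names(channels) <- vapply(channels, function(ch) ch$name, "")
  starts <- vapply(channels, function(ch) ch$start_time, 0)
  if (max(starts) - min(starts) > 1e-9)
    stop("all channels in a segment must share the start time")
  durs <- vapply(channels, function(ch) .channel_n(ch) / ch$sample_rate, 0)
  structure(list(channels = channels, start_time = starts[[1L]],
                 duration = max(durs)),
            class = "mm_segment")
}

.segment_end <- function(seg) seg$start_time + seg$duration

#' Construct a multimodal recording
#'
#' @param participant_id Participant identifier string.
#' @param segments List of [segment()]s; sorted by start time, must not
#'   overlap.
#' @param wrist `"left"`, `"right"` or `"unknown"` - which wrist wore the
#'   device.
#' @param utc_offset_hours Local-time offset of the recording site, used only
#'   for night-window bookkeeping in [farn()].
#' @return An object of class `mm_recording`.
#' @export
recording <- function(participant_id, segments, wrist = "unknown",
                      utc_offset_hours = 0) {
  wrist <- match.arg(wrist, c("left", "right", "unknown"))
  if (length(segments) > 1L) {
    o <- order(vapply(segments, function(s) s$start_time, 0))
    segments <- segments[o]
    ends <- vapply(segments, .segment_end, 0)
    starts <- vapply(segments, function(s) s$start_time, 0)
    if (any(starts[-1L] < ends[-length(ends)] - 1e-9))
      stop("segments overlap in time")
  }
  structure(list(participant_id = as.character(participant_id),
                 segments = segments, wrist = wrist,
                 utc_offset_hours = as.numeric(utc_offset_hours)),
            class = "mm_recording")
}

#' @export
print.mm_recording <- function(x, ...) {
  cat(sprintf("<mm_recording %s: %d segment(s), %.2f h recorded, wrist %s>\n",
              x$participant_id, length(x$segments), recording_hours(x),
              x$wrist))
  invisible(x)
}

#' Hours of data actually recorded
#'
#' Sum of segment durations in hours; gaps between segments (device swaps,
#' streaming loss) contribute zero. This is the denominator of the false alarm
#' rate per 24 h.
#'
#' @param rec A [recording()].
#' @return Hours recorded (numeric scalar).
#' @export
recording_hours <- function(rec) {
  stopifnot(inherits(rec, "mm_recording"))
  sum(vapply(rec$segments, function(s) s$duration, 0)) / 3600
}

#' Construct seizure annotations
#'
#' @param seizure_id Character ids.
#' @param onset,offset Epoch seconds; `offset > onset` is required.
#' @param motor_flags Character vector, semicolon-joined subsets of
#'   `tonic;clonic;automatism;hyperkinetic`.
#' @param tachycardia Logical: ictal tachycardia observed.
#' @param vigilance `"awake"` or `"asleep"` at onset.
#' @param side_matches_device Logical or `NA`: seizure lateralization on the
#'   device wrist.
#' @return A `data.frame` of class `seizure_annotations`, sorted by onset.
#' @export
seizure_annotations <- function(seizure_id, onset, offset,
                                motor_flags = "tonic",
                                tachycardia = FALSE,
                                vigilance = "awake",
                                side_matches_device = NA) {
  n <- length(onset)
  if (n == 0L) {
    df <- data.frame(seizure_id = character(), onset = numeric(),
                     offset = numeric(), motor_flags = character(),
                     tachycardia = logical(), vigilance = character(),
                     side_matches_device = logical(),
                     stringsAsFactors = FALSE)
    class(df) <- c("seizure_annotations", "data.frame")
    return(df)
  }
  if (any(offset <= onset))
    stop("annotation offset must be greater than onset")
  df <- data.frame(seizure_id = as.character(seizure_id),
                   onset = as.numeric(onset), offset = as.numeric(offset),
                   motor_flags = rep_len(as.character(motor_flags), n),
                   tachycardia = rep_len(as.logical(tachycardia), n),
                   vigilance = rep_len(as.character(vigilance), n),
                   side_matches_device = rep_len(as.logical(side_matches_device), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("seizure_annotations", "data.frame")
  df
}
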