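# Session directory dialect: one CSV per channel (ACC.csv three columns,
# EDA.csv / BVP.csv / TEMP.csv one column); line 1 = epoch start time, line 2
# = sample rate in Hz, remaining lines = samples. ACC is stored in raw device
# counts of 1/64 g and converted to g on read. A recording directory holds a
# meta.json sidecar (participant_id, wrist, utc_offset_hours) and one
# session_* subdirectory per contiguous segment.

.acc_counts_per_g <- 64

.read_channel_csv <- function(path, name, ncol_expected) {
  m <- tryCatch(
    as.matrix(read.csv(path, header = FALSE, colClasses = "numeric")),
    warning = function(w) stop(sprintf("non-numeric data in %s", path)),
    error = function(e) stop(sprintf("malformed channel file %s: %s",
                                     path, conditionMessage(e))))
  if (nrow(m) < 2L) stop(sprintf("%s: missing header rows", path))
  if (ncol(m) != ncol_expected)
    stop(sprintf("%s: expected %d column(s), found %d", path, ncol_expected,
                 ncol(m)))
  start <- m[1L, 1L]
  rate <- m[2L, 1L]
  if (!is.finite(start) || !is.finite(rate) || rate <= 0)
    stop(sprintf("%s: non-numeric or invalid header", path))
  samples <- m[-c(1L, 2L), , drop = FALSE]
  dimnames(samples) <- NULL
  if (ncol_expected == 1L) samples <- as.numeric(samples)
  ts_channel(name, start, rate, samples)
}

#' Read one session directory as a recording segment
#'
#' @param dir Directory containing `ACC.csv`, `EDA.csv`, `BVP.csv` and
#'   optionally `TEMP.csv`, each with two header lines (epoch start time,
#'   sample rate) followed by samples. ACC raw counts (1/64 g) are converted
#'   to g.
#' @param acc_counts_per_g Count-to-g conversion divisor; the device default
#'   is 64.
#' @return A [segment()].
#' @export
read_session <- function(dir, acc_counts_per_g = .acc_counts_per_g) {
  mandatory <- c("ACC", "EDA", "BVP")
  chans <- list()
  for (nm in c(mandatory, "TEMP")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm %in% mandatory)
        stop(sprintf("channel-missing error: %s has no %s.csv", dir, nm))
      next
    }
    chans[[nm]] <- .read_channel_csv(path, nm, if (nm == "ACC") 3L else 1L)
  }
  chans$ACC$samples <- chans$ACC$samples / acc_counts_per_g
  segment(chans)
}

#' Write one segment as a session directory
#'
#' Inverse of [read_session()]: ACC is written back in 1/64-g counts so that a
#' write/read round trip reproduces the sample values exactly.
#'
#' @param seg A [segment()].
#' @param dir Output directory (created if absent).
#' @inheritParams read_session
#' @return `dir`, invisibly.
#' @export
write_session <- function(seg, dir, acc_counts_per_g = .acc_counts_per_g) {
  stopifnot(inherits(seg, "mm_segment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in seg$channels) {
    samples <- ch$samples
    nc <- if (is.matrix(samples)) ncol(samples) else 1L
    if (ch$name == "ACC") samples <- samples * acc_counts_per_g
    header <- rbind(rep(ch$start_time, nc), rep(ch$sample_rate, nc))
    m <- rbind(header, if (is.matrix(samples)) samples else cbind(samples))
    write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                file.path(dir, paste0(ch$name, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  invisible(dir)
}

#' Read a full recording directory
#'
#' @param dir Directory with a `meta.json` sidecar (`participant_id`, `wrist`,
#'   `utc_offset_hours`) and one `session_*` subdirectory per contiguous
#'   segment.
#' @inheritParams read_session
#' @return A [recording()].
#' @export
read_recording <- function(dir, acc_counts_per_g = .acc_counts_per_g) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop(sprintf("missing meta.json in %s", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  sess <- sort(list.dirs(dir, recursive = FALSE))
  sess <- sess[grepl("session_", basename(sess))]
  if (length(sess) == 0L) stop(sprintf("no session_* directories in %s", dir))
  segs <- lapply(sess, read_session, acc_counts_per_g = acc_counts_per_g)
  recording(meta$participant_id, segs, wrist = meta$wrist,
            utc_offset_hours = meta$utc_offset_hours)
}

#' Write a full recording directory
#'
#' @param rec A [recording()].
#' @param dir Output directory.
#' @inheritParams read_session
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir, acc_counts_per_g = .acc_counts_per_g) {
  stopifnot(inherits(rec, "mm_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(participant_id = rec$participant_id,
                            wrist = rec$wrist,
                            utc_offset_hours = rec$utc_offset_hours),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  for (i in seq_along(rec$segments))
    write_session(rec$segments[[i]],
                  file.path(dir, sprintf("session_%03d", i)),
                  acc_counts_per_g = acc_counts_per_g)
  invisible(dir)
}

#' Read seizure annotations from CSV
#'
#' Columns: `seizure_id, onset_epoch_s, offset_epoch_s, motor_flags`
#' (semicolon-joined), `tachycardia, vigilance, side_matches_device`.
#' Rows are validated (`offset > onset`) and returned sorted by onset.
#'
#' @param path CSV file path.
#' @return A [seizure_annotations()] data frame.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("seizure_id", "onset_epoch_s", "offset_epoch_s", "motor_flags",
            "tachycardia", "vigilance", "side_matches_device")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("annotation file missing column(s): %s",
                 paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) return(seizure_annotations(character(), numeric(), numeric()))
  if (any(df$offset_epoch_s <= df$onset_epoch_s))
    stop("validation error: annotation offset <= onset")
  seizure_annotations(df$seizure_id, df$onset_epoch_s, df$offset_epoch_s,
                      df$motor_flags, as.logical(df$tachycardia),
                      df$vigilance, as.logical(df$side_matches_device))
}

#' Write seizure annotations to CSV
#'
#' @param ann A [seizure_annotations()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(seizure_id = ann$seizure_id,
                    onset_epoch_s = ann$onset,
                    offset_epoch_s = ann$offset,
                    motor_flags = ann$motor_flags,
                    tachycardia = ann$tachycardia,
                    vigilance = ann$vigilance,
                    side_matches_device = ann$side_matches_device)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
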