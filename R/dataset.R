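# Feature-grid assembly, label derivation, peri-ictal training-set
# construction, z-score normalization with stored parameters, and the data
# selection filters (minimum recording length, seizure duration bounds, EDA
# quality heuristics).

#' Assemble the 11-feature grid for a recording
#'
#' Computes the accelerometry, electrodermal and blood-volume-pulse feature
#' series on a shared 2-s grid. Grid intervals are half-open `[t, t + 2)` and
#' exist only inside contiguous segments; masked (invalid) entries are `NA`
#' in the feature matrix with the per-stream validity recorded in `valid`.
#'
#' @param rec A [recording()].
#' @param acc_args,eda_args,bvp_args Named lists of overrides passed to the
#'   per-modality series functions.
#' @return Object of class `feature_grid`: `participant_id`, `times`,
#'   `features` (n x 11 matrix, canonical column order of [feature_names()]),
#'   `valid` (n x 11 logical).
#' @export
build_feature_grid <- function(rec, acc_args = list(), eda_args = list(),
                               bvp_args = list()) {
  stopifnot(inherits(rec, "mm_recording"))
  missing_ch <- setdiff(c("ACC", "EDA", "BVP"),
                        unique(unlist(lapply(rec$segments,
                                             function(s) names(s$channels)))))
  if (length(rec$segments) && length(missing_ch))
    stop(sprintf("mandatory channel(s) missing: %s",
                 paste(missing_ch, collapse = ", ")))
  if (length(rec$segments) == 0L) {
    empty <- matrix(numeric(), 0L, 11L, dimnames = list(NULL, feature_names()))
    return(structure(list(participant_id = rec$participant_id,
                          times = numeric(), features = empty,
                          valid = empty == 1),
                     class = "feature_grid"))
  }
  acc <- do.call(acc_feature_series, c(list(rec), acc_args))
  eda <- do.call(eda_feature_series, c(list(rec), eda_args))
  bvp <- do.call(bvp_feature_series, c(list(rec), bvp_args))
  stopifnot(identical(acc$times, eda$times), identical(acc$times, bvp$times))
  features <- cbind(acc$features, eda$features, bvp$features)
  valid <- cbind(acc$valid, eda$valid, bvp$valid)
  stopifnot(identical(colnames(features), feature_names()))
  structure(list(participant_id = rec$participant_id, times = acc$times,
                 features = features, valid = valid),
            class = "feature_grid")
}

#' @export
print.feature_grid <- function(x, ...) {
  cat(sprintf("<feature_grid %s: %d grid points x %d features, %.1f%% valid>\n",
              x$participant_id, length(x$times), ncol(x$features),
              100 * mean(x$valid)))
  invisible(x)
}

#' Binary label series for a feature grid
#'
#' A grid interval `[t, t + 2)` is labeled ictal (1) when it overlaps the
#' closed annotation interval `[onset, offset]` of any seizure.
#'
#' @param annotations A [seizure_annotations()] data frame.
#' @param grid A [build_feature_grid()] result (or any list with `times`).
#' @return Integer vector (0/1) aligned to `grid$times`.
#' @export
make_labels <- function(annotations, grid) {
  t <- grid$times
  labels <- integer(length(t))
  for (i in seq_len(nrow(annotations))) {
    hit <- annotations$onset[i] < t + 2 & annotations$offset[i] >= t
    labels[hit] <- 1L
  }
  labels
}

#' Peri-ictal training rows
#'
#' Training data for the detector are the rows inside the union of the
#' closed peri-ictal spans `[onset - pad_s, offset + pad_s]` of the given
#' seizures, under the same interval-overlap convention as [make_labels()]
#' (so with `pad_s = 0` the training rows are exactly the ictal-labeled
#' rows). Both the row subset and the exact index set are returned so test
#' sets can exclude every training row; `guard_idx` additionally covers a
#' guard band of `guard_s` around the training spans, within which test rows
#' would share feature-window data with training rows.
#'
#' @param grid A `feature_grid`.
#' @param annotations Seizures whose peri-ictal data to extract.
#' @param pad_s Peri-ictal padding in seconds (default 600, i.e. 10 min
#'   before and after).
#' @param guard_s Guard band around training spans excluded from testing.
#' @return List: `train_idx` (integer), `guard_idx` (integer, superset),
#'   `spans` (matrix of padded intervals).
#' @export
extract_periictal <- function(grid, annotations, pad_s = 600, guard_s = 600) {
  t <- grid$times
  n <- length(t)
  in_spans <- function(pad) {
    inside <- logical(n)
    for (i in seq_len(nrow(annotations))) {
      a <- annotations$onset[i] - pad
      b <- annotations$offset[i] + pad
      inside <- inside | (t + 2 > a & t <= b)
    }
    inside
  }
  train <- in_spans(pad_s)
  guard <- in_spans(pad_s + guard_s)
  spans <- cbind(start = annotations$onset - pad_s,
                 end = annotations$offset + pad_s)
  list(train_idx = which(train), guard_idx = which(guard), spans = spans)
}

#' Fit z-score normalization parameters
#'
#' Per-feature centering mean and scaling standard deviation, computed on the
#' training rows only (masked entries ignored). Constant (zero-variance)
#' features are an error: they cannot be standardized and would be useless to
#' the detector.
#'
#' @param x Numeric matrix (rows = grid points, columns = features; `NA` =
#'   masked).
#' @return List of class `norm_params`: `center`, `scale` (named vectors).
#' @export
zscore_fit <- function(x) {
  center <- colMeans(x, na.rm = TRUE)
  scale <- apply(x, 2L, sd, na.rm = TRUE)
  bad <- !is.finite(scale) | scale <= 0
  if (any(bad))
    stop(sprintf("zero-variance or empty feature(s): %s",
                 paste(colnames(x)[bad], collapse = ", ")))
  structure(list(center = center, scale = scale), class = "norm_params")
}

#' Apply stored z-score parameters
#'
#' Standardizes with the stored center/scale - never re-fit on test data.
#' Masked (`NA`) entries are imputed as 0 after standardization, i.e. at the
#' training mean, the least informative value for the tree ensemble.
#'
#' @param params A [zscore_fit()] result.
#' @param x Matrix with the same named columns.
#' @param impute Impute masked entries as 0 after standardization (default
#'   `TRUE`).
#' @return Standardized matrix.
#' @export
zscore_apply <- function(params, x, impute = TRUE) {
  stopifnot(inherits(params, "norm_params"))
  nm <- names(params$center)
  if (!all(nm %in% colnames(x)))
    stop("feature-name mismatch between normalization parameters and data")
  x <- x[, nm, drop = FALSE]
  out <- sweep(sweep(x, 2L, params$center, "-"), 2L, params$scale, "/")
  if (impute) out[!is.finite(out)] <- 0
  out
}

#' Selection criteria for recordings and seizures
#'
#' @param min_recording_hours Minimum hours of recorded data per participant.
#' @param seizure_dur_bounds Inclusive seizure duration bounds in seconds.
#' @param flat_zero_uS,flat_zero_frac EDA flat-line heuristic: flagged when at
#'   least `flat_zero_frac` of peri-ictal EDA lies below `flat_zero_uS`.
#' @param unstable_uS_per_s,unstable_max_epochs EDA instability heuristic:
#'   flagged when more than `unstable_max_epochs` 2-s epochs have an absolute
#'   first difference above `unstable_uS_per_s`.
#' @return List of class `selection_criteria`.
#' @export
selection_criteria <- function(min_recording_hours = 24,
                               seizure_dur_bounds = c(10, 600),
                               flat_zero_uS = 0.01, flat_zero_frac = 0.5,
                               unstable_uS_per_s = 5,
                               unstable_max_epochs = 10) {
  stopifnot(seizure_dur_bounds[1L] > 0,
            seizure_dur_bounds[1L] < seizure_dur_bounds[2L])
  structure(list(min_recording_hours = min_recording_hours,
                 seizure_dur_bounds = seizure_dur_bounds,
                 flat_zero_uS = flat_zero_uS, flat_zero_frac = flat_zero_frac,
                 unstable_uS_per_s = unstable_uS_per_s,
                 unstable_max_epochs = unstable_max_epochs),
            class = "selection_criteria")
}

#' Filter seizures by duration bounds
#'
#' Retains seizures with duration inside the inclusive bounds (default 10 s
#' to 10 min, excluding e.g. myoclonic jerks and status epilepticus).
#'
#' @param annotations A [seizure_annotations()] data frame.
#' @param criteria A [selection_criteria()].
#' @return List: `retained` (annotations), `excluded` (annotations),
#'   `log` (data frame of exclusions with the rule hit).
#' @export
filter_seizures <- function(annotations, criteria = selection_criteria()) {
  dur <- annotations$offset - annotations$onset
  lo <- criteria$seizure_dur_bounds[1L]
  hi <- criteria$seizure_dur_bounds[2L]
  keep <- dur >= lo & dur <= hi
  log <- data.frame(
    item = annotations$seizure_id[!keep],
    rule = ifelse(dur[!keep] < lo, "duration_below_minimum",
                  "duration_above_maximum"),
    stringsAsFactors = FALSE)
  list(retained = annotations[keep, , drop = FALSE],
       excluded = annotations[!keep, , drop = FALSE], log = log)
}

#' Filter recordings by minimum recorded hours
#'
#' @param recordings List of [recording()]s.
#' @inheritParams filter_seizures
#' @return List: `retained`, `excluded` (lists of recordings), `log`.
#' @export
filter_recordings <- function(recordings, criteria = selection_criteria()) {
  hrs <- vapply(recordings, recording_hours, 0)
  keep <- hrs >= criteria$min_recording_hours
  log <- data.frame(
    item = vapply(recordings[!keep], function(r) r$participant_id, ""),
    rule = rep("recording_below_minimum_hours", sum(!keep)),
    stringsAsFactors = FALSE)
  list(retained = recordings[keep], excluded = recordings[!keep], log = log)
}

#' Peri-ictal EDA quality heuristics
#'
#' Numeric operationalization of the visual screen for unusable electrodermal
#' data around a seizure: `flat_zero` when at least half of the peri-ictal
#' EDA is below 0.01 microsiemens (electrode contact loss), `unstable` when
#' more than 10 of the 2-s epochs in the span have an absolute first
#' difference above 5 microsiemens/s (loose device). Thresholds are
#' configurable through [selection_criteria()]; the flags approximate a visual
#' check and are reported, not hard exclusions.
#'
#' @param rec A [recording()].
#' @param seizure One-row annotation data frame (or list with
#'   `onset`/`offset`).
#' @param pad_s Peri-ictal span padding (s).
#' @param criteria A [selection_criteria()].
#' @return List: `flat_zero`, `unstable` (logicals).
#' @export
eda_quality_flags <- function(rec, seizure, pad_s = 600,
                              criteria = selection_criteria()) {
  a <- seizure$onset - pad_s
  b <- seizure$offset + pad_s
  vals <- list()
  for (seg in rec$segments) {
    ch <- seg$channels$EDA
    if (is.null(ch)) next
    fs <- ch$sample_rate
    t0 <- max(a, seg$start_time)
    t1 <- min(b, .segment_end(seg))
    if (t1 <= t0) next
    i0 <- as.integer(floor((t0 - seg$start_time) * fs)) + 1L
    i1 <- min(.channel_n(ch), as.integer(ceiling((t1 - seg$start_time) * fs)))
    if (i1 >= i0) vals[[length(vals) + 1L]] <- list(x = ch$samples[i0:i1], fs = fs)
  }
  if (!length(vals)) return(list(flat_zero = TRUE, unstable = FALSE))
  x_all <- unlist(lapply(vals, `[[`, "x"))
  flat <- mean(x_all < criteria$flat_zero_uS) >= criteria$flat_zero_frac
  n_fast <- 0L
  for (v in vals) {
    bs <- as.integer(2 * v$fs)
    nb <- length(v$x) %/% bs
    if (nb < 1L) next
    epoch_rate <- vapply(seq_len(nb), function(k) {
      w <- v$x[((k - 1L) * bs + 1L):(k * bs)]
      max(abs(diff(w))) * v$fs
    }, 0)
    n_fast <- n_fast + sum(epoch_rate > criteria$unstable_uS_per_s)
  }
  list(flat_zero = flat, unstable = n_fast > criteria$unstable_max_epochs)
}
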