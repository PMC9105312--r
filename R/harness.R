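# Cross-validation harnesses. Intra-subject: leave-one-seizure-out per
# participant - train on the peri-ictal data of all other seizures, test on
# the full remaining recording (including the left-out seizure, excluding
# every training row and a guard band around it). Inter-subject: grid search
# in a leave-one-participant-out loop over the training cohort, then one
# final model trained on all training-cohort peri-ictal data and applied to
# the complete recordings of the held-out test cohort.

#' Prepare a participant for evaluation
#'
#' Computes the feature grid and label series once and keeps the lightweight
#' bookkeeping (segment intervals, hours, local-time offset) needed by the
#' harnesses, so raw signals can be released.
#'
#' @param rec A [recording()].
#' @param annotations A [seizure_annotations()] data frame.
#' @param criteria A [selection_criteria()] used to pre-filter seizures.
#' @param ... Passed to [build_feature_grid()].
#' @return List of class `participant_dataset`.
#' @export
prepare_participant <- function(rec, annotations,
                                criteria = selection_criteria(), ...) {
  grid <- build_feature_grid(rec, ...)
  fs <- filter_seizures(annotations, criteria)
  structure(list(
    participant_id = rec$participant_id,
    grid = grid,
    labels = make_labels(annotations, grid),
    annotations = annotations,
    seizures = fs$retained,
    exclusion_log = fs$log,
    hours = recording_hours(rec),
    segments = cbind(start = vapply(rec$segments, function(s) s$start_time, 0),
                     end = vapply(rec$segments, .segment_end, 0)),
    utc_offset_hours = rec$utc_offset_hours), class = "participant_dataset")
}

#' @export
print.participant_dataset <- function(x, ...) {
  cat(sprintf("<participant_dataset %s: %.1f h, %d grid rows, %d/%d seizures retained>\n",
              x$participant_id, x$hours, length(x$grid$times),
              nrow(x$seizures), nrow(x$annotations)))
  invisible(x)
}

# chunks of a time vector as an interval matrix (for nightly bookkeeping)
.chunk_intervals <- function(times) {
  ch <- .contiguous_chunks(times)
  if (!length(ch)) return(matrix(numeric(), 0L, 2L))
  do.call(rbind, lapply(ch, function(idx)
    c(times[idx[1L]], times[idx[length(idx)]] + 2)))
}

# assemble one LOSO fold for a participant
.intra_fold <- function(pd, leave_out, pad_s, guard_s) {
  train_ann <- pd$seizures[-leave_out, , drop = FALSE]
  pi <- extract_periictal(pd$grid, train_ann, pad_s = pad_s,
                          guard_s = guard_s)
  train_idx <- pi$train_idx
  test_idx <- setdiff(seq_along(pd$grid$times), pi$guard_idx)
  stopifnot(length(intersect(train_idx, test_idx)) == 0L)
  test_times <- pd$grid$times[test_idx]
  list(x_train = pd$grid$features[train_idx, , drop = FALSE],
       y_train = pd$labels[train_idx],
       x_test = pd$grid$features[test_idx, , drop = FALSE],
       test_times = test_times,
       truth = annotation_events(pd$seizures[leave_out, , drop = FALSE]),
       hours = length(test_idx) * 2 / 3600,
       night = list(segments = .chunk_intervals(test_times),
                    utc_offset_hours = pd$utc_offset_hours),
       train_idx = train_idx, test_idx = test_idx)
}

#' Intra-subject leave-one-seizure-out evaluation
#'
#' For each retained seizure: train the detector on the peri-ictal data
#' (10 min before to 10 min after) of all the other seizures, test on the
#' complete remaining recording. The hyperparameter grid search is flat: each
#' combination is scored as its mean sensitivity / false-positive count over
#' all folds, and the winner (tie-break rules of [grid_search()])
#' supplies the reported per-fold scores.
#'
#' @param pd A [prepare_participant()] result.
#' @param grid Hyperparameter grid (list of [gtbm_params()]).
#' @param min_seizures Minimum retained seizures required (default 3).
#' @param pad_s Peri-ictal padding (s).
#' @param guard_s Guard band around training spans excluded from testing (s).
#' @param margin_s Event-matching margin (s).
#' @return List of class `intra_subject_result`: `participant_id`, `best`,
#'   `fold_reports`, `aggregate` (mean/pooled sensitivity, mean FP, FAR24
#'   under both aggregations, FARn), `score_table`, `importance`.
#' @export
run_intra_subject <- function(pd, grid = param_grid_reduced(),
                              min_seizures = 3, pad_s = 600, guard_s = 600,
                              margin_s = 120) {
  ns <- nrow(pd$seizures)
  if (ns < min_seizures)
    stop(sprintf("participant %s has %d retained seizure(s); at least %d required",
                 pd$participant_id, ns, min_seizures))
  folds <- lapply(seq_len(ns), .intra_fold, pd = pd, pad_s = pad_s,
                  guard_s = guard_s)
  gs <- grid_search(folds, grid, margin_s = margin_s)
  reports <- gs$fold_scores[[gs$best_index]]

  # per-fold models of the winning combination, for feature importance
  bundles <- lapply(folds, function(f)
    fit_detector(f$x_train, f$y_train, gs$best))

  structure(list(
    participant_id = pd$participant_id,
    best = gs$best,
    fold_reports = reports,
    aggregate = .aggregate_reports(reports),
    score_table = gs$table,
    importance = importance(bundles)), class = "intra_subject_result")
}

.aggregate_reports <- function(reports) {
  tp <- sum(vapply(reports, `[[`, 0, "tp"))
  fn <- sum(vapply(reports, `[[`, 0, "fn"))
  sens <- vapply(reports, `[[`, 0, "sensitivity")
  fps <- vapply(reports, `[[`, 0, "fp")
  f24 <- vapply(reports, `[[`, 0, "far24")
  hrs <- vapply(reports, `[[`, 0, "recording_hours")
  fnr <- vapply(reports, `[[`, 0, "farn")
  list(pooled_sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       mean_sensitivity = mean(sens, na.rm = TRUE),
       mean_fp = mean(fps),
       mean_far24 = mean(f24),                      # mean of per-fold rates
       far24_from_mean_fp = far24(mean(fps), mean(hrs)),  # rate of mean counts
       mean_farn = if (all(is.na(fnr))) NA_real_ else mean(fnr, na.rm = TRUE),
       total_tp = tp, total_fn = fn)
}

# pooled peri-ictal training rows over a list of participant datasets
.pooled_training <- function(pds, pad_s, guard_s) {
  xs <- list(); ys <- list()
  for (pd in pds) {
    pi <- extract_periictal(pd$grid, pd$seizures, pad_s = pad_s,
                            guard_s = guard_s)
    xs[[length(xs) + 1L]] <- pd$grid$features[pi$train_idx, , drop = FALSE]
    ys[[length(ys) + 1L]] <- pd$labels[pi$train_idx]
  }
  list(x = do.call(rbind, xs), y = do.call(c, ys))
}

.full_test_fold <- function(pd) {
  list(x_test = pd$grid$features,
       test_times = pd$grid$times,
       truth = annotation_events(pd$seizures),
       hours = pd$hours,
       night = list(segments = pd$segments,
                    utc_offset_hours = pd$utc_offset_hours))
}

#' Inter-subject leave-one-participant-out evaluation
#'
#' Grid search by leave-one-participant-out over the training cohort: per
#' fold the detector is trained on the pooled peri-ictal data of the other
#' training participants and validated on the held-out participant's complete
#' recording; mean scores across folds select the winning combination. The
#' final model is trained on all training-cohort peri-ictal data with the
#' winning parameters and applied to every test participant's complete
#' recording (out-of-sample).
#'
#' @param train_pds List of [prepare_participant()] results (>= 2).
#' @param test_pds List of [prepare_participant()] results, disjoint from
#'   `train_pds`.
#' @param grid Hyperparameter grid.
#' @param pad_s,guard_s,margin_s See [run_intra_subject()].
#' @return List of class `inter_subject_result`: `best`, `lopo_reports`,
#'   `lopo_aggregate`, `test_reports` (per test participant),
#'   `test_aggregate` (pooled = total TP / total seizures, and mean-of-
#'   participants), `score_table`, `final_bundle`, `importance`.
#' @export
run_inter_subject <- function(train_pds, test_pds,
                              grid = param_grid_reduced(), pad_s = 600,
                              guard_s = 600, margin_s = 120) {
  stopifnot(length(train_pds) >= 2L)
  train_ids <- vapply(train_pds, `[[`, "", "participant_id")
  test_ids <- vapply(test_pds, `[[`, "", "participant_id")
  if (length(intersect(train_ids, test_ids)))
    stop(sprintf("cohorts overlap: %s",
                 paste(intersect(train_ids, test_ids), collapse = ", ")))

  folds <- lapply(seq_along(train_pds), function(v) {
    tr <- .pooled_training(train_pds[-v], pad_s, guard_s)
    c(list(x_train = tr$x, y_train = tr$y), .full_test_fold(train_pds[[v]]))
  })
  gs <- grid_search(folds, grid, margin_s = margin_s)

  tr_all <- .pooled_training(train_pds, pad_s, guard_s)
  final <- fit_detector(tr_all$x, tr_all$y, gs$best)

  test_reports <- lapply(test_pds, function(pd) {
    f <- .full_test_fold(pd)
    pred <- predict(final, f$x_test)
    score_prediction(pred, f$test_times, f$truth,
                     recording_hours = f$hours, margin_s = margin_s,
                     night = f$night)
  })
  names(test_reports) <- test_ids

  structure(list(
    best = gs$best,
    lopo_reports = setNames(gs$fold_scores[[gs$best_index]], train_ids),
    lopo_aggregate = .aggregate_reports(gs$fold_scores[[gs$best_index]]),
    test_reports = test_reports,
    test_aggregate = .aggregate_reports(test_reports),
    score_table = gs$table,
    final_bundle = final,
    importance = importance(final)), class = "inter_subject_result")
}
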