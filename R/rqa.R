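# Recurrence quantification of 3-axis accelerometry. A 10-s window of 3-axis
# samples is treated as a trajectory of 3-D state vectors; the recurrence
# plot thresholds all pairwise Euclidean distances at a radius, and four
# measures summarize its diagonal-line structure: recurrence rate (density of
# recurrent points), determinism (fraction of recurrent points on diagonal
# lines of at least a minimal length), average diagonal line length, and the
# Shannon entropy of the diagonal line-length distribution. Rhythmic (clonic)
# or sustained (tonic) ictal movement produces long diagonals; unstructured
# movement does not.

#' Recurrence plot of a 3-axis window
#'
#' Entry (i, j) is 1 iff the Euclidean distance between state vectors i and j
#' is at most the radius. The state space is the raw 3-axis frame (no
#' time-delay embedding); the radius is adaptive per window, a fraction of the
#' window's maximum pairwise distance, unless `fixed_radius` is given.
#'
#' @param window n x 3 numeric matrix of accelerometry samples (g).
#' @param radius_fraction Radius as a fraction of the maximum pairwise
#'   distance in the window, in (0, 1].
#' @param fixed_radius Optional absolute radius (g); overrides
#'   `radius_fraction` when positive.
#' @return Object of class `recurrence_plot`: list with `matrix` (n x n
#'   logical, symmetric, unit diagonal), `radius`, `window_span` (seconds,
#'   assuming 32 Hz).
#' @export
recurrence_matrix <- function(window, radius_fraction = 0.1,
                              fixed_radius = NULL) {
  window <- as.matrix(window)
  stopifnot(ncol(window) == 3L, nrow(window) >= 1L)
  if (is.null(fixed_radius)) {
    stopifnot(radius_fraction > 0, radius_fraction <= 1)
  }
  d <- as.matrix(stats::dist(window))
  radius <- if (!is.null(fixed_radius) && fixed_radius > 0) fixed_radius
            else radius_fraction * max(d)
  structure(list(matrix = d <= radius, radius = radius,
                 window_span = nrow(window) / 32),
            class = "recurrence_plot")
}

#' Recurrence quantification measures
#'
#' Computes recurrence rate (RR), determinism (DET), average diagonal line
#' length (L) and diagonal line-length Shannon entropy (ENTR, nats) from a
#' recurrence plot. The line of identity is excluded: RR has denominator
#' n^2 - n, and diagonal lines are scanned off the main diagonal only. With no
#' recurrent points, RR = 0, DET = 0, ENTR = 0 and L is `NA` (the
#' undefined-length sentinel); the same degenerate L/ENTR values apply when no
#' line reaches `l_min`.
#'
#' @param rp A [recurrence_matrix()] result, or a square logical/0-1 matrix.
#' @param l_min Minimal diagonal line length in samples (default 2).
#' @return List of class `rqa_measures`: `rr`, `det`, `avg_len`, `entr`.
#' @export
rqa <- function(rp, l_min = 2) {
  m <- if (inherits(rp, "recurrence_plot")) rp$matrix else rp
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), nrow(m) >= 2L, l_min >= 1L)
  v <- .rqa_from_binary(matrix(as.logical(m), nrow(m)), as.integer(l_min))
  structure(list(rr = v[["rr"]], det = v[["det"]],
                 avg_len = v[["avg_len"]], entr = v[["entr"]]),
            class = "rqa_measures")
}

#' @export
print.rqa_measures <- function(x, ...) {
  cat(sprintf("<rqa: RR %.3f, DET %.3f, L %s, ENTR %.3f>\n", x$rr, x$det,
              ifelse(is.na(x$avg_len), "NA", sprintf("%.2f", x$avg_len)),
              x$entr))
  invisible(x)
}

# RQA features of one segment's ACC channel on the 2-s grid.
# grid_offsets: grid times relative to the segment start (seconds).
# Windows are [t - window_s/2, t + window_s/2]; grid points whose window is
# not fully inside the segment are masked (within a contiguous segment this
# is equivalent to requiring full coverage; the tolerance for windows
# clipped by segment edges is `coverage`).
.acc_features_segment <- function(acc, grid_offsets, window_s = 10,
                                  radius_fraction = 0.1, fixed_radius = NULL,
                                  l_min = 2, coverage = 0.95) {
  fs <- acc$sample_rate
  n <- nrow(acc$samples)
  half <- window_s / 2
  lo <- pmax(grid_offsets - half, 0)
  hi <- pmin(grid_offsets + half, n / fs)
  cov <- (hi - lo) / window_s
  valid <- cov >= coverage
  i0 <- pmax(1L, as.integer(floor(lo * fs)) + 1L)
  i1 <- pmin(n, as.integer(ceiling(hi * fs)))
  i0v <- ifelse(valid, i0, 1L)
  i1v <- ifelse(valid, i1, 0L)  # empty window -> NA row from C++
  res <- .rqa_series(acc$samples, i0v, i1v,
                     radius_fraction,
                     if (is.null(fixed_radius)) -1 else fixed_radius,
                     as.integer(l_min))
  out <- cbind(f_acc_det = res[, "det"], f_acc_entr = res[, "entr"],
               f_acc_len = res[, "avg_len"], f_acc_rr = res[, "rr"])
  out[!valid, ] <- NA_real_
  # L carries an NA sentinel in windows with no line >= l_min; that column's
  # validity is per-entry, the other three follow the coverage rule
  vmat <- matrix(valid, length(valid), 4L)
  vmat[, 3L] <- valid & is.finite(out[, "f_acc_len"])
  colnames(vmat) <- colnames(out)
  list(features = out, valid = vmat)
}

#' Accelerometry recurrence features on the 2-s grid
#'
#' For each grid point t the four RQA measures are computed from the 10-s ACC
#' window centered at t. Grid points whose window extends past a segment edge
#' (i.e., into a recording gap) are masked.
#'
#' @param rec A [recording()].
#' @param window_s Window length in seconds (default 10).
#' @inheritParams recurrence_matrix
#' @param l_min Minimal diagonal line length (samples).
#' @return List with `times`, `features` (n x 4 matrix), `valid` (n x 4
#'   logical).
#' @export
acc_feature_series <- function(rec, window_s = 10, radius_fraction = 0.1,
                               fixed_radius = NULL, l_min = 2) {
  per_seg <- lapply(rec$segments, function(seg) {
    offs <- .grid_offsets(seg)
    r <- .acc_features_segment(seg$channels$ACC, offs, window_s,
                               radius_fraction, fixed_radius, l_min)
    list(times = seg$start_time + offs, features = r$features,
         valid = r$valid)
  })
  .bind_feature_chunks(per_seg)
}

# grid offsets (seconds from segment start) of intervals [t, t+2) fully
# inside the segment
.grid_offsets <- function(seg, step = 2) {
  k <- floor(seg$duration / step)
  if (k < 1) return(numeric())
  seq(0, by = step, length.out = k)
}

.bind_feature_chunks <- function(per_seg) {
  list(times = do.call(c, lapply(per_seg, `[[`, "times")),
       features = do.call(rbind, lapply(per_seg, `[[`, "features")),
       valid = do.call(rbind, lapply(per_seg, `[[`, "valid")))
}
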