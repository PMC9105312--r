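# Electrodermal activity features. The skin conductance level (SCL) is the
# raw EDA smoothed by a centered 60-s moving mean; the skin conductance
# response rate (SCRR) counts upward crossings of a derivative threshold on
# the smoothed signal. Each feature is the value over the trailing 5-min
# feature window minus the same value over the 5 minutes before it (the
# baseline window), which removes the tonic level and isolates peri-ictal
# electrodermal responses.

#' Skin conductance level: centered moving mean
#'
#' 60-s centered moving mean of the raw EDA stream; the window shrinks at the
#' segment edges (edge-truncated mean), so a constant input maps to itself
#' everywhere.
#'
#' @param eda Numeric vector, EDA samples in microsiemens.
#' @param fs Sample rate (Hz), device default 4.
#' @param window_s Smoothing window in seconds (default 60).
#' @return Numeric vector, same length as `eda`.
#' @export
scl <- function(eda, fs = 4, window_s = 60) {
  n <- length(eda)
  if (n == 0L) return(numeric())
  w <- round(window_s * fs)          # even order: 240 samples at 4 Hz
  half <- w %/% 2
  cs <- cumsum(c(0, eda))
  i <- seq_len(n)
  out <- numeric(n)
  interior <- i > half & i + half <= n
  ii <- i[interior]
  # centered moving average of even order w: the two edge samples of the
  # (w + 1)-point window get half weight, so a linear ramp maps to itself
  # and a unit impulse gives an interior plateau of exactly 1/w
  out[interior] <- (cs[ii + half + 1L] - cs[ii - half] -
                      0.5 * (eda[ii - half] + eda[ii + half])) / w
  # edges: plain truncated mean (window shrinks)
  edge <- which(!interior)
  if (length(edge)) {
    lo <- pmax(edge - half, 1L)
    hi <- pmin(edge + half, n)
    out[edge] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Skin conductance response rate
#'
#' Counts upward crossings of `+threshold` by the first derivative (micro-
#' siemens per second) of the smoothed EDA signal within the window: the
#' number of transitions from a sub-threshold to a supra-threshold slope.
#'
#' @param scl_window Smoothed (SCL) samples of the window.
#' @param fs Sample rate (Hz).
#' @param threshold Derivative threshold in microsiemens/s (default 0.01).
#' @return Integer count of threshold crossings.
#' @export
scrr <- function(scl_window, fs = 4, threshold = 0.01) {
  if (length(scl_window) < 2L) return(0L)
  d <- diff(scl_window) * fs
  up <- d > threshold
  sum(up & !c(FALSE, up[-length(up)]))
}

# trailing-window EDA features of one segment on the 2-s grid.
# Feature window [t-300, t], baseline window [t-600, t-300]; grid points
# earlier than 600 s into the segment are masked (incomplete baseline).
.eda_features_segment <- function(eda_ch, grid_offsets, window_s = 300,
                                  fs = NULL, threshold = 0.01,
                                  baseline_after = FALSE) {
  fs <- if (is.null(fs)) eda_ch$sample_rate else fs
  x <- scl(eda_ch$samples, fs = fs)
  n <- length(x)
  ng <- length(grid_offsets)
  out <- matrix(NA_real_, ng, 3L,
                dimnames = list(NULL, c("f_eda_dauc", "f_eda_dmax",
                                        "f_eda_dscrr")))
  if (ng == 0L)
    return(list(features = out, valid = matrix(logical(), 0L, 3L)))

  # per-window statistics at 2-s block resolution: windows are multiples of
  # the 2-s grid step, so block-wise prefix structures give exact results
  step <- 2
  wsteps <- window_s / step           # 150 blocks per window
  bs <- as.integer(fs * step)         # samples per block
  nb <- n %/% bs

  # trapezoidal AUC prefix (spacing 1/fs, units uS*s)
  auc_cum <- c(0, cumsum((x[-1L] + x[-n]) / (2 * fs)))
  # block maxima
  bmax <- if (nb > 0)
    vapply(seq_len(nb), function(b) max(x[((b - 1L) * bs + 1L):(b * bs)]), 0)
  else numeric()
  # upward crossing indicator per sample, then per-block counts
  d <- diff(x) * fs
  up <- d > threshold
  cross <- up & !c(FALSE, up[-length(up)])
  cross_cum <- c(0, cumsum(cross))

  gi <- as.integer(round(grid_offsets / step))   # grid index 0-based
  # the baseline window must be complete; the extra step keeps the earliest
  # baseline window clear of the segment's first sample (whose leading
  # trapezoid does not exist), preserving exact offset invariance
  valid <- grid_offsets >= 2 * window_s + step & (gi * bs) <= n

  # windows span blocks (b0, b1], i.e. samples (b0*bs, b1*bs]; prefix sums
  # are over sample index, so the integral / count over samples a..b is
  # prefix[b] - prefix[a]
  f_auc <- function(b0, b1)
    auc_cum[pmin(b1 * bs, n)] - auc_cum[pmax(b0 * bs, 1L)]
  w_max <- function(b_end)     # max over the wsteps blocks ending at b_end
    vapply(b_end, function(b) max(bmax[(b - wsteps + 1L):b]), 0)
  f_cross <- function(b0, b1)
    cross_cum[pmin(b1 * bs, n)] - cross_cum[pmax(b0 * bs, 1L)]

  vg <- which(valid)
  if (length(vg)) {
    b_t <- gi[vg]                      # block id of grid time t
    b_f0 <- b_t - wsteps               # feature window blocks (b_f0, b_t]
    b_b0 <- b_t - 2L * wsteps          # baseline window blocks (b_b0, b_f0]
    auc_f <- f_auc(b_f0, b_t);  auc_b <- f_auc(b_b0, b_f0)
    max_f <- w_max(b_t);        max_b <- w_max(b_f0)
    scr_f <- f_cross(b_f0, b_t); scr_b <- f_cross(b_b0, b_f0)
    sgn <- if (baseline_after) -1 else 1
    out[vg, 1L] <- sgn * (auc_f - auc_b)
    out[vg, 2L] <- sgn * (max_f - max_b)
    out[vg, 3L] <- sgn * (scr_f - scr_b)
  }
  list(features = out, valid = matrix(valid, ng, 3L,
                                      dimnames = list(NULL, colnames(out))))
}

#' Electrodermal features on the 2-s grid
#'
#' Per grid point t, with feature window `[t-300, t]` and baseline window
#' `[t-600, t-300]`: difference in SCL area under the curve (trapezoidal),
#' difference in SCL maximum, and difference in SCR rate. All three are
#' invariant to a constant offset of the EDA stream. Grid points with an
#' incomplete baseline window (less than 600 s into a segment) are masked.
#'
#' @param rec A [recording()].
#' @param window_s Feature/baseline window length in seconds (default 300).
#' @param threshold SCRR derivative threshold (microsiemens/s).
#' @param baseline_after If `TRUE`, swap the roles of the two windows (the
#'   feature value is then computed against the window after it).
#' @return List with `times`, `features` (n x 3), `valid` (n x 3 logical).
#' @export
eda_feature_series <- function(rec, window_s = 300, threshold = 0.01,
                               baseline_after = FALSE) {
  per_seg <- lapply(rec$segments, function(seg) {
    offs <- .grid_offsets(seg)
    r <- .eda_features_segment(seg$channels$EDA, offs, window_s,
                               threshold = threshold,
                               baseline_after = baseline_after)
    list(times = seg$start_time + offs, features = r$features,
         valid = r$valid)
  })
  .bind_feature_chunks(per_seg)
}
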