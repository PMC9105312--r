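# Blood volume pulse processing: trough-based beat detection, a filtered
# heart-rate estimate on the 2-s grid, and a spectral-entropy signal quality
# index (SQI). The BVP waveform dips at each systolic inflow, so beats are
# local minima with a minimum separation (refractory period) and a depth gate
# relative to the local signal amplitude. The SQI is the normalized Shannon
# entropy of the in-band power spectrum of a 10-s window: a clean pulse
# concentrates power at the heart rate and its harmonics (entropy near 0),
# motion artifact spreads it broadband (entropy near 1). Artifact is treated
# as information - the SQI is itself a feature - rather than grounds for
# discarding data.

#' Detect beats in a BVP stream
#'
#' Local minima of the raw series, gated by depth relative to the local
#' peak-to-peak amplitude (estimated over `amp_window_s` blocks) and a
#' refractory separation of `min_separation_s` (0.33 s, i.e. 180 bpm).
#' A flat signal yields an empty beat series.
#'
#' @param bvp Numeric vector of BVP samples or a `ts_channel`.
#' @param fs Sample rate (Hz), device default 64; ignored when `bvp` is a
#'   channel.
#' @param start_time Epoch seconds of the first sample (0 for plain vectors).
#' @param min_separation_s Minimum inter-beat separation (s).
#' @param prominence_fraction Depth gate: a trough must lie below the local
#'   mean by at least this fraction of the local amplitude.
#' @param amp_window_s Block length for the local amplitude estimate (s).
#' @return List of class `beat_series`: `beat_times` (epoch s), `ibis` (s).
#' @export
detect_beats <- function(bvp, fs = 64, start_time = 0,
                         min_separation_s = 0.33,
                         prominence_fraction = 0.25, amp_window_s = 2) {
  if (inherits(bvp, "ts_channel")) {
    fs <- bvp$sample_rate; start_time <- bvp$start_time
    bvp <- bvp$samples
  }
  n <- length(bvp)
  empty <- structure(list(beat_times = numeric(), ibis = numeric()),
                     class = "beat_series")
  if (n < 3L) return(empty)

  # block-wise local amplitude / mean, smoothed over 3 blocks
  bs <- max(1L, as.integer(fs * amp_window_s))
  nb <- max(1L, ceiling(n / bs))
  bidx <- pmin(rep(seq_len(nb), each = bs)[seq_len(n)], nb)
  bmin <- tapply(bvp, bidx, min)
  bmax <- tapply(bvp, bidx, max)
  bmean <- tapply(bvp, bidx, mean)
  sm3 <- function(v) {
    nb <- length(v)
    if (nb < 3L) return(v)
    (v + c(v[1L], v[-nb]) + c(v[-1L], v[nb])) / 3
  }
  amp <- sm3(as.numeric(bmax - bmin))
  mid <- sm3(as.numeric(bmean))

  # strict local minima over a +/-2 sample neighborhood
  i <- 3:(n - 2L)
  is_min <- bvp[i] < bvp[i - 1L] & bvp[i] <= bvp[i + 1L] &
            bvp[i] < bvp[i - 2L] & bvp[i] <= bvp[i + 2L]
  cand <- i[is_min]
  if (!length(cand)) return(empty)
  b <- bidx[cand]
  deep <- bvp[cand] < mid[b] - prominence_fraction * amp[b] / 2 & amp[b] > 0
  cand <- cand[deep]
  if (!length(cand)) return(empty)

  # refractory: greedy acceptance in time order
  min_gap <- min_separation_s * fs
  keep <- logical(length(cand))
  last <- -Inf
  for (k in seq_along(cand)) {
    if (cand[k] - last >= min_gap) {
      keep[k] <- TRUE
      last <- cand[k]
    }
  }
  bt <- start_time + (cand[keep] - 1L) / fs
  structure(list(beat_times = bt, ibis = diff(bt)), class = "beat_series")
}

#' Heart-rate estimate on the 2-s grid
#'
#' Instantaneous HR = 60 / IBI, assigned at the midpoint of each inter-beat
#' interval, after a filter cascade: IBIs outside `[0.33, 2]` s are discarded
#' (plausibility: 30-180 bpm), IBIs deviating more than 25% from the running
#' 5-beat median are discarded (artifact gate), the HR sequence is median
#' filtered over 5 beats, and the result is linearly interpolated to the 2-s
#' grid. Grid points farther than `validity_horizon_s` from any retained beat
#' are invalid.
#'
#' @param beats A [detect_beats()] result.
#' @param grid_times Epoch seconds of the 2-s grid.
#' @param ibi_range Plausible IBI bounds (s).
#' @param median_gate Maximum relative deviation from the running median.
#' @param median_filter Width (beats) of the HR median filter.
#' @param validity_horizon_s Maximum distance to a retained beat (s).
#' @return List of class `hr_estimate`: `hr` (bpm), `valid` (logical), both
#'   aligned to `grid_times`.
#' @export
hr_estimate <- function(beats, grid_times, ibi_range = c(0.33, 2),
                        median_gate = 0.25, median_filter = 5,
                        validity_horizon_s = 10) {
  ng <- length(grid_times)
  out <- list(hr = rep(NA_real_, ng), valid = rep(FALSE, ng))
  class(out) <- "hr_estimate"
  ibis <- beats$ibis
  if (length(ibis) < 1L) return(out)
  mids <- (beats$beat_times[-1L] + beats$beat_times[-length(beats$beat_times)]) / 2

  ok <- ibis >= ibi_range[1L] & ibis <= ibi_range[2L]
  ibis <- ibis[ok]; mids <- mids[ok]
  if (length(ibis) >= 3L) {
    med <- runmed(ibis, k = min(median_filter, length(ibis) - !(length(ibis) %% 2)))
    ok2 <- abs(ibis - med) <= median_gate * med
    ibis <- ibis[ok2]; mids <- mids[ok2]
  }
  if (!length(ibis)) return(out)
  hr <- 60 / ibis
  if (length(hr) >= 3L)
    hr <- runmed(hr, k = min(median_filter, length(hr) - !(length(hr) %% 2)))

  if (length(hr) == 1L) {
    out$hr <- rep(hr, ng)
  } else {
    out$hr <- approx(mids, hr, xout = grid_times, rule = 2)$y
  }
  # validity: distance to nearest retained beat midpoint
  nearest <- findInterval(grid_times, mids)
  d_lo <- ifelse(nearest >= 1L, grid_times - mids[pmax(nearest, 1L)], Inf)
  d_hi <- ifelse(nearest < length(mids), mids[pmin(nearest + 1L, length(mids))] - grid_times, Inf)
  out$valid <- pmin(d_lo, d_hi) <= validity_horizon_s
  out$hr[!out$valid] <- NA_real_
  out
}

#' Spectral-entropy signal quality index of a BVP window
#'
#' Normalized Shannon entropy of the periodogram restricted to the cardiac
#' band 0.5-5 Hz: `H = -sum(p_k log p_k) / log K` with `p_k` the normalized
#' in-band power. Low values indicate a clean periodic pulse; broadband motion
#' artifact drives the value toward 1. An all-zero (powerless) window maps to
#' the degenerate value 1: it carries no evidence of signal quality.
#'
#' @param window Numeric vector, one 10-s BVP window.
#' @param fs Sample rate (Hz).
#' @param band Frequency band (Hz) over which entropy is computed.
#' @return Value in `[0, 1]`.
#' @export
spectral_entropy_sqi <- function(window, fs = 64, band = c(0.5, 5)) {
  n <- length(window)
  if (n < 8L) return(1)
  spec <- Mod(fft(window - mean(window)))^2
  freq <- (seq_len(n) - 1L) * fs / n
  k <- which(freq >= band[1L] & freq <= band[2L])
  p <- spec[k]
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) return(1)
  p <- p / tot
  p <- p[p > 0]
  h <- -sum(p * log(p)) / log(length(k))
  min(max(h, 0), 1)
}

# SQI series of one segment on the 2-s grid (vectorized over windows)
.sqi_segment <- function(bvp, fs, grid_offsets, window_s = 10,
                         band = c(0.5, 5), coverage = 0.95) {
  n <- length(bvp)
  half <- window_s / 2
  lo <- pmax(grid_offsets - half, 0)
  hi <- pmin(grid_offsets + half, n / fs)
  valid <- (hi - lo) / window_s >= coverage
  out <- rep(NA_real_, length(grid_offsets))
  wlen <- as.integer(window_s * fs)
  freq <- (seq_len(wlen) - 1L) * fs / wlen
  kband <- which(freq >= band[1L] & freq <= band[2L])
  logK <- log(length(kband))
  for (g in which(valid)) {
    a <- as.integer(floor(lo[g] * fs)) + 1L
    b <- min(n, a + wlen - 1L)
    w <- bvp[a:b]
    spec <- Mod(fft(w - mean(w)))^2
    p <- spec[kband]
    tot <- sum(p)
    out[g] <- if (!is.finite(tot) || tot <= 0) 1 else {
      p <- p / tot; p <- p[p > 0]
      min(max(-sum(p * log(p)) / logK, 0), 1)
    }
  }
  list(sqi = out, valid = valid)
}

#' Blood-volume-pulse features on the 2-s grid
#'
#' Per grid point t: `f_bvp_dmaxhr` = max HR over `[t-60, t]` minus max HR
#' over `[t-120, t-60]`; `f_bvp_dmeanhr` analogous with means; `f_bvp_sqi`
#' the spectral-entropy quality index of the 10-s window at t; `f_bvp_hr` the
#' HR estimate at t. The differenced HR features are masked when more than
#' half of either 60-s window has no valid HR; the point features follow
#' their own validity (SQI: window coverage; HR: the estimate's horizon).
#'
#' @param rec A [recording()].
#' @param ... Passed to [detect_beats()].
#' @return List with `times`, `features` (n x 4), `valid` (n x 4 logical).
#' @export
bvp_feature_series <- function(rec, ...) {
  per_seg <- lapply(rec$segments, function(seg) {
    ch <- seg$channels$BVP
    offs <- .grid_offsets(seg)
    times <- seg$start_time + offs
    ng <- length(offs)

    beats <- detect_beats(ch, ...)
    hre <- hr_estimate(beats, times)
    sqi <- .sqi_segment(ch$samples, ch$sample_rate, offs)

    wsteps <- 30L  # 60 s of 2-s grid steps
    hr <- hre$hr
    roll_stat <- function(f) {
      vapply(seq_len(ng), function(i) {
        if (i < 1L) return(NA_real_)
        a <- max(1L, i - wsteps + 1L)
        v <- hr[a:i]
        v <- v[is.finite(v)]
        if (!length(v)) NA_real_ else f(v)
      }, 0)
    }
    # validity of the differenced features: >=50% valid HR in both windows,
    # and both windows fully inside the segment
    vfrac <- vapply(seq_len(ng), function(i) {
      a <- max(1L, i - wsteps + 1L)
      mean(hre$valid[a:i])
    }, 0)
    rmax <- roll_stat(max); rmean <- roll_stat(mean)
    lag <- function(v) c(rep(NA_real_, wsteps), v[seq_len(ng - wsteps)])
    d_max <- rmax - lag(rmax)
    d_mean <- rmean - lag(rmean)
    v_diff <- offs >= 120 & vfrac >= 0.5 &
      c(rep(FALSE, min(wsteps, ng)), vfrac[seq_len(max(ng - wsteps, 0))] >= 0.5)

    feats <- cbind(f_bvp_dmaxhr = d_max, f_bvp_dmeanhr = d_mean,
                   f_bvp_sqi = sqi$sqi, f_bvp_hr = hr)
    vmat <- cbind(f_bvp_dmaxhr = v_diff & is.finite(d_max),
                  f_bvp_dmeanhr = v_diff & is.finite(d_mean),
                  f_bvp_sqi = sqi$valid, f_bvp_hr = hre$valid)
    feats[!vmat] <- NA_real_
    list(times = times, features = feats, valid = vmat)
  })
  .bind_feature_chunks(per_seg)
}
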