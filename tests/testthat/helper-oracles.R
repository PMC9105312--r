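# Independent oracles and small fixture builders used across the suite.

# Brute-force RQA: enumerate every off-identity diagonal of a symmetric
# binary matrix with rle(), both triangles, and compute the four measures
# directly from the line-length census. Independent of the package's C++
# diagonal scanner.
rqa_bruteforce <- function(m, l_min = 2) {
  n <- nrow(m)
  lines <- integer()     # all maximal diagonal run lengths, both triangles
  rec_points <- 0L
  for (d in seq_len(n - 1L)) {
    for (tri in c("upper", "lower")) {
      diag_vals <- if (tri == "upper")
        m[cbind(seq_len(n - d), seq_len(n - d) + d)]
      else
        m[cbind(seq_len(n - d) + d, seq_len(n - d))]
      r <- rle(as.integer(diag_vals))
      runs <- r$lengths[r$values == 1L]
      rec_points <- rec_points + sum(runs)
      lines <- c(lines, runs)
    }
  }
  long <- lines[lines >= l_min]
  rr <- rec_points / (n^2 - n)
  det <- if (rec_points > 0) sum(long) / rec_points else 0
  if (length(long)) {
    tab <- table(long)
    p <- as.numeric(tab) / sum(tab)
    avg_len <- mean(long)
    entr <- -sum(p * log(p))
  } else {
    avg_len <- NA_real_
    entr <- 0
  }
  list(rr = rr, det = det, avg_len = avg_len, entr = entr)
}

# random symmetric binary matrix with unit diagonal
random_recurrence <- function(n, p = 0.3) {
  m <- matrix(runif(n * n) < p, n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- TRUE
  m
}

# clean pulse waveform (trough per beat) at a given constant heart rate
pulse_wave <- function(bpm, dur_s, fs = 64, noise_sd = 0) {
  t <- (0:(fs * dur_s - 1)) / fs
  -cos(2 * pi * bpm / 60 * t) + 0.3 * cos(4 * pi * bpm / 60 * t + 0.8) +
    rnorm(length(t), 0, noise_sd)
}

# single-segment recording with externally supplied channel samples
make_recording <- function(acc = NULL, eda = NULL, bvp = NULL, dur_s = 3600,
                           start = 1e9, id = "TST", utc_offset_hours = 0) {
  if (is.null(acc)) acc <- cbind(rnorm(dur_s * 32, 0, 0.01),
                                 rnorm(dur_s * 32, 0, 0.01),
                                 1 + rnorm(dur_s * 32, 0, 0.01))
  if (is.null(eda)) eda <- rep(1.5, dur_s * 4)
  if (is.null(bvp)) bvp <- pulse_wave(60, dur_s)
  recording(id, list(segment(list(
    ts_channel("ACC", start, 32, acc),
    ts_channel("EDA", start, 4, eda),
    ts_channel("BVP", start, 64, bvp)))),
    utc_offset_hours = utc_offset_hours)
}

# small high-signal participant used by detector/harness tests
small_participant <- function(seed, hours = 4, n_seizures = 3,
                              effect_scale = 1, id = "SX") {
  generate_participant(
    synthetic_profile(id, effect_scale = effect_scale),
    total_hours = hours, n_seizures = n_seizures, seed = seed)
}
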