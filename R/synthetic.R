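# Synthetic multimodal cohort generator. Emulates the statistical structure
# the detection pipeline assumes: circadian activity with quiet nights and
# bout-structured daytime movement on the accelerometer; tonic EDA drift with
# Poisson spontaneous skin-conductance responses (more frequent awake) and
# optional post-onset ictal responses; a pulsatile BVP waveform whose heart
# rate carries optional ictal tachycardia and whose amplitude is corrupted by
# movement-coupled broadband artifact (so the spectral-entropy quality index
# degrades during movement, ictal movement included); focal tonic (sustained
# offset + high-frequency tremor) and clonic (2-5 Hz rhythmic bursts) ictal
# movement overlays, attenuated when the device is on the wrist contralateral
# to the seizure; and recording gaps from device swaps. No claim of
# physiological fidelity beyond this feature-relevant structure.

#' Synthetic participant profile
#'
#' @param participant_id Identifier string.
#' @param eda_responder Logical: do seizures elicit an electrodermal
#'   response? May be a vector recycled over seizures (per-seizure override,
#'   e.g. one non-responder seizure).
#' @param ictal_tachycardia Logical: do seizures raise heart rate?
#' @param motor_pattern `"tonic"`, `"clonic"` or `"mixed"`.
#' @param device_on_seizure_side Logical; when `FALSE` the ictal movement
#'   amplitude seen by the device is attenuated by `contralateral_factor`.
#' @param vigilance `"awake"`, `"asleep"` or `"auto"` (night seizures are
#'   asleep).
#' @param baseline_activity_level Scalar multiplier on daytime movement.
#' @param night_schedule Local bedtime and wake hour (defaults 23 and 7).
#' @param utc_offset_hours Local-time offset of the site.
#' @param effect_scale Global multiplier on all ictal effect sizes; 0 gives a
#'   null participant whose seizures leave no trace in any modality.
#' @param contralateral_factor Ictal ACC attenuation for a contralateral
#'   device.
#' @param noise Per-channel noise levels: `acc` (g), `eda` (microsiemens),
#'   `bvp` (waveform units).
#' @param scr_rate Spontaneous skin-conductance-response rates per second,
#'   `c(awake, asleep)`; set to 0 for an electrodermally silent baseline.
#' @return List of class `synthetic_profile`.
#' @export
synthetic_profile <- function(participant_id,
                              eda_responder = TRUE,
                              ictal_tachycardia = TRUE,
                              motor_pattern = c("mixed", "tonic", "clonic"),
                              device_on_seizure_side = TRUE,
                              vigilance = "auto",
                              baseline_activity_level = 1,
                              night_schedule = c(23, 7),
                              utc_offset_hours = 1,
                              effect_scale = 1,
                              contralateral_factor = 0.25,
                              noise = list(acc = 0.02, eda = 0.01, bvp = 3),
                              scr_rate = c(1 / 60, 1 / 300)) {
  motor_pattern <- match.arg(motor_pattern)
  structure(list(participant_id = participant_id,
                 eda_responder = eda_responder,
                 ictal_tachycardia = ictal_tachycardia,
                 motor_pattern = motor_pattern,
                 device_on_seizure_side = device_on_seizure_side,
                 vigilance = vigilance,
                 baseline_activity_level = baseline_activity_level,
                 night_schedule = night_schedule,
                 utc_offset_hours = utc_offset_hours,
                 effect_scale = effect_scale,
                 contralateral_factor = contralateral_factor,
                 noise = noise,
                 scr_rate = scr_rate), class = "synthetic_profile")
}

# local hour of an epoch time
.local_hour <- function(t, utc_offset_hours) ((t / 3600 + utc_offset_hours) %% 24)

.is_night <- function(t, utc_offset_hours, night = c(23, 7)) {
  h <- .local_hour(t, utc_offset_hours)
  if (night[1L] > night[2L]) h >= night[1L] | h < night[2L]
  else h >= night[1L] & h < night[2L]
}

# per-second daytime movement-bout envelope (two-state Markov chain)
.bout_envelope <- function(n_sec, p_start = 1 / 120, p_stop = 1 / 60,
                           level = 1) {
  u <- runif(n_sec)
  env <- numeric(n_sec)
  on <- FALSE
  for (i in seq_len(n_sec)) {
    on <- if (on) u[i] > p_stop else u[i] < p_start
    env[i] <- if (on) level else 0
  }
  # brief ramps to avoid square-wave edges
  stats::filter(env, rep(1 / 5, 5), sides = 2) -> sm
  sm[is.na(sm)] <- env[is.na(sm)]
  as.numeric(sm)
}

# additive SCR kernel: rise over rise_s, exponential decay tau_s
.scr_kernel <- function(amp, fs, rise_s = 2, tau_s = 15) {
  up <- seq(0, amp, length.out = round(rise_s * fs))
  down <- amp * exp(-(seq_len(round(6 * tau_s * fs)) / fs) / tau_s)
  c(up, down)
}

.add_kernel <- function(x, at, kernel) {
  n <- length(x)
  if (at > n) return(x)
  idx <- at:min(n, at + length(kernel) - 1L)
  x[idx] <- x[idx] + kernel[seq_along(idx)]
  x
}

# one contiguous segment of synthetic raw channels
.synth_segment <- function(profile, start_time, duration_s, plan) {
  p <- profile
  fs_acc <- 32; fs_eda <- 4; fs_bvp <- 64
  n_sec <- as.integer(duration_s)
  sec_t <- start_time + seq_len(n_sec) - 1
  night <- .is_night(sec_t, p$utc_offset_hours, p$night_schedule)

  # --- movement envelope (per second), background + ictal overlay ---------
  env <- .bout_envelope(n_sec, level = 0.3 * p$baseline_activity_level)
  env[night] <- env[night] * 0.05
  side <- if (p$device_on_seizure_side) 1 else p$contralateral_factor
  ict_env <- numeric(n_sec)   # for BVP artifact coupling
  for (k in seq_len(nrow(plan))) {
    rel <- sec_t - plan$onset[k]
    ict <- rel >= 0 & sec_t < plan$offset[k]
    ict_env[ict] <- pmax(ict_env[ict], 0.6 * side * p$effect_scale)
  }

  # --- ACC ---------------------------------------------------------------
  n_acc <- n_sec * fs_acc
  t_acc <- start_time + (seq_len(n_acc) - 1) / fs_acc
  env_acc <- rep(env, each = fs_acc)
  swing <- sin(2 * pi * 1.5 * t_acc + runif(1, 0, 2 * pi))
  acc <- cbind(
    env_acc * (0.6 * swing + rnorm(n_acc, 0, 0.5)),
    env_acc * (0.4 * sin(2 * pi * 0.9 * t_acc + runif(1, 0, 2 * pi)) +
                 rnorm(n_acc, 0, 0.5)),
    1 + env_acc * rnorm(n_acc, 0, 0.4))
  acc <- acc + matrix(rnorm(3 * n_acc, 0, p$noise$acc), ncol = 3L)

  amp_ict <- side * p$effect_scale
  for (k in seq_len(nrow(plan))) {
    i0 <- as.integer((plan$onset[k] - start_time) * fs_acc) + 1L
    i1 <- as.integer((plan$offset[k] - start_time) * fs_acc)
    if (i1 < 1L || i0 > n_acc) next
    idx <- max(i0, 1L):min(i1, n_acc)
    tt <- (idx - i0) / fs_acc
    pat <- plan$pattern[k]
    half <- length(idx) %/% 2L
    tonic_part <- if (pat == "tonic") seq_along(idx)
                  else if (pat == "mixed") seq_len(half) else integer()
    clonic_part <- if (pat == "clonic") seq_along(idx)
                   else if (pat == "mixed") (half + 1L):length(idx) else integer()
    if (length(tonic_part)) {
      # sustained posture offset + low-amplitude 8-12 Hz tremor
      f_trem <- runif(1, 8, 12)
      acc[idx[tonic_part], 1L] <- acc[idx[tonic_part], 1L] +
        amp_ict * (0.4 + 0.08 * sin(2 * pi * f_trem * tt[tonic_part]))
      acc[idx[tonic_part], 3L] <- acc[idx[tonic_part], 3L] -
        amp_ict * 0.15
    }
    if (length(clonic_part)) {
      # 2-5 Hz rhythmic jerking, amplitude-modulated in ~2 s bursts
      f_clon <- runif(1, 2, 5)
      burst <- 0.5 + 0.5 * sign(sin(2 * pi * tt[clonic_part] / 3))
      acc[idx[clonic_part], 1L] <- acc[idx[clonic_part], 1L] +
        amp_ict * 0.5 * burst * sin(2 * pi * f_clon * tt[clonic_part])
      acc[idx[clonic_part], 2L] <- acc[idx[clonic_part], 2L] +
        amp_ict * 0.3 * burst * sin(2 * pi * f_clon * tt[clonic_part] + 1)
    }
  }

  # --- EDA ---------------------------------------------------------------
  n_eda <- n_sec * fs_eda
  t_eda <- start_time + (seq_len(n_eda) - 1) / fs_eda
  tonic <- 1.5 + 0.3 * sin(2 * pi * (t_eda - start_time) / 7200 +
                             runif(1, 0, 2 * pi))
  eda <- tonic + rnorm(n_eda, 0, p$noise$eda)
  # spontaneous SCRs: Poisson, rate higher awake
  rate_sec <- ifelse(night, p$scr_rate[2L], p$scr_rate[1L])
  n_scr <- if (sum(rate_sec) > 0) rpois(1, sum(rate_sec)) else 0L
  if (n_scr > 0) {
    at_sec <- sample.int(n_sec, n_scr, replace = TRUE, prob = rate_sec)
    for (a in at_sec)
      eda <- .add_kernel(eda, (a - 1L) * fs_eda + 1L,
                         .scr_kernel(runif(1, 0.2, 1), fs_eda))
  }
  # ictal responses (responder seizures only)
  for (k in seq_len(nrow(plan))) {
    if (!plan$responder[k] || p$effect_scale <= 0) next
    lat <- runif(1, 0, 20)
    at <- as.integer((plan$onset[k] + lat - start_time) * fs_eda) + 1L
    if (at < 1L || at > n_eda) next
    eda <- .add_kernel(eda, at,
                       .scr_kernel(runif(1, 0.5, 3) * p$effect_scale, fs_eda,
                                   rise_s = 20, tau_s = 120))
  }
  eda <- pmax(eda, 0.01)

  # --- BVP ---------------------------------------------------------------
  n_bvp <- n_sec * fs_bvp
  wander <- as.numeric(stats::filter(rnorm(n_sec, 0, 1.5), rep(1 / 30, 30),
                                     sides = 1, method = "convolution"))
  wander[is.na(wander)] <- 0
  hr_sec <- 70 - 8 * night + 4 * sin(2 * pi * seq_len(n_sec) / 600) + wander
  for (k in seq_len(nrow(plan))) {
    if (!plan$tachycardia[k] || p$effect_scale <= 0) next
    dhr <- runif(1, 20, 50) * p$effect_scale
    ramp <- pmin(pmax((sec_t - plan$onset[k]) / 20, 0), 1)  # 20-s rise
    decay <- exp(-pmax(sec_t - plan$offset[k], 0) / 60)     # post-offset decay
    hr_sec <- hr_sec + dhr * ramp * decay
  }
  hr_sec <- pmin(pmax(hr_sec, 40), 190)
  hr_bvp <- rep(hr_sec, each = fs_bvp)
  phase <- 2 * pi * cumsum(hr_bvp / 60) / fs_bvp
  mov <- pmin(rep(env, each = fs_bvp) + rep(ict_env, each = fs_bvp), 1.5)
  bvp <- -100 * (cos(phase) - 0.25 * cos(2 * phase + 0.8)) +
    250 * mov * rnorm(n_bvp) + rnorm(n_bvp, 0, p$noise$bvp)

  # --- TEMP --------------------------------------------------------------
  n_tmp <- n_sec * fs_eda
  temp <- 33 + 0.5 * sin(2 * pi * (seq_len(n_tmp) / fs_eda) / 86400) +
    rnorm(n_tmp, 0, 0.02)

  segment(list(ts_channel("ACC", start_time, fs_acc, acc),
               ts_channel("EDA", start_time, fs_eda, eda),
               ts_channel("BVP", start_time, fs_bvp, bvp),
               ts_channel("TEMP", start_time, fs_eda, temp)))
}

# draw a seizure plan: onsets inside segments with margins, durations within
# the inclusion bounds by construction
.plan_seizures <- function(profile, seg_bounds, n_seizures,
                           dur_range = c(30, 150), edge_margin = 700,
                           min_gap = 1800) {
  if (n_seizures == 0L)
    return(data.frame(onset = numeric(), offset = numeric(),
                      pattern = character(), responder = logical(),
                      tachycardia = logical(), vigilance = character(),
                      stringsAsFactors = FALSE))
  ok_spans <- seg_bounds[seg_bounds[, 2L] - seg_bounds[, 1L] >
                           2 * edge_margin + dur_range[2L], , drop = FALSE]
  if (!nrow(ok_spans)) stop("no segment long enough to place seizures")
  # rejection sampling with full restarts: a greedy draw can paint itself
  # into a corner on short recordings, so stuck attempts are discarded
  onsets <- numeric()
  for (restart in seq_len(200L)) {
    onsets <- numeric()
    for (tries in seq_len(500L)) {
      if (length(onsets) >= n_seizures) break
      si <- sample.int(nrow(ok_spans), 1L)
      cand <- runif(1, ok_spans[si, 1L] + edge_margin,
                    ok_spans[si, 2L] - edge_margin - dur_range[2L])
      if (all(abs(cand - onsets) >= min_gap)) onsets <- c(onsets, cand)
    }
    if (length(onsets) >= n_seizures) break
  }
  if (length(onsets) < n_seizures)
    stop(sprintf("could not place %d seizures in the recording span",
                 n_seizures))
  onsets <- sort(round(onsets))
  dur <- round(runif(n_seizures, dur_range[1L], dur_range[2L]))
  pattern <- if (profile$motor_pattern == "mixed")
    sample(c("tonic", "clonic", "mixed"), n_seizures, replace = TRUE)
  else rep(profile$motor_pattern, n_seizures)
  responder <- rep_len(profile$eda_responder, n_seizures)
  night <- .is_night(onsets, profile$utc_offset_hours,
                     profile$night_schedule)
  vig <- if (identical(profile$vigilance, "auto"))
    ifelse(night, "asleep", "awake") else rep(profile$vigilance, n_seizures)
  data.frame(onset = onsets, offset = onsets + dur, pattern = pattern,
             responder = responder,
             tachycardia = rep(profile$ictal_tachycardia, n_seizures),
             vigilance = vig, stringsAsFactors = FALSE)
}

#' Generate one synthetic participant
#'
#' Builds a multi-segment recording (segments separated by device-swap gaps)
#' with planted focal motor seizures according to the profile, and the
#' matching expert-style annotations. Deterministic given `seed`.
#'
#' @param profile A [synthetic_profile()].
#' @param total_hours Hours of recorded data (excluding gaps).
#' @param n_seizures Number of seizures to plant.
#' @param seed Integer seed.
#' @param segment_hours Nominal segment length between device swaps.
#' @param swap_gap_s Gap between segments (s).
#' @param dur_range Seizure duration range (s), inside the 10 s - 10 min
#'   inclusion bounds.
#' @param start_epoch Epoch start; default noon local time of an arbitrary
#'   fixed day.
#' @return List: `recording` ([recording()]), `annotations`
#'   ([seizure_annotations()]), `plan` (the generative truth).
#' @export
generate_participant <- function(profile, total_hours = 24, n_seizures = 3,
                                 seed = 1, segment_hours = 12,
                                 swap_gap_s = 300, dur_range = c(30, 150),
                                 start_epoch = NULL) {
  stopifnot(total_hours > 0)
  set.seed(seed)
  if (is.null(start_epoch))
    start_epoch <- 18000 * 86400 + (12 - profile$utc_offset_hours) * 3600
  # segment layout
  remaining <- total_hours * 3600
  segs <- list()
  t0 <- start_epoch
  while (remaining > 0) {
    d <- min(remaining, segment_hours * 3600)
    segs[[length(segs) + 1L]] <- c(t0, t0 + d)
    t0 <- t0 + d + swap_gap_s
    remaining <- remaining - d
  }
  seg_bounds <- do.call(rbind, segs)
  plan <- .plan_seizures(profile, seg_bounds, n_seizures,
                         dur_range = dur_range)
  seg_objs <- lapply(seq_len(nrow(seg_bounds)), function(i)
    .synth_segment(profile, seg_bounds[i, 1L],
                   seg_bounds[i, 2L] - seg_bounds[i, 1L], plan))
  rec <- recording(profile$participant_id, seg_objs,
                   wrist = if (profile$device_on_seizure_side) "left" else "right",
                   utc_offset_hours = profile$utc_offset_hours)
  ann <- if (nrow(plan)) seizure_annotations(
    seizure_id = sprintf("%s-%d", profile$participant_id, seq_len(nrow(plan))),
    onset = plan$onset, offset = plan$offset,
    motor_flags = plan$pattern,
    tachycardia = plan$tachycardia,
    vigilance = plan$vigilance,
    side_matches_device = profile$device_on_seizure_side)
  else seizure_annotations(character(), numeric(), numeric())
  list(recording = rec, annotations = ann, plan = plan)
}

#' Default cohort preset
#'
#' Nine participants, 20 seizures: three multi-seizure participants (6, 3 and
#' 3 seizures - the intra-subject / training cohort) and six participants
#' with one or two seizures each (the out-of-sample test cohort). The second
#' training participant is tonic-only, awake, with one non-responder seizure.
#' All profiles wear the device on the seizure side (the positive-control
#' condition: every modality carries its full ictal effect); contralateral
#' attenuation is available per profile via
#' [synthetic_profile()]`(device_on_seizure_side = FALSE)`.
#'
#' @param effect_scale Global ictal effect-size multiplier.
#' @return List with `profiles` and `n_seizures`.
#' @export
cohort_preset_default <- function(effect_scale = 1) {
  profiles <- list(
    synthetic_profile("SP1", motor_pattern = "mixed", vigilance = "asleep",
                      effect_scale = effect_scale),
    synthetic_profile("SP2", motor_pattern = "tonic", vigilance = "awake",
                      eda_responder = c(TRUE, FALSE, TRUE),
                      effect_scale = effect_scale),
    synthetic_profile("SP3", motor_pattern = "mixed",
                      effect_scale = effect_scale),
    synthetic_profile("SP4", motor_pattern = "tonic",
                      effect_scale = effect_scale),
    synthetic_profile("SP5", motor_pattern = "clonic",
                      effect_scale = effect_scale),
    synthetic_profile("SP6", motor_pattern = "mixed",
                      effect_scale = effect_scale),
    synthetic_profile("SP7", motor_pattern = "tonic",
                      ictal_tachycardia = FALSE,
                      effect_scale = effect_scale),
    synthetic_profile("SP8", motor_pattern = "clonic",
                      effect_scale = effect_scale),
    synthetic_profile("SP9", motor_pattern = "mixed",
                      effect_scale = effect_scale))
  list(profiles = profiles, n_seizures = c(6L, 3L, 3L, 2L, 1L, 2L, 1L, 1L, 1L))
}

#' Generate a synthetic cohort
#'
#' Per-participant sub-seeds are derived deterministically from the master
#' seed, so the cohort regenerates identically.
#'
#' @param preset A [cohort_preset_default()]-shaped list (`profiles`,
#'   `n_seizures`), or `NULL` for the default.
#' @param hours_range Recorded hours per participant, drawn uniformly.
#' @param seed Master seed.
#' @param ... Passed to [generate_participant()].
#' @return List of participants (each `recording`, `annotations`, `plan`),
#'   named by participant id.
#' @export
generate_cohort <- function(preset = NULL, hours_range = c(24, 28),
                            seed = 1, ...) {
  if (is.null(preset)) preset <- cohort_preset_default()
  np <- length(preset$profiles)
  stopifnot(np >= 1L, length(preset$n_seizures) == np)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, np)
  hours <- runif(np, hours_range[1L], hours_range[2L])
  out <- lapply(seq_len(np), function(i)
    generate_participant(preset$profiles[[i]], total_hours = hours[i],
                         n_seizures = preset$n_seizures[i],
                         seed = sub_seeds[i], ...))
  names(out) <- vapply(preset$profiles, `[[`, "", "participant_id")
  out
}
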