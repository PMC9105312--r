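test_that("generation is deterministic given the seed", {
  a <- small_participant(81, hours = 1, n_seizures = 2)
  b <- small_participant(81, hours = 1, n_seizures = 2)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$recording$segments[[1]]$channels$ACC$samples,
                   b$recording$segments[[1]]$channels$ACC$samples)
  expect_identical(a$recording$segments[[1]]$channels$EDA$samples,
                   b$recording$segments[[1]]$channels$EDA$samples)
  c <- small_participant(82, hours = 1, n_seizures = 2)
  expect_false(identical(a$annotations$onset, c$annotations$onset))
})

test_that("seizure plans respect counts, bounds and placement", {
  gp <- small_participant(83, hours = 3, n_seizures = 4)
  ann <- gp$annotations
  expect_equal(nrow(ann), 4L)
  dur <- ann$offset - ann$onset
  expect_true(all(dur >= 10 & dur <= 600))   # inclusion bounds by construction
  expect_true(all(nrow(filter_seizures(ann)$retained) == 4L))
  expect_true(all(diff(ann$onset) >= 1800))
  # zero seizures -> empty annotations
  expect_equal(nrow(small_participant(84, hours = 0.5,
                                      n_seizures = 0)$annotations), 0L)
  # infeasible plan errors
  expect_error(small_participant(85, hours = 0.5, n_seizures = 10),
               "place|long enough")
})

test_that("responder seizures leave an EDA trace; non-responders do not", {
  # zero-noise condition: no sensor noise and no spontaneous responses
  noise0 <- list(acc = 0.02, eda = 0, bvp = 3)
  resp <- generate_participant(
    synthetic_profile("R", eda_responder = TRUE, noise = noise0,
                      scr_rate = c(0, 0)),
    total_hours = 1.5, n_seizures = 1, seed = 86)
  nonr <- generate_participant(
    synthetic_profile("N", eda_responder = FALSE, noise = noise0,
                      scr_rate = c(0, 0)),
    total_hours = 1.5, n_seizures = 1, seed = 86)
  dmax_at <- function(gp) {
    f <- eda_feature_series(gp$recording)
    at <- which.min(abs(f$times - (gp$annotations$onset[1] + 120)))
    f$features[at, "f_eda_dmax"]
  }
  expect_gt(dmax_at(resp), 0.2)
  expect_lt(abs(dmax_at(nonr)), 0.15)   # only drift/spontaneous activity
})

test_that("ictal tachycardia and motion raise the HR and SQI features", {
  gp <- generate_participant(
    synthetic_profile("T", ictal_tachycardia = TRUE, motor_pattern = "clonic"),
    total_hours = 1.5, n_seizures = 1, seed = 87)
  f <- bvp_feature_series(gp$recording)
  on <- gp$annotations$onset[1]; off <- gp$annotations$offset[1]
  ict <- f$times >= on & f$times <= off + 30
  base <- f$times < on - 300
  d <- f$features[ict, "f_bvp_dmaxhr"]
  expect_gt(max(d[is.finite(d)]), 10)   # tachycardia ramp visible
  expect_gt(mean(f$features[ict, "f_bvp_sqi"], na.rm = TRUE),
            mean(f$features[base, "f_bvp_sqi"], na.rm = TRUE))
})

test_that("contralateral device attenuates the ictal accelerometry", {
  mk <- function(side) generate_participant(
    synthetic_profile("C", motor_pattern = "clonic",
                      device_on_seizure_side = side),
    total_hours = 1.5, n_seizures = 1, seed = 88)
  ipsi <- mk(TRUE); contra <- mk(FALSE)
  # identical seed -> identical plan; compare ictal ACC energy
  expect_equal(ipsi$annotations$onset, contra$annotations$onset)
  energy <- function(gp) {
    seg <- gp$recording$segments[[1]]
    fs <- 32
    i0 <- (gp$annotations$onset[1] - seg$start_time) * fs
    i1 <- (gp$annotations$offset[1] - seg$start_time) * fs
    x <- seg$channels$ACC$samples[i0:i1, 1]
    sd(x)
  }
  expect_gt(energy(ipsi), 2 * energy(contra))
})

test_that("the default cohort preset has the study cohort shape", {
  preset <- cohort_preset_default()
  expect_length(preset$profiles, 9L)
  expect_equal(sum(preset$n_seizures), 20L)
  expect_equal(sort(preset$n_seizures[preset$n_seizures >= 3], TRUE),
               c(6L, 3L, 3L))
  expect_true(all(preset$n_seizures[preset$n_seizures < 3] %in% 1:2))
  # cohort regeneration with the same master seed is identical (scaled down)
  mini <- list(profiles = preset$profiles[1:2], n_seizures = c(2L, 1L))
  c1 <- generate_cohort(mini, hours_range = c(1.5, 2), seed = 9)
  c2 <- generate_cohort(mini, hours_range = c(1.5, 2), seed = 9)
  expect_identical(lapply(c1, `[[`, "annotations"),
                   lapply(c2, `[[`, "annotations"))
})

test_that("night windows carry lower activity than daytime", {
  gp <- generate_participant(synthetic_profile("D"), total_hours = 24,
                             n_seizures = 0, seed = 89, segment_hours = 24)
  seg <- gp$recording$segments[[1]]
  acc <- seg$channels$ACC$samples
  t <- seg$start_time + (seq_len(nrow(acc)) - 1) / 32
  night <- ictalwear:::.is_night(t, gp$recording$utc_offset_hours)
  expect_lt(sd(acc[night, 1]), sd(acc[!night, 1]) / 2)
})
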