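lab <- function(...) as.integer(c(...))

test_that("smoothing fills short gaps then removes orphans, idempotently", {
  times <- seq(0, 400, by = 2)
  # two 10-s runs separated by a 20-s gap merge into one 40-s run
  x <- integer(201)
  x[11:15] <- 1L; x[26:30] <- 1L        # 20-28 s and 50-58 s -> gap 20 s
  sm <- smooth_labels(x, times[1:201])
  expect_equal(sum(sm), 20L)            # 40 s
  expect_equal(range(which(sm == 1L)), c(11L, 30L))

  # a 30-s gap still merges ("at most 30 s"); 32 s does not
  x30 <- integer(100); x30[10:12] <- 1L; x30[28:30] <- 1L   # gap 15 steps
  expect_equal(sum(smooth_labels(x30)), 21L)
  x32 <- integer(100); x32[10:12] <- 1L; x32[29:31] <- 1L   # gap 16 steps
  expect_equal(sum(smooth_labels(x32)), 6L)

  # isolated 2-s orphan removed; 6-s run kept
  xo <- integer(50); xo[25] <- 1L
  expect_equal(sum(smooth_labels(xo)), 0L)
  xk <- integer(50); xk[25:27] <- 1L
  expect_equal(sum(smooth_labels(xk)), 3L)

  # smoothing never bridges recording gaps
  tg <- c(seq(0, 58, by = 2), seq(100, 158, by = 2))
  xg <- integer(60); xg[28:30] <- 1L; xg[31:33] <- 1L  # adjacent across gap
  smg <- smooth_labels(xg, tg)
  expect_equal(smg, xg)   # both runs are 6 s, kept, gap not filled

  # idempotence on random series
  set.seed(71)
  for (i in 1:20) {
    r <- as.integer(runif(300) < 0.2)
    once <- smooth_labels(r)
    expect_identical(smooth_labels(once), once)
  }
})

test_that("event extraction applies the 6 s - 10 min bounds", {
  times <- seq(0, 2998, by = 2)
  x <- integer(1500)
  x[101:102] <- 1L                      # 4 s: below minimum
  expect_equal(nrow(to_events(x, times)), 0L)
  x <- integer(1500); x[101:103] <- 1L  # exactly 6 s
  ev <- to_events(x, times)
  expect_equal(nrow(ev), 1L)
  expect_equal(unname(ev[1, ]), c(200, 206))
  x <- integer(1500); x[101:450] <- 1L  # 700 s: truncated to 600 s, one event
  ev2 <- to_events(x, times)
  expect_equal(nrow(ev2), 1L)
  expect_equal(unname(ev2[1, 2] - ev2[1, 1]), 600)
})

test_that("margin matching: worked overlap cases and absorption", {
  truth <- rbind(c(100, 160))
  # direct overlap
  expect_equal(match_events(truth, rbind(c(150, 200)))$tp, 1L)
  # 90 s after offset: inside the 2-min margin
  m <- match_events(truth, rbind(c(250, 270)))
  expect_equal(m$tp, 1L); expect_equal(m$fp, 0L); expect_equal(m$fn, 0L)
  # isolated prediction far away: false positive
  m2 <- match_events(truth, rbind(c(1000, 1020)))
  expect_equal(m2$tp, 0L); expect_equal(m2$fp, 1L); expect_equal(m2$fn, 1L)
  # multiple predictions inside one margin window collapse to one TP, no FP
  m3 <- match_events(truth, rbind(c(90, 110), c(130, 150), c(200, 230)))
  expect_equal(m3$tp, 1L); expect_equal(m3$fp, 0L)
  # beyond the margin on the early side
  m4 <- match_events(truth, rbind(c(-60, -30)))
  expect_equal(m4$tp, 0L); expect_equal(m4$fp, 1L)
})

test_that("matching is monotone in the margin and classifies every event once", {
  set.seed(72)
  for (i in 1:15) {
    truth <- to_events(as.integer(runif(500) < 0.1), seq(0, 998, by = 2))
    pred <- to_events(as.integer(runif(500) < 0.1), seq(0, 998, by = 2))
    prev_tp <- -1L
    for (mar in c(0, 60, 120, 300)) {
      m <- match_events(truth, pred, margin_s = mar)
      expect_gte(m$tp, prev_tp)
      expect_equal(m$tp + m$fn, nrow(truth))
      expect_equal(m$fp + sum(m$pred_matched), nrow(pred))
      prev_tp <- m$tp
    }
  }
})

test_that("far24 arithmetic at representative counts and durations", {
  expect_equal(round(far24(3, 84.4), 2), 0.85)
  expect_equal(round(far24(37, 50.2), 2), 17.69)
  expect_equal(round(far24(28, 84.4), 2), 7.96)
  expect_equal(round(far24(1, 50.2), 2), 0.48)
  expect_equal(far24(0, 10), 0)
  expect_error(far24(1, 0), "positive")
})

test_that("nightly hours and FARn respect local time and data loss", {
  # one full day starting at local noon, utc offset +1: night 23:00-07:00
  start <- (12 - 1) * 3600
  segs <- rbind(c(start, start + 86400))
  expect_equal(nightly_hours(segs, utc_offset_hours = 1), 8)

  # a 2-h gap inside the night is excluded
  segs2 <- rbind(c(start, start + 12 * 3600),
                 c(start + 14 * 3600, start + 86400))   # gap 02:00-04:00 local
  expect_equal(nightly_hours(segs2, utc_offset_hours = 1), 6)

  # 2 night FPs with 16 h of night data -> 1.0 per standard night
  two_nights <- rbind(c(start, start + 2 * 86400))
  expect_equal(nightly_hours(two_nights, utc_offset_hours = 1), 16)
  fp_ev <- rbind(c(start + 12.5 * 3600, start + 12.6 * 3600),   # 00:30 local
                 c(start + 36 * 3600, start + 36.1 * 3600),     # 00:00 local
                 c(start + 3600, start + 3700))                 # 13:00 local
  fn <- farn(fp_ev, two_nights, utc_offset_hours = 1)
  expect_equal(fn$fp_night, 2L)
  expect_equal(fn$farn, 2 * 8 / 16)
  expect_equal(farn(fp_ev[0, , drop = FALSE], two_nights, 1)$farn, 0)
  # no nightly coverage -> undefined sentinel
  day_only <- rbind(c(start, start + 3600))
  expect_true(is.na(farn(fp_ev, day_only, 1)$farn))
})

test_that("event sets export as 3-column interval CSV", {
  ev <- rbind(c(100, 160), c(500, 520))
  colnames(ev) <- c("start", "end")
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, "P1", path)
  back <- read.csv(path)
  expect_identical(colnames(back), c("participant_id", "start", "end"))
  expect_equal(back$start, c(100, 500))
  expect_equal(back$end, c(160, 520))
})

test_that("score_prediction assembles the report and PPV conventions", {
  times <- seq(0, 7198, by = 2)
  labels <- integer(3600)
  labels[1501:1530] <- 1L   # 60-s predicted event at 3000-3060
  truth <- rbind(c(3010, 3050))
  rep <- score_prediction(labels, times, truth, recording_hours = 2)
  expect_equal(rep$tp, 1L); expect_equal(rep$fp, 0L)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$ppv, 1)
  expect_equal(rep$far24, 0)
  # no predictions at all: PPV defined as 0
  rep0 <- score_prediction(integer(3600), times, truth, recording_hours = 2)
  expect_equal(rep0$ppv, 0)
  expect_equal(rep0$fn, 1L)
  expect_equal(rep0$sensitivity, 0)
})
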