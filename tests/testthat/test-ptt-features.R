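test_that("compute_ptt recovers a constructed 250-ms crossing", {
  rp <- seq(10, 60, by = 1)
  pl <- make_pleth(rp, rep(250, length(rp)))
  beats <- compute_ptt(rp, pl)
  expect_true(all(beats$valid))
  expect_true(all(abs(beats$ptt_raw - 250) < 5))
})

test_that("PTT below the 150-ms floor is marked invalid, not dropped", {
  rp <- seq(10, 40, by = 1)
  pl <- make_pleth(rp, rep(120, length(rp)))
  beats <- compute_ptt(rp, pl)
  expect_true(all(!beats$valid))
  expect_true(all(abs(beats$ptt_raw - 120) < 5))
})

test_that("a beat with no pulse within 2 s is invalid, never an error", {
  rp <- c(10, 11, 12, 20)                # last beat's pulse is missing
  pl <- make_pleth(rp[1:3], rep(250, 3), duration = 25)
  beats <- compute_ptt(rp, pl)
  expect_false(beats$valid[4])
  expect_true(is.na(beats$ptt_raw[4]))
  expect_error(compute_ptt(numeric(0), pl), "empty")
})

test_that("1,000 programmed delays are recovered within one pleth sample", {
  set.seed(42)
  rp <- 10 + cumsum(runif(1000, 0.55, 0.75))
  truth <- runif(1000, 200, 300)
  pl <- make_pleth(rp, truth)
  beats <- compute_ptt(rp, pl)
  expect_true(all(beats$valid))
  expect_lte(max(abs(beats$ptt_raw - truth)), 10)
})

test_that("smooth_ptt2 equals the brute-force windowed mean", {
  set.seed(7)
  b <- make_beats(runif(200, 200, 300))
  b$valid[sample(200, 30)] <- FALSE
  sm <- smooth_ptt2(b)
  x <- ifelse(b$valid, b$ptt_raw, NA)
  brute <- vapply(seq_len(200), function(i) {
    w <- max(1, i - 8):min(200, i + 8)
    mean(x[w], na.rm = TRUE)
  }, numeric(1))
  brute[is.nan(brute)] <- NA
  expect_equal(sm$ptt2, brute)
})

test_that("PTT2 impulse response: one 267-ms beat among 250-ms beats", {
  b <- make_beats(c(rep(250, 20), 267, rep(250, 20)))
  sm <- smooth_ptt2(b)
  expect_equal(sm$ptt2[21], 251)           # 250 + 17/17
  expect_equal(sm$ptt2[1], 250)            # edge window shrinks, stays constant
})

test_that("spike masking removes the spike plus guard and nothing else", {
  dt <- 0.5
  n <- 4 * 3600 / dt
  b <- make_beats(rep(250, n), dt = dt)
  art0 <- remove_ptt_artefact(b)
  expect_false(any(art0$beats$mask))
  expect_equal(art0$artefact_free_hours, 4, tolerance = 1e-3)
  # one 120-ms spike lasting 5 s
  i0 <- 10000; i1 <- i0 + 5 / dt
  b$ptt_raw[i0:i1] <- 370
  art <- remove_ptt_artefact(b)
  lost <- 4 - art$artefact_free_hours
  expect_gt(lost * 3600, 5 + 2 * 10 - 2)
  expect_lt(lost * 3600, 5 + 2 * 10 + 3)
})

test_that("arousal rule fixtures straddle the 15-ms and 5-45-s boundaries", {
  n_ev <- function(d) detect_ptt_arousals(d)$n
  expect_equal(n_ev(make_dip_series(20, 10)), 1)
  expect_equal(n_ev(make_dip_series(15, 10)), 1)
  expect_equal(n_ev(make_dip_series(14, 10)), 0)
  expect_equal(n_ev(make_dip_series(20, 60)), 0)   # too slow a descent
  expect_equal(n_ev(make_dip_series(20, 10, hold = 30)), 1)
  flat <- data.frame(beat_time = 0:299, ptt2 = rep(250, 300))
  expect_equal(n_ev(flat), 0)
})

test_that("arousal count is shift-invariant and zero on monotone series", {
  d <- make_dip_series(22, 12)
  d2 <- d; d2$ptt2 <- d2$ptt2 + 37
  expect_equal(detect_ptt_arousals(d)$n, detect_ptt_arousals(d2)$n)
  up <- data.frame(beat_time = 0:299, ptt2 = 250 + seq(0, 60, length.out = 300))
  expect_equal(detect_ptt_arousals(up)$n, 0)
})

test_that("arousals outside the valid PTT2 range are not counted", {
  d <- make_dip_series(20, 10, base = 140)         # whole series below 150 ms
  expect_equal(detect_ptt_arousals(d)$n, 0)
  d_hi <- make_dip_series(20, 10, base = 520)      # above 500 ms
  expect_equal(detect_ptt_arousals(d_hi)$n, 0)
})

test_that("ptt_ai equals events per artefact-free hour and flags zero hours", {
  d <- make_dip_series(20, 10)
  r <- detect_ptt_arousals(d, artefact_free_hours = 2)
  expect_equal(r$ptt_ai, r$n / 2)
  expect_false(r$flagged)
  r0 <- detect_ptt_arousals(d, artefact_free_hours = 0)
  expect_true(r0$flagged)
  expect_true(is.na(r0$ptt_ai))
})

test_that("injected arousal count equals detected count on clean recordings", {
  tot_inj <- 0; tot_det <- 0
  for (sd in 1:6) {
    p <- subject_profile(c("normal", "uars_mild_osa", "severe_osa")[(sd %% 3) + 1],
                         swing_amplitude = c(14, 20.7, 26.7)[(sd %% 3) + 1],
                         arousal_rate = 12, arousal_drop = 25,
                         desat_rate = 1, study_hours = 1.5)
    rec <- simulate_subject(p, seed = 800 + sd)
    beats <- compute_ptt(rec$r_peaks, rec$pleth)
    art <- remove_ptt_artefact(beats)
    det <- detect_ptt_arousals(smooth_ptt2(art$beats), mask = art$beats$mask)
    tot_inj <- tot_inj + rec$truth$n_arousals
    tot_det <- tot_det + det$n
  }
  expect_identical(tot_det, tot_inj)
})

test_that("respiratory channel interpolates linearly and applies the 3-sample mean", {
  b <- data.frame(beat_time = c(0, 2, 4, 6, 8), ptt_raw = c(240, 260, 240, 260, 240),
                  valid = TRUE)
  raw <- derive_resp_channel(b, smooth = FALSE)
  expect_equal(raw$value[raw$time == 1], 250)      # linear midpoint
  expect_equal(raw$value[raw$time == 2], 260)
  sm <- derive_resp_channel(b)
  expect_equal(sm$value[sm$time == 2], mean(c(250, 260, 250)))
  expect_error(derive_resp_channel(make_beats(c(250))), "valid beats")
})

test_that("3-sample mean attenuates a 4-s sinusoid by exactly 1/3", {
  tt <- 0:399
  b <- data.frame(beat_time = tt, ptt_raw = 250 + 10 * sin(2 * pi * tt / 4),
                  valid = TRUE)
  sm <- derive_resp_channel(b)
  mid <- sm$value[50:350]
  expect_equal(max(abs(mid - 250)), 10 / 3, tolerance = 1e-6)
})

test_that("pttrs of a sinusoid is its trough-to-peak amplitude", {
  tt <- 0:599
  ch <- data.frame(time = tt, value = 250 + 10 * sin(2 * pi * tt / 7.3),
                   mask = FALSE)
  class(ch) <- c("resp_channel", "data.frame")
  r <- compute_pttrs(ch)
  expect_equal(r$pttrs, 20, tolerance = 0.1)
  flat <- data.frame(time = tt, value = rep(250, 600), mask = FALSE)
  expect_warning(r0 <- compute_pttrs(flat), "no detectable breath")
  expect_equal(r0$pttrs, 0)
  expect_true(r0$flagged)
})

test_that("pttrs is amplitude-equivariant and shift-invariant", {
  tt <- 0:599
  mk <- function(a, c0) {
    d <- data.frame(time = tt, value = c0 + a * sin(2 * pi * tt / 6.1),
                    mask = FALSE)
    compute_pttrs(d)$pttrs
  }
  base <- mk(5, 250)
  expect_equal(mk(15, 250), 3 * base, tolerance = 1e-6)
  expect_equal(mk(5, 320), base, tolerance = 1e-6)
})

test_that("duration rule boundary is inclusive and validates input", {
  expect_false(apply_duration_rule(2.9))
  expect_true(apply_duration_rule(3.0))
  expect_true(apply_duration_rule(4.0, min_hours = 4))
  expect_false(apply_duration_rule(3.9, min_hours = 4))
  expect_error(apply_duration_rule(-1), "non-negative")
})

test_that("generator/extractor round trip recovers the configured swing", {
  diffs <- vapply(1:8, function(i) {
    sw <- c(10, 14, 18, 22, 26, 30, 13.7, 20.7)[i]
    p <- subject_profile(swing_amplitude = sw, arousal_rate = 6,
                         desat_rate = 1, study_hours = 1)
    rec <- simulate_subject(p, seed = 50 + i)
    beats <- compute_ptt(rec$r_peaks, rec$pleth)
    art <- remove_ptt_artefact(beats)
    rc <- derive_resp_channel(art$beats, mask = art$beats$mask)
    compute_pttrs(rc)$pttrs - sw
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 1)
  expect_lt(max(abs(diffs)), 2)
})
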