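test_that("profile validation names the offending field", {
  expect_error(subject_profile(swing_amplitude = -1), "swing_amplitude")
  expect_error(subject_profile(ptt_baseline = 100), "ptt_baseline")
  expect_error(subject_profile(artefact_fraction = 1), "artefact_fraction")
  expect_error(subject_profile(study_hours = 0), "study_hours")
  expect_error(subject_profile(baseline_spo2 = 101), "baseline_spo2")
  expect_error(subject_profile(respiratory_rate = 20), "respiratory_rate")
})

test_that("degenerate profile gives a flat PTT trace up to drift and no arousals", {
  p <- subject_profile(arousal_rate = 0, artefact_fraction = 0,
                       swing_amplitude = 0, desat_rate = 0,
                       ptt_noise_sd = 0, study_hours = 0.5)
  rec <- simulate_subject(p, seed = 11)
  expect_identical(rec$truth$n_arousals, 0L)
  beats <- compute_ptt(rec$r_peaks, rec$pleth)
  # drift is a 5-ms-amplitude hour-period sinusoid; over 30 min the trace
  # stays within that envelope around the configured baseline
  expect_lt(diff(range(beats$ptt_raw, na.rm = TRUE)), 12)
  expect_lt(abs(mean(beats$ptt_raw, na.rm = TRUE) - 250), 10)
})

test_that("identical (profile, seed) gives bit-identical recordings", {
  p <- subject_profile("moderate_osa", study_hours = 0.4, desat_rate = 10)
  a <- simulate_subject(p, seed = 99)
  b <- simulate_subject(p, seed = 99)
  expect_identical(a, b)
  c <- simulate_subject(p, seed = 100)
  expect_false(identical(a$pleth$y, c$pleth$y))
})

test_that("video labels are category-consistent", {
  for (sd in 1:4) {
    rec_n <- simulate_subject(subject_profile("normal", study_hours = 0.3,
                                              desat_rate = 0), seed = sd)
    expect_identical(nrow(rec_n$video_labels), 0L)
    expect_false(rec_n$snoring)
    rec_p <- simulate_subject(subject_profile("primary_snoring",
                                              study_hours = 0.3), seed = sd)
    expect_lt(nrow(rec_p$video_labels), 3L)
    expect_true(rec_p$snoring)
    rec_u <- simulate_subject(subject_profile("uars_mild_osa",
                                              study_hours = 0.3), seed = sd)
    expect_gte(sum(rec_u$video_labels$has_arousal), 3L)
  }
})

test_that("artefact injection with fraction 0 is the identity", {
  p <- subject_profile(study_hours = 0.3)
  rec <- simulate_subject(p, seed = 5)
  expect_identical(inject_artefacts(rec, 0), rec)
  expect_error(inject_artefacts(rec, 1), "fraction")
})

test_that("heavy artefact forces exclusion under the 3-h rule", {
  p <- subject_profile("primary_snoring", study_hours = 5)
  rec <- simulate_subject(p, seed = 7)
  bad <- inject_artefacts(rec, 0.6, seed = 8, spo2_fraction = 0.5)
  beats <- compute_ptt(bad$r_peaks, bad$pleth)
  art <- remove_ptt_artefact(beats)
  expect_lt(art$artefact_free_hours, 3)
  expect_false(apply_duration_rule(art$artefact_free_hours))
  ox <- compute_oximetry_summary(bad$spo2)
  expect_lt(ox$valid_hours, 4)
  expect_false(ox$included)
  # the original recording is untouched and fully usable
  art0 <- remove_ptt_artefact(compute_ptt(rec$r_peaks, rec$pleth))
  expect_gt(art0$artefact_free_hours, 4.9)
})

test_that("cohort category draw matches the configured prevalences", {
  mix <- c(normal = 174, primary_snoring = 239, uars_mild_osa = 132,
           moderate_osa = 63, severe_osa = 21) / 629
  profs <- draw_cohort_profiles(629, mix = mix, seed = 1)
  counts <- table(factor(vapply(profs, `[[`, character(1), "category"),
                         levels = names(mix)))
  expected <- 629 * mix
  # within ~3 SD of multinomial sampling error per category
  sds <- sqrt(629 * mix * (1 - mix))
  expect_true(all(abs(counts - expected) <= 3.5 * sds))
  expect_error(draw_cohort_profiles(10, mix = mix * 2, seed = 1), "sum to 1")
})

test_that("point-mass mix yields a single-category cohort", {
  profs <- draw_cohort_profiles(10, mix = c(normal = 1), seed = 3)
  expect_true(all(vapply(profs, `[[`, character(1), "category") == "normal"))
})

test_that("artefact burden distribution reproduces the cohort exclusion structure", {
  profs <- draw_cohort_profiles(3000, seed = 17)
  af <- vapply(profs, function(q) (1 - q$artefact_fraction) * q$study_hours,
               numeric(1))
  oxh <- vapply(profs, function(q) (1 - q$spo2_artefact_fraction) * q$study_hours,
                numeric(1))
  # ~31% lose the 3-h PTT rule; a few percent lose the 4-h oximetry rule
  expect_gt(mean(af < 3), 0.24)
  expect_lt(mean(af < 3), 0.38)
  expect_gt(mean(oxh < 4), 0.005)
  expect_lt(mean(oxh < 4), 0.10)
  # retained studies carry ~4.8 h of artefact-free PTT on average
  expect_gt(mean(af[af >= 3]), 4.2)
  expect_lt(mean(af[af >= 3]), 5.4)
})

test_that("expected extracted swing is monotone in configured swing", {
  pttrs_at <- function(sw) {
    p <- subject_profile(swing_amplitude = sw, arousal_rate = 0,
                         desat_rate = 0, study_hours = 0.5)
    rec <- simulate_subject(p, seed = 31)
    beats <- compute_ptt(rec$r_peaks, rec$pleth)
    rc <- derive_resp_channel(beats)
    compute_pttrs(rc)$pttrs
  }
  vals <- vapply(c(8, 16, 24, 32), pttrs_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})
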