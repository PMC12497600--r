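# Synthetic overnight-recording generator.
#
# The generator writes the quantities the extraction modules are supposed to
# recover directly into the signals: pleth pulse onsets lag each R-peak by a
# PTT series composed of a baseline, a respiratory oscillation, arousal dips
# and slow drift; SpO2 carries flat-bottomed desaturation events. Everything
# injected is recorded in the `truth` element of the returned recording.

PLETH_FS <- 100          # Hz; 10 ms granularity, finer than every rule threshold
PULSE_UPSTROKE <- 0.15   # s, raised-cosine foot-to-peak time
PULSE_DECAY <- 0.12      # s, exponential decay constant after the peak

# Breath-by-breath respiratory oscillation: one -cos cycle per breath
# (inspiratory trough then expiratory peak), 5% CV breath-duration jitter so
# the phase is incommensurate with the 1-Hz resampling grid.
make_breath_grid <- function(dur, respiratory_rate) {
  Tb <- 60 / respiratory_rate
  nbr <- ceiling(dur / Tb * 1.3) + 10L
  bd <- pmax(stats::rnorm(nbr, Tb, 0.05 * Tb), 0.5 * Tb)
  list(start = c(0, cumsum(bd)), dur = bd)
}

osc_eval <- function(t, grid) {
  k <- pmin(pmax(findInterval(t, grid$start), 1L), length(grid$dur))
  u <- (t - grid$start[k]) / grid$dur[k]
  -cos(2 * pi * u)
}

# Piecewise-linear arousal dips: fall over 10-30 s, short hold, recover.
draw_arousal_events <- function(dur, rate, drop) {
  if (rate <= 0 || drop <= 0) {
    return(data.frame(onset = numeric(0), fall = numeric(0),
                      hold = numeric(0), recover = numeric(0),
                      drop = numeric(0)))
  }
  n <- stats::rpois(1, rate * dur / 3600)
  if (n == 0L) return(draw_arousal_events(dur, 0, drop))
  onset <- sort(stats::runif(n, 120, max(121, dur - 200)))
  keep <- c(TRUE, diff(onset) > 120)       # no overlapping arousals
  onset <- onset[keep]
  m <- length(onset)
  data.frame(onset = onset,
             fall = stats::runif(m, 8, 25),
             hold = stats::runif(m, 1, 3),
             recover = stats::runif(m, 10, 20),
             drop = rep(drop, m))
}

dip_eval <- function(t, ev) {
  out <- numeric(length(t))
  if (nrow(ev) == 0L) return(out)
  for (j in seq_len(nrow(ev))) {
    on <- ev$onset[j]; f <- ev$fall[j]; h <- ev$hold[j]; r <- ev$recover[j]
    idx <- which(t >= on & t <= on + f + h + r)
    if (!length(idx)) next
    tt <- t[idx] - on
    d <- ifelse(tt < f, tt / f,
                ifelse(tt < f + h, 1, 1 - (tt - f - h) / r))
    out[idx] <- out[idx] - ev$drop[j] * d
  }
  out
}

#' End-to-end gain of the respiratory-channel smoothing chain
#'
#' The derived respiratory channel (1-Hz interpolation plus 3-sample moving
#' mean of beat-sampled PTT) attenuates a respiratory oscillation by a factor
#' that depends on heart rate and breathing frequency. The generator measures
#' this gain empirically by pushing a noise-free unit oscillation through
#' [derive_resp_channel()] and [compute_pttrs()] on a short calibration
#' segment, and scales the injected oscillation by its inverse so that the
#' extracted PTTrs matches the configured trough-to-peak swing.
#'
#' @param heart_rate bpm.
#' @param respiratory_rate breaths/min.
#' @param cal_seconds calibration segment length, s.
#' @return scalar gain in (0, 1]: extracted swing / injected swing.
#' @export
resp_chain_gain <- function(heart_rate, respiratory_rate, cal_seconds = 600) {
  rr <- 60 / heart_rate
  rpk <- cumsum(pmax(stats::rnorm(ceiling(cal_seconds / rr) + 5L, rr, 0.03 * rr),
                     0.3 * rr))
  rpk <- rpk[rpk < cal_seconds]
  grid <- make_breath_grid(cal_seconds, respiratory_rate)
  ptt <- 250 + 10 * osc_eval(rpk, grid)
  beats <- data.frame(beat_time = rpk, ptt_raw = ptt, valid = TRUE)
  rc <- derive_resp_channel(beats)
  res <- compute_pttrs(rc, prominence = 0.5)
  g <- res$pttrs / 20
  if (!is.finite(g) || g <= 0.02) {
    stop("respiratory oscillation does not survive the smoothing chain at ",
         respiratory_rate, " breaths/min", call. = FALSE)
  }
  min(g, 1)
}

#' Simulate one overnight multi-channel recording
#'
#' Generates R-peak times (jittered R-R intervals), a 100-Hz plethysmograph
#' whose pulse upstrokes lag each R-peak by the subject's time-varying PTT,
#' a 1-Hz integer SpO2 trace with flat-bottomed desaturation events, and
#' category-consistent video-surrogate obstruction labels. The injected PTT
#' series is `ptt_baseline` plus a respiratory oscillation (scaled by the
#' inverse of [resp_chain_gain()] so the extracted PTTrs targets
#' `swing_amplitude`), arousal dips of `arousal_drop` ms developing over
#' 10-30 s, and a slow 5-ms sinusoidal drift.
#'
#' @param profile a [subject_profile()].
#' @param seed integer seed; identical (profile, seed) pairs give identical
#'   recordings.
#' @return an object of class `sleep_recording`: list with `r_peaks` (s),
#'   `pleth` (list of `fs`, `y`), `spo2` (integer percent at 1 Hz),
#'   `duration` (s), `snoring`, `video_labels` (data.frame `start`, `end`,
#'   `has_arousal`) and `truth` (injected ground truth).
#' @examples
#' rec <- simulate_subject(subject_profile(study_hours = 0.5), seed = 7)
#' range(rec$spo2)
#' @export
simulate_subject <- function(profile, seed = 1L) {
  validate_profile(profile)
  set.seed(seed)
  dur <- profile$study_hours * 3600

  # R-peaks: 3% CV jitter exercises beat alignment without moving thresholds
  rr <- 60 / profile$heart_rate
  rri <- pmax(stats::rnorm(ceiling(dur / rr * 1.1) + 10L, rr, 0.03 * rr), 0.3 * rr)
  rpk <- cumsum(rri)
  rpk <- rpk[rpk < dur - 1.5]

  gain <- if (profile$swing_amplitude > 0) {
    resp_chain_gain(profile$heart_rate, profile$respiratory_rate)
  } else 1
  amp <- profile$swing_amplitude / (2 * gain)

  grid <- make_breath_grid(dur, profile$respiratory_rate)
  arousals <- draw_arousal_events(dur, profile$arousal_rate, profile$arousal_drop)
  drift_phase <- stats::runif(1, 0, 2 * pi)

  ptt_beats <- profile$ptt_baseline +
    amp * osc_eval(rpk, grid) +
    dip_eval(rpk, arousals) +
    5 * sin(2 * pi * rpk / 3600 + drift_phase) +
    stats::rnorm(length(rpk), 0, profile$ptt_noise_sd)

  # Plethysmograph: each pulse starts at zero at its foot, raised-cosine
  # upstroke (the 50% point is exactly foot + 75 ms), then exponential decay.
  foot <- rpk + ptt_beats / 1000 - PULSE_UPSTROKE / 2
  foot <- foot[foot > 0]
  tt <- seq(0, dur, by = 1 / PLETH_FS)
  idx <- findInterval(tt, foot)
  phase <- tt - foot[pmax(idx, 1L)]
  y <- numeric(length(tt))
  up <- idx >= 1L & phase < PULSE_UPSTROKE
  y[up] <- 0.5 * (1 - cos(pi * phase[up] / PULSE_UPSTROKE))
  dec <- idx >= 1L & phase >= PULSE_UPSTROKE
  y[dec] <- exp(-(phase[dec] - PULSE_UPSTROKE) / PULSE_DECAY)
  y <- y + stats::rnorm(length(y), 0, 0.005)

  spo2_truth <- draw_desat_events(dur, profile)
  spo2 <- spo2_truth$spo2

  vl <- draw_video_labels(dur, profile)

  structure(list(
    r_peaks = rpk,
    pleth = list(fs = PLETH_FS, y = y),
    spo2 = spo2,
    duration = dur,
    snoring = vl$snoring,
    video_labels = vl$episodes,
    truth = list(
      profile = profile,
      n_arousals = nrow(arousals),
      arousal_events = arousals,
      n_desats = nrow(spo2_truth$events),
      n_below_80 = sum(spo2_truth$events$nadir < 80),
      desat_events = spo2_truth$events,
      injected_amplitude = amp,
      chain_gain = gain,
      seed = seed)
  ), class = "sleep_recording")
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf(
    "<sleep_recording> %.1f h | %d beats | %d desats | %d arousals | %s\n",
    x$duration / 3600, length(x$r_peaks), x$truth$n_desats,
    x$truth$n_arousals, x$truth$profile$category))
  invisible(x)
}

# Flat-bottomed (trapezoidal) desaturations: 20% fall, 60% hold at an
# integer nadir, 20% recovery, so the time spent >= 4 points below baseline
# comfortably satisfies the >5 s / <180 s counting rule.
draw_desat_events <- function(dur, profile) {
  dur <- floor(dur)
  base <- round(profile$baseline_spo2)
  s <- profile$baseline_spo2 + stats::rnorm(dur, 0, profile$spo2_noise_sd)
  n <- if (profile$desat_rate > 0) stats::rpois(1, profile$desat_rate * dur / 3600) else 0L
  events <- data.frame(start = numeric(0), end = numeric(0),
                       nadir = numeric(0), duration = numeric(0))
  if (n > 0L) {
    onset <- sort(stats::runif(n, 150, max(151, dur - 250)))
    d <- pmin(pmax(stats::rnorm(n, profile$desat_duration,
                                0.2 * profile$desat_duration), 12), 170)
    keep <- c(TRUE, diff(onset) > 30 + d[-length(d)])
    onset <- onset[keep]; d <- d[keep]
    depth <- pmax(round(stats::rnorm(length(onset), profile$desat_depth, 1.5)), 4)
    nadir <- pmax(base - depth, 55)
    for (j in seq_along(onset)) {
      f <- 0.2 * d[j]; h <- 0.6 * d[j]
      idx <- which(seq_len(dur) - 1 >= onset[j] & seq_len(dur) - 1 <= onset[j] + d[j])
      if (!length(idx)) next
      tt <- (idx - 1) - onset[j]
      frac <- ifelse(tt < f, tt / f, ifelse(tt < f + h, 1, (d[j] - tt) / (d[j] - f - h)))
      s[idx] <- nadir[j] + (1 - pmin(pmax(frac, 0), 1)) * (profile$baseline_spo2 - nadir[j]) +
        stats::rnorm(length(idx), 0, profile$spo2_noise_sd)
    }
    events <- data.frame(start = onset, end = onset + d, nadir = nadir, duration = d)
  }
  list(spo2 = as.integer(round(pmin(pmax(s, 0), 100))), events = events)
}

draw_video_labels <- function(dur, profile) {
  n <- profile$n_obstructive
  if (is.null(n)) {
    n <- switch(profile$category,
                normal = 0L,
                primary_snoring = sample(0:2, 1),
                uars_mild_osa = 3L + stats::rpois(1, 4),
                moderate_osa = 3L + stats::rpois(1, 6),
                severe_osa = 4L + stats::rpois(1, 8),
                abnormal_other = 0L)
  }
  snoring <- profile$category != "normal" && profile$category != "abnormal_other"
  if (n == 0L) {
    return(list(snoring = snoring,
                episodes = data.frame(start = numeric(0), end = numeric(0),
                                      has_arousal = logical(0))))
  }
  start <- sort(stats::runif(n, 60, max(61, dur - 120)))
  len <- stats::runif(n, 15, 60)
  arous <- switch(profile$category,
                  uars_mild_osa = rep(TRUE, n),
                  moderate_osa = seq_len(n) <= max(1L, ceiling(0.8 * n)),
                  severe_osa = seq_len(n) <= max(1L, ceiling(0.8 * n)),
                  rep(FALSE, n))
  list(snoring = snoring,
       episodes = data.frame(start = start, end = start + len, has_arousal = arous))
}

# Random non-overlapping artefact windows totalling ~ fraction * duration.
draw_artefact_windows <- function(dur, fraction) {
  target <- fraction * dur
  if (target <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  lens <- numeric(0); total <- 0
  while (total < target) {
    L <- 30 + stats::rexp(1, 1 / 90)
    lens <- c(lens, L); total <- total + L
  }
  lens[length(lens)] <- max(5, lens[length(lens)] - (total - target))
  k <- length(lens)
  free <- dur - sum(lens)
  if (free < 0) { lens <- lens * dur / sum(lens) * 0.98; free <- dur - sum(lens) }
  g <- stats::runif(k + 1)
  gaps <- free * g / sum(g)
  start <- cumsum(gaps[seq_len(k)] + c(0, lens[-k]))
  data.frame(start = start, end = start + lens)
}

#' Inject plethysmograph and SpO2 artefact into a recording
#'
#' Corrupts approximately `fraction` of the study time on the
#' plethysmograph (alternating signal dropout and broadband noise bursts,
#' which produce PTT jumps well above the 50-ms spike rule, typically
#' >100 ms) and `spo2_fraction` of the SpO2 trace (implausible low, jumpy
#' readings caught by the saturation artefact mask). The input recording is
#' not modified.
#'
#' @param recording a `sleep_recording`.
#' @param fraction proportion of study time with plethysmograph artefact,
#'   in `[0, 1)`.
#' @param seed integer seed.
#' @param spo2_fraction proportion with SpO2 artefact; defaults to `fraction`.
#' @return a new `sleep_recording` with corrupted signals; the artefact
#'   windows are recorded under `artefact_windows`.
#' @export
inject_artefacts <- function(recording, fraction, seed = 1L,
                             spo2_fraction = fraction) {
  stopifnot(inherits(recording, "sleep_recording"))
  check_field(fraction >= 0 && fraction < 1, "fraction", "must lie in [0, 1)")
  check_field(spo2_fraction >= 0 && spo2_fraction < 1, "spo2_fraction",
              "must lie in [0, 1)")
  if (fraction == 0 && spo2_fraction == 0) return(recording)
  set.seed(seed)
  rec <- recording
  dur <- rec$duration
  pw <- draw_artefact_windows(dur, fraction)
  if (nrow(pw)) {
    fs <- rec$pleth$fs
    for (j in seq_len(nrow(pw))) {
      i0 <- max(1L, floor(pw$start[j] * fs)); i1 <- min(length(rec$pleth$y), ceiling(pw$end[j] * fs))
      if (i1 <= i0) next
      rec$pleth$y[i0:i1] <- if (j %% 2L == 0L) 0 else stats::runif(i1 - i0 + 1L, 0, 1)
    }
  }
  sw <- draw_artefact_windows(dur, spo2_fraction)
  if (nrow(sw)) {
    for (j in seq_len(nrow(sw))) {
      i0 <- max(1L, floor(sw$start[j])); i1 <- min(length(rec$spo2), ceiling(sw$end[j]))
      if (i1 <= i0) next
      rec$spo2[i0:i1] <- as.integer(round(stats::runif(i1 - i0 + 1L, 25, 45)))
    }
  }
  rec$artefact_windows <- list(pleth = pw, spo2 = sw)
  rec
}

#' Simulate a cohort of synthetic recordings
#'
#' Draws per-subject profiles with [draw_cohort_profiles()] (categories from
#' `mix`, per-category swing/demographic distributions from `params`) and
#' simulates each recording, applying the profile's artefact fractions.
#' Signal-level cohorts are intended for moderate `n`; for the statistical
#' layer at full cohort size use [simulate_feature_cohort()].
#'
#' @inheritParams draw_cohort_profiles
#' @return list of `sleep_recording` objects.
#' @export
simulate_cohort <- function(n, mix = NULL, seed = 1L,
                            params = cohort_parameters(), artefacts = TRUE) {
  profiles <- draw_cohort_profiles(n, mix, seed, params, artefacts)
  set.seed(seed + 1L)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  lapply(seq_len(n), function(i) {
    rec <- simulate_subject(profiles[[i]], seed = seeds[i])
    p <- profiles[[i]]
    if (p$artefact_fraction > 0 || p$spo2_artefact_fraction > 0) {
      rec <- inject_artefacts(rec, p$artefact_fraction, seed = seeds[n + i],
                              spo2_fraction = p$spo2_artefact_fraction)
    }
    rec
  })
}
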