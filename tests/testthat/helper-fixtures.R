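# Shared fixture builders. Signals are constructed in code at test time.

# Plethysmograph with one pulse per programmed delay: raised-cosine upstroke
# (foot -> peak in 150 ms, half-amplitude point exactly foot + 75 ms), then
# exponential decay restarting from zero at each foot.
make_pleth <- function(r_peaks, delays_ms, fs = 100, duration = NULL) {
  if (is.null(duration)) duration <- max(r_peaks) + 2
  foot <- r_peaks + delays_ms / 1000 - 0.075
  tt <- seq(0, duration, by = 1 / fs)
  idx <- findInterval(tt, foot)
  phase <- tt - foot[pmax(idx, 1L)]
  y <- numeric(length(tt))
  up <- idx >= 1L & phase < 0.15
  y[up] <- 0.5 * (1 - cos(pi * phase[up] / 0.15))
  dec <- idx >= 1L & phase >= 0.15
  y[dec] <- exp(-(phase[dec] - 0.15) / 0.12)
  list(fs = fs, y = y)
}

# Beat series at a regular grid with given PTT values, all valid.
make_beats <- function(ptt, dt = 0.6, t0 = 0) {
  data.frame(beat_time = t0 + (seq_along(ptt) - 1) * dt,
             ptt_raw = ptt,
             valid = rep(TRUE, length(ptt)))
}

# PTT2-style series sampled at 1 Hz: baseline with one linear dip of given
# depth (ms) and fall time (s), optional flat hold, then linear recovery.
make_dip_series <- function(depth, fall, hold = 0, recover = 10,
                            pre = 60, post = 60, base = 250) {
  v <- c(rep(base, pre),
         base - depth * seq_len(fall) / fall,
         rep(base - depth, hold),
         base - depth + depth * seq_len(recover) / recover,
         rep(base, post))
  data.frame(beat_time = seq_along(v) - 1, ptt2 = v)
}

# SpO2 trace: constant baseline with flat-bottomed dips. The shoulders sit
# 2-3 points below baseline (never deep enough to qualify), so the
# qualifying run is exactly `holds` seconds long.
make_spo2 <- function(duration, base = 98, onsets = numeric(0),
                      depths = numeric(0), holds = numeric(0)) {
  s <- rep(base, duration)
  for (k in seq_along(onsets)) {
    i0 <- onsets[k]
    shoulder <- base - min(3, ceiling(depths[k] / 2))
    s[i0 + 1] <- shoulder
    s[i0 + 1 + seq_len(holds[k])] <- base - depths[k]
    s[i0 + 2 + holds[k]] <- shoulder
  }
  as.integer(round(s))
}

# Minimal oximetry/ptt stand-ins for categoriser tests.
fake_ox <- function(score, included = TRUE) {
  structure(list(score = as.integer(score), included = included),
            class = "oximetry_summary")
}
fake_ptt <- function(included = TRUE, hours = 5) {
  structure(list(included = included, ptt_duration_hours = hours),
            class = "ptt_summary")
}

# One cached artefact-free signal-level cohort shared across test files.
cohort_cache <- new.env(parent = emptyenv())
cached_clean_cohort <- function() {
  if (is.null(cohort_cache$recs)) {
    pars <- cohort_parameters()
    pars$study_hours <- c(mean = 4, sd = 0.2)
    cohort_cache$recs <- simulate_cohort(20, seed = 424, params = pars,
                                         artefacts = FALSE)
  }
  cohort_cache$recs
}
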