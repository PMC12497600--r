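# Beat-wise PTT extraction and the derived channels: the smoothed PTT2
# series used for arousal detection and the 1-Hz respiratory channel whose
# trough-to-peak swing is PTTrs.

#' Compute beat-wise pulse transit time
#'
#' For each ECG R-peak, finds the next plethysmograph pulse and measures the
#' time to the point where the upstroke crosses 50% of the pulse amplitude
#' (pulse peak minus pulse foot), interpolated between samples. Beats whose
#' PTT falls outside `valid_range` are marked invalid; an R-peak with no
#' pulse within `max_lag` seconds is marked invalid (signal dropout), never
#' an error.
#'
#' @param r_peaks strictly increasing R-peak times, s.
#' @param pleth list with elements `fs` (sampling rate, Hz) and `y`
#'   (waveform samples starting at t = 0).
#' @param valid_range physiologically valid PTT range, ms.
#' @param max_lag maximum R-peak-to-pulse lag, s.
#' @return a `beat_series` data.frame: `beat_time` (s), `ptt_raw` (ms, `NA`
#'   on dropout) and `valid`.
#' @export
compute_ptt <- function(r_peaks, pleth, valid_range = c(150, 500), max_lag = 2) {
  if (length(r_peaks) == 0L) stop("`r_peaks` is empty", call. = FALSE)
  if (is.null(pleth$y) || length(pleth$y) < 10L) {
    stop("`pleth` must supply a waveform (`y`) and sampling rate (`fs`)",
         call. = FALSE)
  }
  if (any(diff(r_peaks) <= 0)) {
    stop("`r_peaks` must be strictly increasing", call. = FALSE)
  }
  fs <- pleth$fs
  ysm <- mov_mean(pleth$y, 5L)
  n <- length(ysm)

  # candidate pulses: upward crossings of the half-amplitude reference level
  above <- ysm >= 0.5
  ci <- which(!above[-n] & above[-1]) + 1L
  ptt_na <- data.frame(beat_time = r_peaks,
                       ptt_raw = rep(NA_real_, length(r_peaks)),
                       valid = rep(FALSE, length(r_peaks)))
  class(ptt_na) <- c("beat_series", "data.frame")
  if (length(ci) == 0L) return(ptt_na)

  # pulse foot = minimum over the 150 ms before the crossing,
  # pulse peak = maximum over the 150 ms after it
  win <- ceiling(0.15 * fs)
  foot_v <- rep(Inf, length(ci))
  for (o in seq_len(win)) foot_v <- pmin(foot_v, ysm[pmax(ci - o, 1L)])
  peak_v <- rep(-Inf, length(ci))
  for (o in 0:win) peak_v <- pmax(peak_v, ysm[pmin(ci + o, n)])
  lev <- foot_v + 0.5 * (peak_v - foot_v)

  # sub-sample 50%-crossing: first sample at or above the level near the
  # reference crossing, linearly interpolated against its predecessor
  offs <- -(win - 1L):4L
  idx_mat <- outer(ci, offs, `+`)
  idx_mat[idx_mat < 1L] <- 1L
  idx_mat[idx_mat > n] <- n
  Y <- matrix(ysm[idx_mat], nrow = length(ci))
  ge <- Y >= lev
  k <- max.col(ge, ties.method = "first")
  has <- ge[cbind(seq_along(ci), k)] & k > 1L
  j1 <- ci + offs[pmax(k, 2L)]
  j0 <- j1 - 1L
  dy <- ysm[j1] - ysm[j0]
  t_star <- ((j0 - 1L) + (lev - ysm[j0]) / ifelse(abs(dy) < 1e-12, NA, dy)) / fs
  t_star <- t_star[has & is.finite(t_star)]
  t_star <- sort(t_star)
  if (length(t_star) == 0L) return(ptt_na)

  pos <- findInterval(r_peaks, t_star) + 1L
  ptt_raw <- rep(NA_real_, length(r_peaks))
  ok <- pos <= length(t_star)
  ptt_raw[ok] <- (t_star[pos[ok]] - r_peaks[ok]) * 1000
  ptt_raw[!is.na(ptt_raw) & ptt_raw > max_lag * 1000] <- NA_real_
  valid <- !is.na(ptt_raw) & ptt_raw >= valid_range[1] & ptt_raw <= valid_range[2]
  out <- data.frame(beat_time = r_peaks, ptt_raw = ptt_raw, valid = valid)
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Smooth raw PTT into the PTT2 channel
#'
#' Centred 17-beat moving mean of the raw PTT restricted to valid beats; the
#' window shrinks at the series edges and PTT2 is defined wherever the
#' window contains at least one valid beat.
#'
#' @param beats a `beat_series` from [compute_ptt()].
#' @param points averaging window in beats.
#' @return data.frame `beat_time`, `ptt2`.
#' @export
smooth_ptt2 <- function(beats, points = 17L) {
  x <- ifelse(beats$valid, beats$ptt_raw, NA_real_)
  data.frame(beat_time = beats$beat_time, ptt2 = mov_mean(x, as.integer(points)))
}

#' Mask PTT spike artefact and measure artefact-free time
#'
#' Samples adjacent to a jump of more than `spike_threshold` ms between
#' consecutive raw PTT values are masked together with a guard interval of
#' `guard` seconds on each side, mimicking manual exclusion of a corrupted
#' region. Artefact-free time is the summed spacing between consecutive
#' clean beats, ignoring gaps longer than `max_gap` seconds (signal
#' dropout carries no usable PTT).
#'
#' @param beats a `beat_series`.
#' @param spike_threshold jump size defining a spike, ms.
#' @param guard guard interval masked each side of a spike, s.
#' @param max_gap largest inter-beat spacing counted as covered, s.
#' @return list with `beats` (input plus logical `mask` column) and
#'   `artefact_free_hours`.
#' @export
remove_ptt_artefact <- function(beats, spike_threshold = 50, guard = 10,
                                max_gap = 2) {
  t <- beats$beat_time
  x <- beats$ptt_raw
  n <- length(x)
  mask <- rep(FALSE, n)
  if (n >= 2L) {
    d <- abs(diff(x))
    jumps <- which(!is.na(d) & d > spike_threshold)
    if (length(jumps)) {
      # merge overlapping guard intervals, then mask by interval lookup
      lo <- t[jumps] - guard
      hi <- t[jumps + 1L] + guard
      hi_run <- cummax(hi)
      new_iv <- c(TRUE, lo[-1L] > hi_run[-length(hi_run)])
      grp <- cumsum(new_iv)
      m_lo <- lo[new_iv]
      m_hi <- as.numeric(tapply(hi, grp, max))
      pos <- findInterval(t, m_lo)
      mask <- pos >= 1L & t <= m_hi[pmax(pos, 1L)]
    }
  }
  good <- which(!mask & !is.na(x))
  af <- 0
  if (length(good) >= 2L) {
    dt <- diff(t[good])
    af <- sum(dt[dt <= max_gap]) / 3600
  }
  out <- beats
  out$mask <- mask
  list(beats = out, artefact_free_hours = af)
}

#' Detect PTT arousals on the PTT2 channel
#'
#' An arousal is a drop in PTT2 of at least `drop_threshold` ms whose
#' descent (running maximum to trough) develops over `window[1]` to
#' `window[2]` seconds, with every sample inside the valid PTT range and
#' unmasked.
#'
#' A sample is inside an arousal when PTT2 sits at least `drop_threshold`
#' ms below its maximum over the preceding `window[1]` to `window[2]`
#' seconds (upper lag bound exclusive, so a threshold drop that needs the
#' full 45 s - e.g. a slow ramp - does not count) and the drop did not
#' already occur entirely within the last `window[1]` seconds (which would
#' be a spike, not a developing arousal). Contiguous qualifying samples -
#' and fragments separated by less than `merge_gap` seconds, as happens
#' when respiratory ripple rides on the descent - merge into one event, so
#' one physiological arousal is never counted twice.
#'
#' @param ptt2 data.frame `beat_time`, `ptt2` from [smooth_ptt2()].
#' @param mask optional logical artefact mask aligned with `ptt2` rows.
#' @param drop_threshold minimum drop, ms.
#' @param window permissible drop development window, s.
#' @param valid_range valid PTT2 range, ms.
#' @param merge_gap qualifying fragments closer than this merge, s.
#' @param artefact_free_hours denominator for the arousal index; when `NULL`
#'   or zero the index is returned as `NA` and flagged.
#' @return list with `events` (data.frame `start`, `end`, `drop`), `n`,
#'   `ptt_ai` (events/h) and `flagged`.
#' @export
detect_ptt_arousals <- function(ptt2, mask = NULL, drop_threshold = 15,
                                window = c(5, 45), valid_range = c(150, 500),
                                merge_gap = 15,
                                artefact_free_hours = NULL) {
  t <- ptt2$beat_time
  x <- ptt2$ptt2
  usable <- is.finite(x) & x >= valid_range[1] & x <= valid_range[2]
  if (!is.null(mask)) usable <- usable & !mask
  ev_start <- numeric(0); ev_end <- numeric(0); ev_drop <- numeric(0)
  for (run in contiguous_runs(usable)) {
    # break runs at inter-beat gaps > 5 s (unbridgeable dropout)
    gaps <- which(diff(t[run]) > 5)
    pieces <- if (length(gaps)) split(run, findInterval(seq_along(run), gaps + 1L)) else list(run)
    for (piece in pieces) {
      m <- length(piece)
      if (m < 3L) next
      tp <- t[piece]; xp <- x[piece]
      st <- sparse_max_table(xp)
      i <- seq_len(m)
      a <- findInterval(tp - window[2], tp) + 1L   # first sample with lag < window[2]
      b <- findInterval(tp - window[1], tp)        # last sample with lag >= window[1]
      far_ok <- a <= b
      far_idx <- rep(NA_integer_, m)
      far_idx[far_ok] <- st$query(a[far_ok], b[far_ok])
      drop_far <- xp[far_idx] - xp
      cc <- b + 1L                                 # first sample with lag < window[1]
      d <- i - 1L
      near_ok <- cc <= d & cc >= 1L
      fast <- rep(-Inf, m)
      fast[near_ok] <- xp[st$query(cc[near_ok], d[near_ok])] - xp[near_ok]
      qual <- far_ok & !is.na(drop_far) & drop_far >= drop_threshold &
        fast < drop_threshold
      if (!any(qual)) next
      qi <- which(qual)
      new_ev <- c(TRUE, diff(tp[qi]) > merge_gap)
      grp <- cumsum(new_ev)
      for (g in unique(grp)) {
        gi <- qi[grp == g]
        ev_start <- c(ev_start, tp[far_idx[gi[1]]])
        ev_end <- c(ev_end, tp[gi[length(gi)]])
        ev_drop <- c(ev_drop, max(drop_far[gi]))
      }
    }
  }
  o <- order(ev_start)
  events <- data.frame(start = ev_start[o], end = ev_end[o], drop = ev_drop[o])
  flagged <- is.null(artefact_free_hours) || !is.finite(artefact_free_hours) ||
    artefact_free_hours <= 0
  ai <- if (flagged) NA_real_ else nrow(events) / artefact_free_hours
  list(events = events, n = nrow(events), ptt_ai = ai, flagged = flagged)
}

#' Derive the 1-Hz respiratory PTT channel
#'
#' Linearly interpolates the valid raw PTT onto a 1-s grid and applies a
#' centred 3-sample moving mean. Grid samples bridging an inter-beat gap
#' longer than `max_gap` seconds, or falling in a masked region, are masked.
#'
#' @param beats a `beat_series`.
#' @param mask optional per-beat artefact mask (from [remove_ptt_artefact()]).
#' @param max_gap largest inter-beat gap interpolated across, s.
#' @param smooth apply the 3-sample moving mean (disable to inspect the raw
#'   interpolated channel).
#' @return a `resp_channel` data.frame: `time` (s), `value` (ms), `mask`.
#' @export
derive_resp_channel <- function(beats, mask = NULL, max_gap = 2, smooth = TRUE) {
  use <- beats$valid & is.finite(beats$ptt_raw)
  if (!is.null(mask)) use <- use & !mask
  bt <- beats$beat_time[use]
  bx <- beats$ptt_raw[use]
  if (length(bt) < 2L) stop("fewer than 2 valid beats", call. = FALSE)
  grid <- seq(ceiling(bt[1]), floor(bt[length(bt)]), by = 1)
  v <- stats::approx(bt, bx, xout = grid, ties = "ordered")$y
  pos <- findInterval(grid, bt)
  pos <- pmin(pmax(pos, 1L), length(bt) - 1L)
  gmask <- (bt[pos + 1L] - bt[pos]) > max_gap
  v[gmask] <- NA_real_
  val <- if (smooth) mov_mean(v, 3L) else v
  val[gmask] <- NA_real_
  out <- data.frame(time = grid, value = val, mask = gmask | !is.finite(val))
  class(out) <- c("resp_channel", "data.frame")
  out
}

#' PTT respiratory swing (PTTrs)
#'
#' Identifies successive trough/peak pairs of the respiratory channel
#' (alternating extrema with minimum prominence `prominence` ms and at least
#' `min_sep` seconds from trough to peak) and returns the mean respiratory
#' rise from inspiratory trough to expiratory peak, in ms.
#'
#' @param resp a `resp_channel` from [derive_resp_channel()].
#' @param prominence minimum extremum prominence, ms.
#' @param min_sep minimum trough-to-peak separation, s.
#' @return list with `pttrs` (ms; 0 when no breath cycle is detectable,
#'   with `flagged = TRUE` and a warning), `n_breaths`, `flagged`.
#' @export
compute_pttrs <- function(resp, prominence = 1, min_sep = 1) {
  keep <- !resp$mask & is.finite(resp$value)
  rises <- numeric(0)
  for (run in contiguous_runs(keep)) {
    if (length(run) < 3L) next
    ex <- zigzag_extrema(resp$time[run], resp$value[run], prominence)
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      if (ex$type[i] == -1L && ex$type[i + 1L] == 1L &&
          ex$time[i + 1L] - ex$time[i] >= min_sep) {
        rises <- c(rises, ex$value[i + 1L] - ex$value[i])
      }
    }
  }
  if (length(rises) == 0L) {
    warning("no detectable breath cycle in respiratory channel")
    return(list(pttrs = 0, n_breaths = 0L, flagged = TRUE))
  }
  list(pttrs = mean(rises), n_breaths = length(rises), flagged = FALSE)
}

#' Minimum artefact-free PTT duration rule
#'
#' Studies with less than `min_hours` of artefact-free PTT are excluded;
#' the boundary is inclusive (exactly `min_hours` hours is included). The
#' default of 3 h supports the primary analysis; 4 h reproduces the
#' duration sensitivity analysis.
#'
#' @param artefact_free_hours hours of artefact-free PTT.
#' @param min_hours inclusion threshold, h.
#' @return logical: included?
#' @export
apply_duration_rule <- function(artefact_free_hours, min_hours = 3) {
  if (!is.finite(artefact_free_hours) || artefact_free_hours < 0) {
    stop("`artefact_free_hours` must be a non-negative number", call. = FALSE)
  }
  artefact_free_hours >= min_hours
}

#' Per-subject PTT summary
#'
#' Runs the full PTT chain on a recording: beat-wise PTT, spike masking,
#' PTT2 smoothing, arousal detection, respiratory channel and PTTrs, and
#' the minimum-duration rule.
#'
#' @param recording a `sleep_recording`.
#' @param min_hours minimum artefact-free PTT hours for inclusion.
#' @param spike_threshold spike rule, ms.
#' @param drop_threshold arousal drop rule, ms.
#' @param window arousal descent window, s.
#' @param valid_range valid PTT range, ms.
#' @return a `ptt_summary` list: `pttrs`, `ptt_ai`, `n_arousals`,
#'   `ptt_duration_hours`, `included`, `flagged`.
#' @export
ptt_summary <- function(recording, min_hours = 3, spike_threshold = 50,
                        drop_threshold = 15, window = c(5, 45),
                        valid_range = c(150, 500)) {
  beats <- compute_ptt(recording$r_peaks, recording$pleth,
                       valid_range = valid_range)
  art <- remove_ptt_artefact(beats, spike_threshold = spike_threshold)
  p2 <- smooth_ptt2(art$beats)
  ar <- detect_ptt_arousals(p2, mask = art$beats$mask,
                            drop_threshold = drop_threshold, window = window,
                            valid_range = valid_range,
                            artefact_free_hours = art$artefact_free_hours)
  pttrs <- list(pttrs = NA_real_, flagged = TRUE)
  n_valid <- sum(art$beats$valid & !art$beats$mask, na.rm = TRUE)
  if (n_valid >= 2L) {
    rc <- derive_resp_channel(art$beats, mask = art$beats$mask)
    pttrs <- tryCatch(suppressWarnings(compute_pttrs(rc)),
                      error = function(e) list(pttrs = NA_real_, flagged = TRUE))
  }
  structure(list(
    pttrs = pttrs$pttrs,
    ptt_ai = ar$ptt_ai,
    n_arousals = ar$n,
    ptt_duration_hours = art$artefact_free_hours,
    included = apply_duration_rule(art$artefact_free_hours, min_hours),
    flagged = isTRUE(pttrs$flagged) || ar$flagged
  ), class = "ptt_summary")
}
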