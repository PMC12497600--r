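# Desaturation-event detection, ODI3/ODI4, the 4-h validity rule and the
# four-level oximetry severity score.

#' Mask implausible SpO2 samples
#'
#' Motion/low-perfusion artefact shows as implausibly low or jumpy
#' readings: samples below `floor` percent, non-finite samples, and both
#' sides of a sample-to-sample jump larger than `jump` points are masked.
#'
#' @param spo2 1-Hz SpO2 trace, percent.
#' @param floor lowest credible saturation, percent.
#' @param jump largest credible change between consecutive seconds, points.
#' @return logical mask, `TRUE` = artefact.
#' @export
mask_spo2_artefact <- function(spo2, floor = 50, jump = 4) {
  m <- !is.finite(spo2) | spo2 < floor
  if (length(spo2) >= 2L) {
    d <- abs(diff(spo2))
    big <- which(is.finite(d) & d > jump)
    m[big] <- TRUE
    m[big + 1L] <- TRUE
  }
  m
}

# Running baseline: q-th percentile of the preceding `window` (s) of
# unmasked samples, on integer-rounded values (incremental histogram;
# re-evaluated every `step` samples since the baseline drifts slowly).
running_baseline <- function(spo2, mask, window = 300, q = 0.9,
                             min_samples = 10, step = 5L) {
  n <- length(spo2)
  s <- pmin(pmax(round(spo2), 0L), 100L)
  base <- rep(NA_real_, n)
  counts <- integer(101L)
  m <- 0L
  last <- NA_real_
  for (i in seq_len(n)) {
    j <- i - 1L
    if (j >= 1L && !mask[j] && is.finite(s[j])) {
      counts[s[j] + 1L] <- counts[s[j] + 1L] + 1L
      m <- m + 1L
    }
    j <- i - window - 1L
    if (j >= 1L && !mask[j] && is.finite(s[j])) {
      counts[s[j] + 1L] <- counts[s[j] + 1L] - 1L
      m <- m - 1L
    }
    if (m >= min_samples) {
      if (i %% step == 1L || is.na(last)) {
        need <- ceiling(q * m)
        last <- which(cumsum(counts) >= need)[1] - 1L
      }
      base[i] <- last
    } else {
      last <- NA_real_
    }
  }
  base
}

#' Detect oxygen desaturation events
#'
#' An event is a maximal run of unmasked samples whose saturation sits more
#' than `drop_threshold` percent below the running baseline (90th percentile
#' of the preceding 120 s of unmasked samples), lasting more than 5 s and
#' less than 180 s. On integer-valued oximeter output a strict ">3%" drop
#' means a fall of at least 4 points (`integer_drop = TRUE`, the default);
#' set `integer_drop = FALSE` for a continuous strict-inequality threshold.
#'
#' @param spo2 1-Hz SpO2 trace, percent.
#' @param drop_threshold drop defining an event, percent (3 for ODI3, 4 for
#'   ODI4).
#' @param mask logical artefact mask (`TRUE` = artefact); default none.
#' @param integer_drop interpret the threshold on integer data (fall of at
#'   least `drop_threshold + 1` points).
#' @param min_duration,max_duration strict duration bounds, s.
#' @param baseline_window,baseline_quantile running-baseline parameters; the
#'   5-min window keeps the baseline stable across even the longest
#'   countable event, so the 180-s rule keeps its bite.
#' @return data.frame with one row per event: `start`, `end` (s), `baseline`,
#'   `nadir`, `depth` (percent), `duration` (s).
#' @export
detect_desats <- function(spo2, drop_threshold = 3, mask = NULL,
                          integer_drop = TRUE,
                          min_duration = 5, max_duration = 180,
                          baseline_window = 300, baseline_quantile = 0.9) {
  n <- length(spo2)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      baseline = numeric(0), nadir = numeric(0),
                      depth = numeric(0), duration = numeric(0))
  if (n == 0L) return(empty)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (all(mask)) return(empty)
  base <- running_baseline(spo2, mask, window = baseline_window,
                           q = baseline_quantile)
  drop <- base - spo2
  qual <- if (integer_drop) {
    !mask & is.finite(drop) & drop >= drop_threshold + 1
  } else {
    !mask & is.finite(drop) & drop > drop_threshold
  }
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths > min_duration & r$lengths < max_duration)
  if (!length(sel)) return(empty)
  out <- lapply(sel, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    nad <- min(spo2[i0:i1])
    b <- base[i0]
    data.frame(start = i0 - 1, end = i1, baseline = b, nadir = nad,
               depth = b - nad, duration = i1 - i0 + 1)
  })
  do.call(rbind, out)
}

#' Four-level oximetry severity score
#'
#' Score 1 when neither ODI3 >= `odi3_threshold` nor ODI4 >=
#' `odi4_threshold` (normal or inconclusive oximetry); otherwise score 2
#' with no saturation episode below 80%, score 3 with one or two, and score
#' 4 with three or more. Episodes below 80% are counted per detected
#' desaturation event whose nadir is below 80%.
#'
#' @param odi3,odi4 desaturation indices, events/h (or an `oximetry_summary`
#'   as the first argument).
#' @param min_spo2 minimum unmasked saturation, percent.
#' @param n_below_80 number of counted desaturation events with nadir < 80%.
#' @param odi3_threshold,odi4_threshold abnormality gates, events/h.
#' @return integer score 1-4 (vectorised).
#' @export
oximetry_score <- function(odi3, odi4 = NULL, min_spo2 = NULL,
                           n_below_80 = NULL,
                           odi3_threshold = 7, odi4_threshold = 4) {
  if (inherits(odi3, "oximetry_summary")) {
    s <- odi3
    return(oximetry_score(s$odi3, s$odi4, s$min_spo2, s$n_below_80,
                          odi3_threshold, odi4_threshold))
  }
  gate <- (is.finite(odi3) & odi3 >= odi3_threshold) |
    (is.finite(odi4) & odi4 >= odi4_threshold)
  score <- ifelse(!gate, 1L,
                  ifelse(n_below_80 >= 3, 4L,
                         ifelse(n_below_80 >= 1 | min_spo2 < 80, 3L, 2L)))
  score[!is.finite(odi3) & !is.finite(odi4)] <- NA_integer_
  as.integer(score)
}

#' Per-subject oximetry summary
#'
#' Applies the artefact mask (sensor-level rules plus wholesale removal of
#' 20-min epochs with more than `epoch_masked_max` of their samples
#' masked), detects ODI3 and ODI4 events, and derives the saturation
#' summaries, validity rule and oximetry score.
#'
#' @param spo2 1-Hz SpO2 trace, percent.
#' @param mask optional artefact mask; defaults to [mask_spo2_artefact()].
#' @param min_hours minimum artefact-free oximetry hours for inclusion.
#' @param epoch_seconds epoch length for wholesale artefact exclusion, s.
#' @param epoch_masked_max masked fraction above which an epoch is dropped.
#' @param odi3_drop,odi4_drop drop thresholds, percent.
#' @param integer_drop see [detect_desats()].
#' @param odi3_threshold,odi4_threshold score gates, events/h.
#' @return an `oximetry_summary` list: `mean_spo2`, `min_spo2`, `mean_nadir`
#'   (`NA` when no events), `odi3`, `odi4`, `n_below_80`, `valid_hours`,
#'   `score`, `included`, plus the two event tables.
#' @export
compute_oximetry_summary <- function(spo2, mask = NULL, min_hours = 4,
                                     epoch_seconds = 1200,
                                     epoch_masked_max = 0.5,
                                     odi3_drop = 3, odi4_drop = 4,
                                     integer_drop = TRUE,
                                     odi3_threshold = 7, odi4_threshold = 4) {
  n <- length(spo2)
  if (n == 0L) stop("empty SpO2 trace", call. = FALSE)
  if (is.null(mask)) mask <- mask_spo2_artefact(spo2)
  epoch <- (seq_len(n) - 1L) %/% as.integer(epoch_seconds)
  bad_epoch <- tapply(mask, epoch, mean) > epoch_masked_max
  mask <- as.logical(mask | bad_epoch[match(epoch, as.integer(names(bad_epoch)))])
  valid_hours <- sum(!mask) / 3600
  ev3 <- detect_desats(spo2, odi3_drop, mask, integer_drop = integer_drop)
  ev4 <- detect_desats(spo2, odi4_drop, mask, integer_drop = integer_drop)
  odi3 <- if (valid_hours > 0) nrow(ev3) / valid_hours else NA_real_
  odi4 <- if (valid_hours > 0) nrow(ev4) / valid_hours else NA_real_
  clean <- spo2[!mask & is.finite(spo2)]
  mean_spo2 <- if (length(clean)) mean(clean) else NA_real_
  min_spo2 <- if (length(clean)) min(clean) else NA_real_
  mean_nadir <- if (nrow(ev3)) mean(ev3$nadir) else NA_real_
  n_below_80 <- sum(ev3$nadir < 80)
  structure(list(
    mean_spo2 = mean_spo2, min_spo2 = min_spo2, mean_nadir = mean_nadir,
    odi3 = odi3, odi4 = odi4, n_below_80 = n_below_80,
    valid_hours = valid_hours,
    score = oximetry_score(odi3, odi4, min_spo2, n_below_80,
                           odi3_threshold, odi4_threshold),
    included = valid_hours >= min_hours,
    events_odi3 = ev3, events_odi4 = ev4
  ), class = "oximetry_summary")
}

#' @export
print.oximetry_summary <- function(x, ...) {
  cat(sprintf(
    "<oximetry_summary> ODI3 %.2f | ODI4 %.2f | min %.0f%% | score %s | %.2f valid h%s\n",
    x$odi3, x$odi4, x$min_spo2, x$score, x$valid_hours,
    if (x$included) "" else " (excluded)"))
  invisible(x)
}
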