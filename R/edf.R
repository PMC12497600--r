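# Minimal plain-EDF (European Data Format) writer/reader for the two
# synthetic signal channels. Data records are 1 s of 16-bit little-endian
# integers per signal; R-peak times, episode labels and generator truth
# travel in a JSON sidecar next to the .edf file.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write signals to a plain EDF file
#'
#' @param signals list of signals, each a list with `label`, `fs`
#'   (samples/s), `y` (numeric samples), `phys_min`, `phys_max`,
#'   `dim` (physical dimension string).
#' @param path output file.
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, patient = "X", recording = "synthetic") {
  ns <- length(signals)
  n_rec <- min(vapply(signals, function(s) floor(length(s$y) / s$fs), numeric(1)))
  stopifnot(n_rec >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wc <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wc("0", 8); wc(patient, 80); wc(recording, 80)
  wc("01.01.26", 8); wc("22.00.00", 8)
  wc(256 * (1 + ns), 8); wc("", 44); wc(n_rec, 8); wc("1", 8); wc(ns, 4)
  for (f in list(c("label", 16), c("transducer", 80), c("dim", 8),
                 c("phys_min", 8), c("phys_max", 8), c("dig_min", 8),
                 c("dig_max", 8), c("prefilter", 80), c("spr", 8),
                 c("reserved", 32))) {
    for (s in signals) {
      v <- switch(f[1],
                  label = s$label, transducer = "", dim = s$dim %||% "",
                  phys_min = s$phys_min, phys_max = s$phys_max,
                  dig_min = -32768, dig_max = 32767, prefilter = "",
                  spr = s$fs, reserved = "")
      wc(v, as.integer(f[2]))
    }
  }
  dig <- lapply(signals, function(s) {
    y <- s$y[seq_len(n_rec * s$fs)]
    y <- pmin(pmax(y, s$phys_min), s$phys_max)
    as.integer(round((y - s$phys_min) / (s$phys_max - s$phys_min) * 65535 - 32768))
  })
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      spr <- signals[[k]]$fs
      writeBin(dig[[k]][((r - 1) * spr + 1):(r * spr)], con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a plain EDF file
#'
#' @param path EDF file.
#' @return list with `n_records`, `record_duration` and `signals` (each a
#'   list `label`, `fs`, `y` in physical units).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rc <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rc(8)
  if (version != "0") stop("unreadable file: not plain EDF", call. = FALSE)
  rc(80); rc(80); rc(8); rc(8); rc(8); rc(44)
  n_rec <- as.integer(rc(8))
  rec_dur <- as.numeric(rc(8))
  ns <- as.integer(rc(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rc(w), character(1))
  label <- fld(16); fld(80); dim <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80); spr <- as.integer(fld(8)); fld(32)
  raw <- vector("list", ns)
  for (k in seq_len(ns)) raw[[k]] <- integer(n_rec * spr[k])
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      raw[[k]][((r - 1) * spr[k] + 1):(r * spr[k])] <-
        readBin(con, integer(), n = spr[k], size = 2, endian = "little",
                signed = TRUE)
    }
  }
  signals <- lapply(seq_len(ns), function(k) {
    y <- (raw[[k]] - dmin[k]) / (dmax[k] - dmin[k]) * (pmax_[k] - pmin_[k]) + pmin_[k]
    list(label = label[k], fs = spr[k] / rec_dur, y = y, dim = dim[k])
  })
  list(n_records = n_rec, record_duration = rec_dur, signals = signals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to EDF plus JSON sidecar
#'
#' Signals (Pleth at 100 Hz, SpO2 at 1 Hz) go to plain EDF; R-peak times,
#' snoring flag, episode labels and the generator truth go to a JSON
#' sidecar with the same basename.
#'
#' @param recording a `sleep_recording`.
#' @param path target `.edf` path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "sleep_recording"))
  signals <- list(
    list(label = "Pleth", fs = recording$pleth$fs, y = recording$pleth$y,
         phys_min = -1, phys_max = 2, dim = "au"),
    list(label = "SpO2", fs = 1, y = as.numeric(recording$spo2),
         phys_min = 0, phys_max = 100, dim = "%"))
  write_edf(signals, path)
  truth <- recording$truth
  side <- list(
    r_peaks = round(recording$r_peaks, 4),
    snoring = recording$snoring,
    video_labels = recording$video_labels,
    truth = list(profile = unclass(truth$profile),
                 n_arousals = truth$n_arousals,
                 n_desats = truth$n_desats,
                 n_below_80 = truth$n_below_80,
                 injected_amplitude = truth$injected_amplitude,
                 chain_gain = truth$chain_gain,
                 seed = truth$seed))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = 10, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.edf$", "", path), ".json")

#' Read a recording from EDF plus JSON sidecar
#'
#' @param path `.edf` path written by [write_recording()].
#' @return a `sleep_recording`.
#' @export
read_recording <- function(path) {
  e <- read_edf(path)
  labels <- vapply(e$signals, `[[`, character(1), "label")
  for (need in c("Pleth", "SpO2")) {
    if (!need %in% labels) {
      stop("missing channel: ", need, call. = FALSE)
    }
  }
  pl <- e$signals[[match("Pleth", labels)]]
  sp <- e$signals[[match("SpO2", labels)]]
  side <- list()
  sp_path <- sidecar_path(path)
  if (file.exists(sp_path)) side <- jsonlite::read_json(sp_path, simplifyVector = TRUE)
  vl <- side$video_labels
  if (is.null(vl) || length(vl) == 0L) {
    vl <- data.frame(start = numeric(0), end = numeric(0), has_arousal = logical(0))
  }
  profile <- side$truth$profile
  truth <- side$truth
  if (!is.null(profile)) {
    profile$n_obstructive <- profile$n_obstructive %||% NULL
    truth$profile <- tryCatch(do.call(subject_profile, profile),
                              error = function(e) profile)
  }
  structure(list(
    r_peaks = as.numeric(side$r_peaks),
    pleth = list(fs = pl$fs, y = pl$y),
    spo2 = as.integer(round(sp$y)),
    duration = e$n_records * e$record_duration,
    snoring = isTRUE(side$snoring),
    video_labels = vl,
    truth = truth
  ), class = "sleep_recording")
}
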