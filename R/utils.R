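# Internal numeric helpers shared across the signal-processing modules.

#' Centred moving mean with edge shrinkage
#'
#' Mean over a centred window of `k` samples; the window shrinks at the
#' series edges and `NA` samples are dropped from the average. Positions
#' whose window contains no finite sample are `NA`.
#'
#' @param x numeric vector.
#' @param k odd window width in samples.
#' @return numeric vector of `length(x)`.
#' @keywords internal
#' @noRd
mov_mean <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  stopifnot(k >= 1L, k %% 2L == 1L)
  half <- (k - 1L) %/% 2L
  ok <- is.finite(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(ok))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- s / m
  out[m == 0L] <- NA_real_
  out
}

#' Alternating trough/peak extrema by amplitude threshold
#'
#' Walks the series keeping a running candidate extremum; a reversal of at
#' least `prominence` confirms the candidate and flips direction. Returns
#' the confirmed extrema in order, each labelled trough (-1) or peak (+1).
#'
#' @param t sample times (seconds).
#' @param x sample values; must contain no NA (split masked series first).
#' @param prominence minimum reversal amplitude confirming an extremum.
#' @return data.frame with columns `time`, `value`, `type` (+1 peak, -1 trough).
#' @keywords internal
#' @noRd
zigzag_extrema <- function(t, x, prominence = 1) {
  n <- length(x)
  out_t <- numeric(0); out_v <- numeric(0); out_s <- integer(0)
  if (n < 2L) {
    return(data.frame(time = out_t, value = out_v, type = out_s))
  }
  # ties update the candidate's time, so a plateau extremum is stamped at its
  # last sample (descent durations start where the channel leaves the top)
  mode <- 0L                       # 0 unknown, +1 rising (seeking peak), -1 falling
  cmin <- x[1]; cmin_t <- t[1]
  cmax <- x[1]; cmax_t <- t[1]
  for (i in 2:n) {
    xi <- x[i]
    if (mode == 0L) {
      if (xi <= cmin) { cmin <- xi; cmin_t <- t[i] }
      if (xi >= cmax) { cmax <- xi; cmax_t <- t[i] }
      if (xi >= cmin + prominence) {
        out_t <- c(out_t, cmin_t); out_v <- c(out_v, cmin); out_s <- c(out_s, -1L)
        mode <- 1L; cmax <- xi; cmax_t <- t[i]
      } else if (xi <= cmax - prominence) {
        out_t <- c(out_t, cmax_t); out_v <- c(out_v, cmax); out_s <- c(out_s, 1L)
        mode <- -1L; cmin <- xi; cmin_t <- t[i]
      }
    } else if (mode == 1L) {
      if (xi >= cmax) { cmax <- xi; cmax_t <- t[i] }
      if (xi <= cmax - prominence) {
        out_t <- c(out_t, cmax_t); out_v <- c(out_v, cmax); out_s <- c(out_s, 1L)
        mode <- -1L; cmin <- xi; cmin_t <- t[i]
      }
    } else {
      if (xi <= cmin) { cmin <- xi; cmin_t <- t[i] }
      if (xi >= cmin + prominence) {
        out_t <- c(out_t, cmin_t); out_v <- c(out_v, cmin); out_s <- c(out_s, -1L)
        mode <- 1L; cmax <- xi; cmax_t <- t[i]
      }
    }
  }
  # close the final candidate so a terminal half-cycle is not lost
  if (mode == 1L && cmax - utils::tail(out_v, 1) >= prominence) {
    out_t <- c(out_t, cmax_t); out_v <- c(out_v, cmax); out_s <- c(out_s, 1L)
  } else if (mode == -1L && utils::tail(out_v, 1) - cmin >= prominence) {
    out_t <- c(out_t, cmin_t); out_v <- c(out_v, cmin); out_s <- c(out_s, -1L)
  }
  data.frame(time = out_t, value = out_v, type = out_s)
}

#' Split indices of a logical keep-vector into contiguous runs
#' @return list of integer index vectors where `keep` is TRUE.
#' @keywords internal
#' @noRd
contiguous_runs <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(j) starts[j]:ends[j])
}

#' Sparse table for O(1) range-argmax queries
#'
#' Builds the doubling table once (O(n log n)); `query(a, b)` returns the
#' index of the maximum of `x[a..b]`, vectorised over query pairs.
#' @keywords internal
#' @noRd
sparse_max_table <- function(x) {
  n <- length(x)
  K <- max(0L, floor(log2(n)))
  idx <- matrix(NA_integer_, n, K + 1L)
  idx[, 1L] <- seq_len(n)
  if (K >= 1L) {
    for (k in seq_len(K)) {
      span <- 2L^(k - 1L)
      j <- seq_len(n - 2L * span + 1L)
      a <- idx[j, k]
      b <- idx[j + span, k]
      idx[j, k + 1L] <- ifelse(x[b] > x[a], b, a)
    }
  }
  list(query = function(a, b) {
    k <- floor(log2(b - a + 1))
    i1 <- idx[cbind(a, k + 1L)]
    i2 <- idx[cbind(b - 2L^k + 1L, k + 1L)]
    ifelse(x[i2] > x[i1], i2, i1)
  })
}

# validation helper: error messages name the offending field
check_field <- function(cond, field, msg) {
  if (!isTRUE(cond)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
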