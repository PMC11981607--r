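## Shared numerical helpers: run-length event segmentation, moving averages,
## seeded RNG scoping. Interval conventions are half-open [onset, offset) in
## seconds throughout the package.

#' Segment a logical vector into maximal runs of TRUE
#'
#' Core primitive shared by the calcium-transient and fast-running detectors:
#' maximal contiguous runs of `above`, optionally merged across short gaps and
#' filtered by a minimum duration.
#'
#' @param above logical vector (one element per sample).
#' @param t numeric vector of sample times in seconds, same length as `above`.
#' @param merge_gap_s runs separated by a gap strictly shorter than this many
#'   seconds are merged into one event.
#' @param min_duration_s events whose total supra-threshold time (sum of the
#'   constituent run durations, excluding merged gaps) is below this are
#'   discarded -- so two brief noise blips bridged by a merge gap do not pass
#'   as one long event.
#' @return tibble with one row per event: `start_idx`, `end_idx` (inclusive
#'   sample indices), `onset_s`, `offset_s` (half-open interval), `above_s`.
#' @keywords internal
find_runs <- function(above, t, merge_gap_s = 0, min_duration_s = 0) {
  stopifnot(length(above) == length(t))
  empty <- tibble(start_idx = integer(), end_idx = integer(),
                  onset_s = numeric(), offset_s = numeric(),
                  above_s = numeric())
  if (!any(above, na.rm = TRUE)) return(empty)
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  dt <- if (length(t) > 1) stats::median(diff(t)) else 0
  runs <- data.frame(start = starts[keep], end = ends[keep],
                     above = (ends[keep] - starts[keep] + 1L) * dt)

  ## merge runs whose separating gap is shorter than merge_gap_s
  if (nrow(runs) > 1 && merge_gap_s > 0) {
    merged <- runs[1, , drop = FALSE]
    for (i in seq_len(nrow(runs))[-1]) {
      k <- nrow(merged)
      gap <- t[runs$start[i]] - t[merged$end[k]] - dt
      if (gap < merge_gap_s) {
        merged$end[k] <- runs$end[i]
        merged$above[k] <- merged$above[k] + runs$above[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }

  runs <- runs[runs$above >= min_duration_s, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  tibble(
    start_idx = as.integer(runs$start),
    end_idx = as.integer(runs$end),
    onset_s = t[runs$start],
    offset_s = t[runs$end] + dt,
    above_s = runs$above
  )
}

#' Centered moving average with replicated endpoints
#'
#' @param x numeric vector.
#' @param k window length in samples (coerced to an odd integer >= 1).
#' @keywords internal
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < k) return(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1L):(half + length(x))]
}

#' Evaluate code under a fixed seed without touching global RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## low-pass filter a white-noise vector; returns a band-limited series with
## unit standard deviation (used by generators so that "noise sd" parameters
## mean what they say after filtering)
band_limited_noise <- function(n, fs, cutoff_hz) {
  w <- rnorm(n)
  if (n < 12 || cutoff_hz >= fs / 2) return(w)
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  y <- as.numeric(signal::filtfilt(bf, w))
  s <- sd(y)
  if (s > 0) y / s else y
}

## strict positive scalar check with a readable error
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
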