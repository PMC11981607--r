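## Trajectory-based behavioral measures: smoothed speed, zone occupancy and
## entries, assay preference indices, fast-running episodes, center-pause
## outcome classification, and open-to-closed arm transitions.
##
## A trajectory is a tibble `time_s`, `x_mm`, `y_mm` with `fps` and `arena`
## attributes (see `as_trajectory()`). Intervals are half-open in seconds.

#' Construct / validate a trajectory tibble
#'
#' @param df data frame with columns `time_s`, `x_mm`, `y_mm`.
#' @param fps frame rate, Hz.
#' @param arena arena name (see [arena_zones()]).
#' @return tibble of class `trajectory`.
#' @export
as_trajectory <- function(df, fps = 30, arena = "epm") {
  check_positive(fps, "fps")
  need <- c("time_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("Missing trajectory column(s): %s",
                                  paste(miss, collapse = ", ")))
  if (!all(is.finite(df$x_mm)) || !all(is.finite(df$y_mm))) {
    abort("Positions must be finite.")
  }
  out <- as_tibble(df)
  attr(out, "fps") <- fps
  attr(out, "arena") <- arena
  if (!inherits(out, "trajectory")) class(out) <- c("trajectory", class(out))
  out
}

#' Compute smoothed locomotion speed
#'
#' Positions are smoothed with a centered moving average of
#' `smooth_window_s` seconds, then speed is obtained by central finite
#' differences (endpoints replicated). Smoothing is needed because tracking
#' jitter at video frame rates otherwise dominates the derivative.
#'
#' @param traj a trajectory tibble.
#' @param smooth_window_s smoothing window, seconds (default 0.2).
#' @return the trajectory with an added `speed_mm_s` column.
#' @export
compute_speed <- function(traj, smooth_window_s = 0.2) {
  fps <- sampling_rate_fps(traj)
  n <- nrow(traj)
  if (n < 2) abort("Need at least two frames to compute speed.")
  k <- round(smooth_window_s * fps)
  xs <- moving_average(traj$x_mm, k)
  ys <- moving_average(traj$y_mm, k)
  v <- numeric(n)
  i <- 2:(n - 1)
  v[i] <- sqrt((xs[i + 1] - xs[i - 1])^2 + (ys[i + 1] - ys[i - 1])^2) * fps / 2
  v[1] <- v[2]; v[n] <- v[n - 1]
  out <- dplyr::mutate(traj, speed_mm_s = v)
  keep_traj_attrs(out, traj)
}

sampling_rate_fps <- function(traj) {
  fps <- attr(traj, "fps")
  if (is.null(fps)) abort("Trajectory has no `fps` attribute; use `as_trajectory()`.")
  check_positive(fps, "fps")
  fps
}

keep_traj_attrs <- function(out, traj) {
  attr(out, "fps") <- attr(traj, "fps")
  attr(out, "arena") <- attr(traj, "arena")
  class(out) <- class(traj)
  out
}

traj_zones <- function(traj, zones = NULL) {
  zones %||% arena_zones(attr(traj, "arena"))
}

#' Per-zone occupancy, entries and total distance
#'
#' Each frame is assigned to a zone by point-in-polygon test; occupancy time
#' is frame count / fps. An entry is a transition into a zone that then lasts
#' at least `min_dwell` frames (debouncing tracking jitter at boundaries).
#' Total distance is the polyline length of the smoothed path.
#'
#' @param traj a trajectory tibble.
#' @param zones optional zone list; defaults to the trajectory's arena.
#' @param min_dwell minimum dwell (frames) for a zone visit to count as an
#'   entry (default 3).
#' @param smooth_window_s position smoothing for the distance computation.
#' @return object of class `occupancy_summary`: list with `zone_times` tibble
#'   (`zone`, `time_s`, `entries`), `total_distance_mm`, `n_outside`,
#'   `duration_s`.
#' @export
zone_occupancy <- function(traj, zones = NULL, min_dwell = 3,
                           smooth_window_s = 0.2) {
  zones <- traj_zones(traj, zones)
  fps <- sampling_rate_fps(traj)
  az <- assign_zones(traj$x_mm, traj$y_mm, zones)
  if (az$n_outside > 0) {
    warn(sprintf("%d frame(s) fell outside all zones; assigned to nearest zone.",
                 az$n_outside))
  }
  r <- rle(az$zone)
  visits <- tibble(zone = r$values, len = r$lengths)
  per_zone <- purrr::map_dfr(names(zones), function(nm) {
    vz <- visits[visits$zone == nm, , drop = FALSE]
    ## the initial visit is not an "entry"; count transitions into the zone
    n_entry <- sum(vz$len >= min_dwell)
    if (nrow(visits) && visits$zone[1] == nm && visits$len[1] >= min_dwell) {
      n_entry <- n_entry - 1L
    }
    tibble(zone = nm, time_s = sum(vz$len) / fps, entries = as.integer(n_entry))
  })
  k <- round(smooth_window_s * fps)
  xs <- moving_average(traj$x_mm, k); ys <- moving_average(traj$y_mm, k)
  dist <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  structure(list(zone_times = per_zone, total_distance_mm = dist,
                 n_outside = az$n_outside,
                 duration_s = nrow(traj) / fps),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf("<occupancy_summary> %.1f s, %.0f mm travelled\n",
              x$duration_s, x$total_distance_mm))
  print(x$zone_times)
  invisible(x)
}

#' Assay preference indices
#'
#' Computes the standard preference ratios: three-chamber sociability
#' (`tct`, stranger / object interaction time), female-encounter motivation
#' (`fet`, female / male time), and sucrose preference
#' (`spt`, sucrose / (sucrose + water) intake).
#'
#' @param a,b the two measured quantities: `tct`: time near stranger, time
#'   near object (s); `fet`: time near female, time near male (s); `spt`:
#'   sucrose intake, water intake (ml).
#' @param assay one of `"tct"`, `"fet"`, `"spt"`.
#' @return one-row tibble with `assay`, `a`, `b`, `index`, `defined`.
#'   A zero denominator yields `index = NA` with `defined = FALSE` (never
#'   infinity).
#' @export
preference_index <- function(a, b, assay = c("tct", "fet", "spt")) {
  assay <- match.arg(assay)
  denom <- switch(assay, tct = b, fet = b, spt = a + b)
  num <- switch(assay, tct = a, fet = a, spt = a)
  defined <- is.finite(denom) && denom > 0
  tibble(assay = assay, a = a, b = b,
         index = if (defined) num / denom else NA_real_,
         defined = defined)
}

#' Detect fast-running episodes (speed strictly exceeding a threshold)
#'
#' Maximal runs of frames with smoothed speed strictly above `threshold`
#' ("exceeding"), lasting at least `min_dur_s`, merged across gaps shorter
#' than `merge_gap_s`.
#'
#' @param traj trajectory with a `speed_mm_s` column (see [compute_speed()]).
#' @param threshold speed threshold, mm/s (default 400).
#' @param min_dur_s minimum episode duration, seconds (default 0.25).
#' @param merge_gap_s merge gap, seconds (default 0.2).
#' @return tibble of events: `kind` (`"fast_running"`), `onset_s`,
#'   `offset_s`, `peak_speed`.
#' @export
detect_fast_running <- function(traj, threshold = 400, min_dur_s = 0.25,
                                merge_gap_s = 0.2) {
  check_positive(threshold, "threshold")
  sp <- need_speed(traj)
  runs <- find_runs(sp > threshold, traj$time_s,
                    merge_gap_s = merge_gap_s, min_duration_s = min_dur_s)
  if (!nrow(runs)) return(empty_events())
  tibble(kind = "fast_running", onset_s = runs$onset_s, offset_s = runs$offset_s,
         peak_speed = purrr::map2_dbl(runs$start_idx, runs$end_idx,
                                      ~ max(sp[.x:.y])))
}

## extend a locomotion bout past the destination-arm boundary: keep frames
## while the animal stays in the same zone and keeps moving (speed above
## `floor_speed`), capped at `max_extend_s`, so the bout peak reflects the
## full dash rather than being truncated at the zone line
extend_bout <- function(dest, za, sp, floor_speed, fps, max_extend_s = 3) {
  j <- dest
  cap <- min(length(sp), dest + round(max_extend_s * fps))
  while (j < cap && za[j + 1L] == za[dest] && sp[j + 1L] > floor_speed) {
    j <- j + 1L
  }
  j
}

need_speed <- function(traj) {
  if (is.null(traj$speed_mm_s)) abort("Run `compute_speed()` first.")
  traj$speed_mm_s
}

empty_events <- function() {
  tibble(kind = character(), onset_s = numeric(), offset_s = numeric(),
         peak_speed = numeric())
}

#' Classify center-pause outcomes in the elevated plus maze
#'
#' A pause is a dwell in the center zone with smoothed speed below
#' `pause_speed` for at least `pause_min_s`. The outcome is labeled by the
#' next arm entered after the pause -- a return to a closed arm
#' (`pause_then_return_run` / `_walk`, split by whether the exit bout's peak
#' speed reaches `run_threshold`) or an exit into an open arm
#' (`pause_then_exit_open`). Events are timestamped at exit onset so they can
#' anchor peri-event signal alignment.
#'
#' @param traj EPM trajectory with `speed_mm_s`.
#' @param pause_speed speed ceiling defining a pause, mm/s (default 20).
#' @param pause_min_s minimum pause duration, seconds (default 0.5).
#' @param run_threshold run/walk split for the exit bout, mm/s (default 400,
#'   the same cutoff used for fast running).
#' @return events tibble as in [detect_fast_running()].
#' @export
classify_center_pause_outcomes <- function(traj, pause_speed = 20,
                                           pause_min_s = 0.5,
                                           run_threshold = 400) {
  if (!identical(attr(traj, "arena"), "epm")) {
    abort("Center-pause classification requires an EPM trajectory.")
  }
  sp <- need_speed(traj)
  zones <- arena_zones("epm")
  za <- assign_zones(traj$x_mm, traj$y_mm, zones)$zone
  paused <- za == "center" & sp < pause_speed
  runs <- find_runs(paused, traj$time_s, min_duration_s = pause_min_s)
  if (!nrow(runs)) return(empty_events())
  fps <- sampling_rate_fps(traj)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    after <- (runs$end_idx[i] + 1L):nrow(traj)
    if (runs$end_idx[i] >= nrow(traj)) next
    arm_idx <- after[startsWith(za[after], "open_arm") |
                     startsWith(za[after], "closed_arm")]
    if (!length(arm_idx)) next
    dest <- arm_idx[1]
    bout_end <- extend_bout(dest, za, sp, floor_speed = pause_speed,
                            fps = fps)
    peak <- max(sp[(runs$end_idx[i] + 1L):bout_end])
    kind <- if (startsWith(za[dest], "closed_arm")) {
      if (peak >= run_threshold) "pause_then_return_run" else "pause_then_return_walk"
    } else {
      "pause_then_exit_open"
    }
    out[[length(out) + 1L]] <- tibble(kind = kind,
                                      onset_s = traj$time_s[runs$end_idx[i] + 1L],
                                      offset_s = traj$time_s[dest],
                                      peak_speed = peak)
  }
  if (!length(out)) return(empty_events())
  dplyr::bind_rows(out)
}

#' Detect open-to-closed arm transitions in the elevated plus maze
#'
#' Every transition from an open arm to a closed arm (through the center)
#' yields one event, labeled run or walk by the peak smoothed speed of the
#' bout between leaving the open arm and entering the closed arm. Transitions
#' in the opposite direction are not emitted.
#'
#' @param traj EPM trajectory with `speed_mm_s`.
#' @param run_threshold run/walk split, mm/s (default 400).
#' @return events tibble (`kind` is `open_to_closed_run` or
#'   `open_to_closed_walk`).
#' @export
detect_open_to_closed_transitions <- function(traj, run_threshold = 400) {
  if (!identical(attr(traj, "arena"), "epm")) {
    abort("Open-to-closed transition detection requires an EPM trajectory.")
  }
  sp <- need_speed(traj)
  za <- assign_zones(traj$x_mm, traj$y_mm, arena_zones("epm"))$zone
  arm <- ifelse(startsWith(za, "open_arm"), "open",
                ifelse(startsWith(za, "closed_arm"), "closed", NA))
  out <- list()
  r <- rle(arm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  vis <- data.frame(arm = r$values, start = starts, end = ends)
  vis <- vis[!is.na(vis$arm), , drop = FALSE]
  if (nrow(vis) >= 2) {
    for (i in seq_len(nrow(vis) - 1L)) {
      if (vis$arm[i] == "open" && vis$arm[i + 1L] == "closed") {
        onset <- min(vis$end[i] + 1L, nrow(traj))
        dest <- vis$start[i + 1L]
        bout_end <- extend_bout(dest, za, sp, floor_speed = 20,
                                fps = sampling_rate_fps(traj))
        peak <- max(sp[onset:bout_end])
        out[[length(out) + 1L]] <- tibble(
          kind = if (peak >= run_threshold) "open_to_closed_run" else "open_to_closed_walk",
          onset_s = traj$time_s[onset], offset_s = traj$time_s[dest],
          peak_speed = peak)
      }
    }
  }
  if (!length(out)) return(empty_events())
  dplyr::bind_rows(out)
}
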