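## Acoustic startle response (ASR) and prepulse inhibition (PPI) from
## high-speed (200 fps) pose keypoints.
##
## Protocol: a quiet baseline of at least 20 minutes, a habituation phase of
## 10 pulses 20 s apart, then a PPI phase of 20 trials -- 5 pulse-only and
## 15 prepulse+pulse in seeded random order -- with the prepulse 500 ms
## before the pulse. Pulse: 105 dB, 0.2 s; prepulse: 75 dB, 0.2 s. The
## startle amplitude of a trial is the mean over labeled body parts of the
## peak displacement from the pre-stimulus position within 200 ms of pulse
## onset; trials contaminated by spontaneous locomotion are excluded.

#' Build an ASR/PPI trial schedule
#'
#' @param baseline_s duration of the initial quiet baseline, seconds
#'   (default 1200 = 20 min; shorten only for simulation economy).
#' @param n_habituation number of habituation pulses (default 10).
#' @param habituation_interval_s spacing of habituation pulses (default 20).
#' @param n_pulse_only,n_prepulse PPI-phase trial counts (defaults 5 and 15).
#' @param trial_interval_s spacing of PPI trials (default 20).
#' @param prepulse_lead_s prepulse onset before pulse onset (default 0.5).
#' @param seed seed for the randomized PPI trial order.
#' @return tibble: `trial`, `phase` (`habituation`/`ppi`), `type`
#'   (`habituation_pulse`, `pulse_only`, `prepulse_pulse`), `pulse_onset_s`,
#'   `prepulse_onset_s` (NA when absent); attributes record the dB levels
#'   (105 pulse / 75 prepulse) and 0.2 s stimulus duration.
#' @export
build_trial_schedule <- function(baseline_s = 1200, n_habituation = 10,
                                 habituation_interval_s = 20,
                                 n_pulse_only = 5, n_prepulse = 15,
                                 trial_interval_s = 20,
                                 prepulse_lead_s = 0.5, seed = 1) {
  hab_onsets <- baseline_s + habituation_interval_s * seq_len(n_habituation)
  types <- with_seed(seed, sample(c(rep("pulse_only", n_pulse_only),
                                    rep("prepulse_pulse", n_prepulse))))
  ppi_start <- max(hab_onsets, baseline_s) + trial_interval_s
  ppi_onsets <- ppi_start + trial_interval_s * (seq_along(types) - 1)
  out <- dplyr::bind_rows(
    tibble(phase = "habituation", type = "habituation_pulse",
           pulse_onset_s = hab_onsets, prepulse_onset_s = NA_real_),
    tibble(phase = "ppi", type = types, pulse_onset_s = ppi_onsets,
           prepulse_onset_s = ifelse(types == "prepulse_pulse",
                                     ppi_onsets - prepulse_lead_s, NA_real_)))
  out <- dplyr::mutate(out, trial = dplyr::row_number(), .before = 1)
  attr(out, "pulse_db") <- 105
  attr(out, "prepulse_db") <- 75
  attr(out, "stimulus_duration_s") <- 0.2
  out
}

#' Simulate a startle session with known per-trial amplitudes
#'
#' Body-part keypoints jitter around rest positions; at each pulse onset a
#' stimulus-locked displacement impulse of the trial's true amplitude is
#' added, confined to the 200 ms response window (triangular profile whose
#' peak is attained exactly at one sample, so noiseless recovery is exact).
#'
#' @param schedule a [build_trial_schedule()] tibble.
#' @param true_amps numeric vector of true startle amplitudes (displacement
#'   units), one per schedule row.
#' @param n_body_parts number of labeled body parts (default 4).
#' @param fs frame rate in Hz (default 200).
#' @param jitter_sd keypoint jitter SD in the same displacement units
#'   (default 0.05).
#' @param baseline_move_speed if positive, adds slow sinusoidal whole-body
#'   drift of this mean speed (units/s) during the baseline windows of the
#'   trials listed in `moving_trials` -- used to exercise invalid-trial
#'   flagging.
#' @param moving_trials integer trial ids contaminated by locomotion.
#' @param seed integer seed.
#' @return list with `session` (tibble `time_s` plus `part<i>_x`/`_y`
#'   columns, `fs` attribute), `schedule`, and `truth` (per-trial amplitude).
#' @export
simulate_startle <- function(schedule, true_amps, n_body_parts = 4, fs = 200,
                             jitter_sd = 0.05, baseline_move_speed = 0,
                             moving_trials = integer(), seed) {
  if (length(true_amps) != nrow(schedule)) {
    abort("`true_amps` must have one value per schedule row.")
  }
  dur <- max(schedule$pulse_onset_s) + 5
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs

  ## triangular impulse over the 200 ms window whose unit peak is attained at
  ## exactly one sample, so noiseless recovery is exact
  win_n <- round(0.2 * fs)
  pk <- win_n %/% 2
  kern <- 1 - abs(seq_len(win_n) - 1 - pk) / pk
  kern[kern < 0] <- 0

  impulse <- rep(0, n)
  for (i in seq_len(nrow(schedule))) {
    i0 <- round(schedule$pulse_onset_s[i] * fs) + 1L
    idx <- i0:min(i0 + win_n - 1L, n)
    impulse[idx] <- impulse[idx] + true_amps[i] * kern[seq_along(idx)]
  }
  drift <- rep(0, n)
  if (baseline_move_speed > 0 && length(moving_trials)) {
    for (tr in moving_trials) {
      on <- schedule$pulse_onset_s[schedule$trial == tr]
      idx <- which(t >= on - 1.5 & t < on - 0.1)
      ## sinusoid with mean |velocity| = baseline_move_speed
      f0 <- 2
      amp <- baseline_move_speed / (4 * f0)
      drift[idx] <- amp * sin(2 * pi * f0 * (t[idx] - t[idx][1]))
    }
  }
  cols <- with_seed(seed, {
    purrr::map(seq_len(n_body_parts), function(p) {
      x0 <- p * 10
      list(x = x0 + drift + rnorm(n, 0, jitter_sd),
           y = impulse + drift + rnorm(n, 0, jitter_sd))
    })
  })
  session <- tibble(time_s = t)
  for (p in seq_len(n_body_parts)) {
    session[[sprintf("part%d_x", p)]] <- cols[[p]]$x
    session[[sprintf("part%d_y", p)]] <- cols[[p]]$y
  }
  attr(session, "fs") <- fs
  list(session = session,
       schedule = schedule,
       truth = tibble(trial = schedule$trial, amplitude = true_amps))
}

body_part_names <- function(session) {
  unique(sub("_(x|y)$", "", grep("_(x|y)$", names(session), value = TRUE)))
}

#' Startle amplitude of each trial
#'
#' Per body part, the vibration amplitude is the peak absolute displacement
#' from its pre-stimulus mean position (over `position_baseline_s` before
#' pulse onset) within the `window_s` response window after pulse onset; the
#' trial amplitude is the mean over body parts.
#'
#' @param session keypoint tibble from [simulate_startle()] or
#'   [read_pose_csv()] (columns `<part>_x`, `<part>_y`, attribute `fs`).
#' @param schedule trial schedule tibble.
#' @param window_s response window after pulse onset (default 0.2 s).
#' @param position_baseline_s pre-stimulus window defining the rest position
#'   (default 0.1 s).
#' @param statistic `"peak"` (default) or `"rms"` displacement.
#' @return tibble: `trial`, `type`, `amplitude`, plus per-body-part columns.
#' @export
startle_amplitudes <- function(session, schedule, window_s = 0.2,
                               position_baseline_s = 0.1,
                               statistic = c("peak", "rms")) {
  statistic <- match.arg(statistic)
  fs <- sampling_rate(session)
  parts <- body_part_names(session)
  if (!length(parts)) abort("No body-part keypoint columns found.")
  n <- nrow(session)
  purrr::map_dfr(seq_len(nrow(schedule)), function(i) {
    on <- schedule$pulse_onset_s[i]
    i0 <- round(on * fs) + 1L
    i1 <- i0 + round(window_s * fs) - 1L
    if (i1 > n) abort(sprintf("Trial %d response window extends past the recording end.",
                              schedule$trial[i]))
    b0 <- max(1L, i0 - round(position_baseline_s * fs))
    amps <- vapply(parts, function(p) {
      x <- session[[paste0(p, "_x")]]; y <- session[[paste0(p, "_y")]]
      dx <- x[i0:i1] - mean(x[b0:(i0 - 1L)])
      dy <- y[i0:i1] - mean(y[b0:(i0 - 1L)])
      disp <- sqrt(dx^2 + dy^2)
      if (statistic == "peak") max(disp) else sqrt(mean(disp^2))
    }, numeric(1))
    res <- tibble(trial = schedule$trial[i], type = schedule$type[i],
                  amplitude = mean(amps))
    res[paste0(parts, "_amp")] <- as.list(amps)
    res
  })
}

#' Flag trials contaminated by spontaneous locomotion
#'
#' A trial is invalid when the mean body-part speed over the pre-stimulus
#' baseline window exceeds `move_threshold`; invalid trials are excluded from
#' downstream averages, mirroring the manual exclusion of startle responses
#' affected by random movement.
#'
#' @inheritParams startle_amplitudes
#' @param baseline_window_s pre-stimulus window length, seconds (default 1).
#' @param move_threshold mean-speed ceiling, displacement units per second
#'   (default 50).
#' @return `schedule` with added columns `baseline_speed`, `valid`.
#' @export
flag_invalid_trials <- function(session, schedule, baseline_window_s = 1,
                                move_threshold = 50) {
  fs <- sampling_rate(session)
  parts <- body_part_names(session)
  sp <- purrr::map_dbl(seq_len(nrow(schedule)), function(i) {
    on <- schedule$pulse_onset_s[i]
    i0 <- max(1L, round((on - baseline_window_s) * fs) + 1L)
    i1 <- max(i0 + 1L, round(on * fs))
    mean(vapply(parts, function(p) {
      x <- session[[paste0(p, "_x")]][i0:i1]
      y <- session[[paste0(p, "_y")]][i0:i1]
      mean(sqrt(diff(x)^2 + diff(y)^2)) * fs
    }, numeric(1)))
  })
  out <- dplyr::mutate(schedule, baseline_speed = sp,
                       valid = sp <= move_threshold)
  attr(out, "move_threshold") <- move_threshold
  out
}

#' Prepulse-inhibition ratio
#'
#' PPI ratio = mean startle amplitude of valid prepulse+pulse trials divided
#' by mean amplitude of valid pulse-only trials. Values below 1 indicate
#' inhibition of the startle response by the prepulse.
#'
#' @param results tibble with `type`, `amplitude` and (optionally) `valid`
#'   columns -- typically [startle_amplitudes()] joined with
#'   [flag_invalid_trials()].
#' @return one-row tibble: `ppi_ratio`, `n_prepulse`, `n_pulse_only`,
#'   `mean_prepulse`, `mean_pulse_only`, `defined`.
#' @export
ppi_ratio <- function(results) {
  if (is.null(results[["valid"]])) results$valid <- TRUE
  keep <- results[results$valid & results$type %in% c("pulse_only", "prepulse_pulse"), ]
  m_pp <- keep$amplitude[keep$type == "prepulse_pulse"]
  m_po <- keep$amplitude[keep$type == "pulse_only"]
  if (!length(m_pp) || !length(m_po)) {
    abort("Need at least one valid trial of each type (prepulse_pulse and pulse_only).")
  }
  defined <- mean(m_po) > 0
  tibble(ppi_ratio = if (defined) mean(m_pp) / mean(m_po) else NA_real_,
         n_prepulse = length(m_pp), n_pulse_only = length(m_po),
         mean_prepulse = mean(m_pp), mean_pulse_only = mean(m_po),
         defined = defined)
}
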