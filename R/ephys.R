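## Patch-clamp feature extraction: spike detection, F-I curves and rheobase,
## action-potential threshold (dV/dt criterion) and half-width, passive
## membrane properties from a test pulse, miniature-PSC detection, synaptic
## connectivity classification, and LTP normalization to percent baseline.

#' Detect action potentials in a current-clamp trace
#'
#' Peaks above `min_height_mv` (default 0 mV) separated by at least
#' `min_separation_s`.
#'
#' @param v_mV voltage trace.
#' @param fs sampling rate, Hz.
#' @param min_height_mv peak height criterion, mV (default 0).
#' @param min_separation_s minimum inter-spike separation, seconds
#'   (default 0.001).
#' @return integer vector of spike peak sample indices (ordered).
#' @export
detect_spikes <- function(v_mV, fs, min_height_mv = 0, min_separation_s = 0.001) {
  if (all(v_mV <= min_height_mv)) return(integer())
  pk <- pracma::findpeaks(v_mV, minpeakheight = min_height_mv,
                          minpeakdistance = max(1L, round(min_separation_s * fs)))
  if (is.null(pk)) return(integer())
  sort(as.integer(pk[, 2]))
}

#' F-I curve: spike counts per current step
#'
#' @param sweeps long tibble from [simulate_fi_sweeps()] (or read from file):
#'   columns `step_pA`, `time_s`, `v_mV`, with an `fs` attribute.
#' @param steps_pA the expected step grid (default `seq(0, 100, 10)`); any
#'   missing step is an error naming the gaps.
#' @param ... passed to [detect_spikes()].
#' @return object of class `fi_curve`: tibble `step_pA`, `n_spikes`, with the
#'   rheobase (smallest step with >= 1 spike, or `NA`) as an attribute.
#' @export
fi_curve <- function(sweeps, steps_pA = seq(0, 100, 10), ...) {
  fs <- sampling_rate(sweeps)
  present <- unique(sweeps$step_pA)
  missing <- setdiff(steps_pA, present)
  if (length(missing)) {
    abort(sprintf("Missing current step(s): %s pA.",
                  paste(missing, collapse = ", ")))
  }
  out <- sweeps |>
    dplyr::filter(.data$step_pA %in% steps_pA) |>
    dplyr::group_by(.data$step_pA) |>
    dplyr::summarise(n_spikes = length(detect_spikes(.data$v_mV, fs, ...)),
                     .groups = "drop") |>
    dplyr::arrange(.data$step_pA)
  attr(out, "rheobase_pA") <- rheobase(out)
  class(out) <- c("fi_curve", class(out))
  out
}

#' Rheobase from an F-I table
#'
#' @param fi tibble with `step_pA`, `n_spikes`.
#' @return smallest step current with at least one spike (pA), or `NA` when
#'   no step elicits a spike.
#' @export
rheobase <- function(fi) {
  hit <- fi$step_pA[fi$n_spikes >= 1]
  if (!length(hit)) NA_real_ else min(hit)
}

#' Action-potential threshold by the dV/dt slope criterion
#'
#' The membrane voltage at the onset of the upstroke: scanning backward from
#' the spike peak, the earliest sample of the contiguous stretch where the
#' depolarization rate is at least `criterion_v_per_s` (central-difference
#' dV/dt).
#'
#' @param v_mV voltage trace.
#' @param fs sampling rate, Hz.
#' @param spike_idx spike peak sample index.
#' @param criterion_v_per_s slope criterion in V/s (default 20).
#' @return threshold voltage in mV, or `NA` (flagged with a warning) when the
#'   slope never reaches the criterion before the peak.
#' @export
ap_threshold <- function(v_mV, fs, spike_idx, criterion_v_per_s = 20) {
  n <- length(v_mV)
  dvdt <- c(NA, (v_mV[3:n] - v_mV[1:(n - 2)]) / 2 * fs / 1000, NA)  # V/s
  k <- spike_idx - 1L
  if (k < 2 || !isTRUE(dvdt[k] >= criterion_v_per_s)) {
    ## walk back to the upstroke in case the peak sample itself has low slope
    while (k >= 2 && !isTRUE(dvdt[k] >= criterion_v_per_s) &&
           spike_idx - k < round(0.005 * fs)) k <- k - 1L
  }
  if (k < 2 || !isTRUE(dvdt[k] >= criterion_v_per_s)) {
    warn("dV/dt never reaches the slope criterion before the peak; threshold undefined.")
    return(NA_real_)
  }
  while (k >= 2 && isTRUE(dvdt[k - 1L] >= criterion_v_per_s)) k <- k - 1L
  v_mV[k]
}

#' Action-potential half-width
#'
#' Full width at half-maximal amplitude, where the amplitude reference is
#' threshold-to-peak: the width of the spike at the voltage midway between
#' threshold and peak, with linear interpolation at the two crossings.
#'
#' @inheritParams ap_threshold
#' @param threshold_mv spike threshold from [ap_threshold()]; computed if
#'   missing.
#' @return half-width in milliseconds, or `NA` (with a warning) for a
#'   malformed spike.
#' @export
ap_half_width <- function(v_mV, fs, spike_idx, threshold_mv = NULL,
                          criterion_v_per_s = 20) {
  if (is.null(threshold_mv)) {
    threshold_mv <- ap_threshold(v_mV, fs, spike_idx, criterion_v_per_s)
  }
  peak <- v_mV[spike_idx]
  if (!is.finite(threshold_mv) || peak <= threshold_mv) {
    warn("Malformed spike (peak does not exceed threshold); half-width undefined.")
    return(NA_real_)
  }
  half <- (peak + threshold_mv) / 2
  ## falling crossing
  i <- spike_idx
  n <- length(v_mV)
  while (i < n && v_mV[i + 1L] > half) i <- i + 1L
  if (i >= n) { warn("Spike truncated before the falling half-max crossing."); return(NA_real_) }
  t_fall <- i + (v_mV[i] - half) / (v_mV[i] - v_mV[i + 1L])
  ## rising crossing
  j <- spike_idx
  while (j > 1 && v_mV[j - 1L] > half) j <- j - 1L
  if (j <= 1) { warn("Spike truncated before the rising half-max crossing."); return(NA_real_) }
  t_rise <- j - (v_mV[j] - half) / (v_mV[j] - v_mV[j - 1L])
  (t_fall - t_rise) / fs * 1000
}

#' Passive membrane properties from a hyperpolarizing test pulse
#'
#' The raw deflection is the mean over the last 10 ms of the step relative to
#' the pre-step baseline. Because a 50 ms step with a realistic membrane time
#' constant (10-25 ms) ends before charging completes, the asymptotic
#' deflection is estimated jointly with the time constant: the onset
#' transient is fitted with a single exponential, the steady state corrected
#' by the fitted fraction of charging completed in the measurement window,
#' and the fit iterated to a fixed point. On an ideal RC response this
#' recovers the true R and tau to numerical precision. Membrane resistance is
#' `deltaV / deltaI` (current clamp) or `step / deltaI` (voltage clamp);
#' capacitance = tau / R.
#'
#' @param sweep tibble `time_s`, `v_mV` (or `i_pA` in voltage clamp),
#'   `command_pA` (or `command_mV`), with `fs` and `step_window_s`
#'   attributes (the latter `c(on_s, off_s)`).
#' @param mode `"current_clamp"` (default) or `"voltage_clamp"`.
#' @param steady_state_ms width of the steady-state window at the end of the
#'   step (default 10 ms).
#' @return one-row tibble: `r_m_mohm`, `tau_m_ms`, `capacitance_pF`,
#'   `delta` (raw last-10-ms deflection, mV or pA), `fit_rmse`.
#' @export
passive_props <- function(sweep, mode = c("current_clamp", "voltage_clamp"),
                          steady_state_ms = 10) {
  mode <- match.arg(mode)
  fs <- sampling_rate(sweep)
  win <- attr(sweep, "step_window_s")
  if (is.null(win)) abort("Sweep lacks a `step_window_s` attribute (step on/off times).")
  t <- sweep$time_s
  pre <- t < win[1]
  ss <- t >= win[2] - steady_state_ms / 1000 & t < win[2]
  on <- t >= win[1] & t < win[2]
  if (mode == "current_clamp") {
    y <- sweep$v_mV
    d_i <- mean(sweep$command_pA[ss]) - mean(sweep$command_pA[pre])   # pA
    if (abs(d_i) < 1e-12) abort("Zero-amplitude current step.")
  } else {
    y <- sweep$i_pA
    d_cmd <- mean(sweep$command_mV[ss]) - mean(sweep$command_mV[pre])  # mV
  }
  y0 <- mean(y[pre])
  d_raw <- mean(y[ss]) - y0
  if (abs(d_raw) < 1e-12) abort("Zero-amplitude response to the step.")
  t_on <- t[on] - win[1]
  y_on <- y[on]
  t_ss <- t[ss] - win[1]

  ## three-parameter exponential fit of the onset, y = yinf + a*exp(-t/tau),
  ## by profile least squares: for fixed tau the model is linear in
  ## (yinf, a), so the residual sum is minimized over tau with optimize();
  ## the fitted asymptote corrects the last-10-ms deflection for incomplete
  ## charging (a 50 ms step with tau 10-25 ms ends ~5-15% short of steady
  ## state). Exact on an ideal RC response.
  if (length(t_on) < 4) {
    abort("Exponential fit of the step onset failed: too few samples.")
  }
  rss_at <- function(tau) {
    f <- lm(y_on ~ exp(-t_on / tau))
    sum(stats::resid(f)^2)
  }
  opt <- stats::optimize(rss_at, interval = c(5e-4, 0.2))
  tau_s <- opt$minimum
  fit <- lm(y_on ~ exp(-t_on / tau_s))
  y_inf <- coef(fit)[[1]]
  a <- coef(fit)[[2]]
  if (!is.finite(tau_s) || sign(a) != sign(-(y_inf - y0)) && abs(a) > 1e-9) {
    abort("Exponential fit of the step onset failed: non-decaying transient.")
  }
  d_est <- y_inf - y0
  if (abs(d_est) < 1e-12) abort("Exponential fit degenerate: zero fitted deflection.")
  rmse <- sqrt(mean(stats::resid(fit)^2))
  tau_ms <- tau_s * 1000
  r_m <- if (mode == "current_clamp") abs(d_est / d_i * 1000)          # MOhm
         else abs(d_cmd / d_est * 1000)
  cap <- tau_ms / r_m * 1000                                           # pF
  tibble(r_m_mohm = r_m, tau_m_ms = tau_ms, capacitance_pF = cap,
         delta = d_raw, fit_rmse = rmse)
}

#' Detect miniature postsynaptic currents
#'
#' The trace is band-passed (1-2000 Hz Butterworth, zero-phase) and
#' thresholded in the polarity direction; detected excursions separated by at
#' least `min_interval_s` become events, with amplitude measured on the raw
#' trace as peak minus the local pre-event baseline (median over
#' `baseline_ms` before onset).
#'
#' @param trace tibble `time_s`, `i_pA` with an `fs` attribute.
#' @param polarity `"negative"` (inward mEPSC) or `"positive"` (outward
#'   mIPSC).
#' @param threshold_pA detection threshold on the filtered trace, pA
#'   (default 10).
#' @param min_interval_s minimum event separation, seconds (default 0.01).
#' @param band_hz filter band, Hz (default `c(1, 2000)`).
#' @param baseline_ms local-baseline window before onset (default 5 ms).
#' @return object of class `mini_set`: list with `events` tibble (`time_s`,
#'   `amplitude_pA` magnitudes), `polarity`, `frequency_hz`, `duration_s`.
#' @export
detect_minis <- function(trace, polarity = c("negative", "positive"),
                         threshold_pA = 10, min_interval_s = 0.01,
                         band_hz = c(1, 2000), baseline_ms = 5) {
  polarity <- match.arg(polarity)
  fs <- sampling_rate(trace)
  x <- trace$i_pA
  sgn <- if (polarity == "negative") -1 else 1
  bf <- signal::butter(2, pmin(band_hz / (fs / 2), 0.99), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x)) * sgn    # events now positive
  runs <- find_runs(xf > threshold_pA, trace$time_s,
                    merge_gap_s = min_interval_s)
  nb <- max(1L, round(baseline_ms / 1000 * fs))
  hw <- max(1L, round(0.0005 * fs))   # +/- 0.5 ms averaging around the peak
  n <- length(x)
  ev <- purrr::pmap_dfr(runs, function(start_idx, end_idx, onset_s, offset_s, ...) {
    pk_rel <- which.max(xf[start_idx:end_idx])
    pk <- start_idx + pk_rel - 1L
    b0 <- max(1L, start_idx - nb)
    base <- median(x[b0:max(b0, start_idx - 1L)])
    peak <- mean(x[max(1L, pk - hw):min(n, pk + hw)])
    tibble(time_s = trace$time_s[pk],
           amplitude_pA = abs(peak - base))
  })
  if (!nrow(runs)) ev <- tibble(time_s = numeric(), amplitude_pA = numeric())
  dur <- diff(range(trace$time_s)) + 1 / fs
  structure(list(events = ev, polarity = polarity,
                 frequency_hz = nrow(ev) / dur, duration_s = dur,
                 threshold_pA = threshold_pA),
            class = "mini_set")
}

#' @export
print.mini_set <- function(x, ...) {
  cat(sprintf("<mini_set> %d %s events in %.1f s (%.2f Hz), mean amplitude %.1f pA\n",
              nrow(x$events), x$polarity, x$duration_s, x$frequency_hz,
              mean(x$events$amplitude_pA)))
  invisible(x)
}

#' Classify synaptic connectivity from responses at two holding potentials
#'
#' Each neuron is tested for a light-evoked excitatory inward current at
#' -70 mV and an inhibitory outward current at +10 mV; neurons are classed as
#' `both`, `excitatory_only`, `inhibitory_only` or `none`, and cohort
#' percentages (over classified neurons, to one decimal) are reported.
#'
#' @param responses tibble with one row per neuron: `neuron`,
#'   `excitatory` (logical, response at -70 mV), `inhibitory` (logical,
#'   response at +10 mV). `NA` in either column excludes the neuron (counted
#'   in `n_excluded`).
#' @return object of class `connectivity_call`: list with `calls` tibble
#'   (`neuron`, `class`), `percentages` tibble (`class`, `n`, `percent`;
#'   percentages of responsive neurons, to one decimal -- the three response
#'   classes sum to 100 up to rounding, non-responders carry `percent = 0`),
#'   `n_classified`, `n_responsive`, `n_excluded`.
#' @export
classify_connectivity <- function(responses) {
  need <- c("neuron", "excitatory", "inhibitory")
  miss <- setdiff(need, names(responses))
  if (length(miss)) abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  excl <- is.na(responses$excitatory) | is.na(responses$inhibitory)
  r <- responses[!excl, , drop = FALSE]
  cls <- dplyr::case_when(
    r$excitatory & r$inhibitory ~ "both",
    r$excitatory ~ "excitatory_only",
    r$inhibitory ~ "inhibitory_only",
    TRUE ~ "none")
  calls <- tibble(neuron = r$neuron, class = cls)
  lev <- c("both", "inhibitory_only", "excitatory_only", "none")
  counts <- as.integer(table(factor(cls, levels = lev)))
  n_resp <- sum(counts[1:3])
  pct <- tibble(class = lev, n = counts,
                percent = c(if (n_resp > 0) round(100 * counts[1:3] / n_resp, 1)
                            else rep(0, 3), 0))
  if (n_resp == 0 && nrow(r) > 0) {
    warn("No responsive neurons; class percentages are all zero.")
  }
  structure(list(calls = calls, percentages = pct,
                 n_classified = nrow(r), n_responsive = n_resp,
                 n_excluded = sum(excl)),
            class = "connectivity_call")
}

#' @export
print.connectivity_call <- function(x, ...) {
  cat(sprintf("<connectivity_call> %d neurons classified (%d excluded)\n",
              x$n_classified, x$n_excluded))
  print(x$percentages)
  invisible(x)
}

#' Normalize an evoked-amplitude series to percent of baseline
#'
#' Normalized amplitude = 100 * amplitude / mean(baseline amplitudes), where
#' the baseline comprises all sweeps up to the induction time. Minute-binned
#' means are reported, along with the values at the conventional 1st, 10th,
#' 20th and 30th post-induction minutes.
#'
#' @param amplitudes tibble `time_min`, `amplitude_pA`.
#' @param induction_time_min induction time, minutes (baseline = sweeps at or
#'   before it; default 10).
#' @param report_min post-induction minutes to report (default
#'   `c(1, 10, 20, 30)`).
#' @return object of class `ltp_timecourse`: list with `normalized` tibble
#'   (`time_min`, `percent_baseline`), `binned` tibble (`minute`,
#'   `percent_baseline`), `at_minutes` tibble, `baseline_mean_pA`.
#' @export
ltp_normalize <- function(amplitudes, induction_time_min = 10,
                          report_min = c(1, 10, 20, 30)) {
  base <- amplitudes$amplitude_pA[amplitudes$time_min <= induction_time_min]
  if (!length(base)) abort("No baseline sweeps at or before the induction time.")
  bm <- mean(base)
  if (!is.finite(bm) || bm == 0) abort("Zero baseline mean; cannot normalize.")
  norm <- dplyr::mutate(amplitudes,
                        percent_baseline = 100 * .data$amplitude_pA / bm)
  post <- dplyr::filter(norm, .data$time_min > induction_time_min)
  binned <- post |>
    dplyr::mutate(minute = ceiling(.data$time_min - induction_time_min)) |>
    dplyr::group_by(.data$minute) |>
    dplyr::summarise(percent_baseline = mean(.data$percent_baseline),
                     .groups = "drop")
  at <- tibble(minute = report_min,
               percent_baseline = binned$percent_baseline[
                 match(report_min, binned$minute)])
  structure(list(normalized = norm, binned = binned, at_minutes = at,
                 baseline_mean_pA = bm,
                 induction_time_min = induction_time_min),
            class = "ltp_timecourse")
}

#' @export
print.ltp_timecourse <- function(x, ...) {
  cat(sprintf("<ltp_timecourse> baseline mean %.1f pA; percent of baseline at minutes %s: %s\n",
              x$baseline_mean_pA,
              paste(x$at_minutes$minute, collapse = "/"),
              paste(sprintf("%.0f%%", x$at_minutes$percent_baseline), collapse = "/")))
  invisible(x)
}
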