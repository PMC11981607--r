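## Synthetic patch-clamp data with analytically known properties.
##
## Current-clamp sweeps follow a leaky integrate-and-fire model
##   tau_m dV/dt = -(V - v_rest) + I * r_m
## integrated by forward Euler at `fs`; threshold crossings paste a
## stereotyped spike waveform (Gaussian bump) and reset the membrane after a
## refractory period, so spike shape features can be tested against template
## parameters. The analytic rheobase is the smallest current with
## I * r_m > (v_threshold - v_rest).

#' Default generator parameters for a model neuron
#'
#' @param v_rest resting potential, mV.
#' @param v_threshold spike threshold, mV.
#' @param r_m membrane resistance, MOhm.
#' @param tau_m membrane time constant, ms.
#' @param spike_peak_mv spike template peak voltage, mV.
#' @param spike_sigma_ms Gaussian spike template width parameter, ms.
#' @param refractory_ms absolute refractory period, ms.
#' @return list of parameters for the sweep generators.
#' @export
neuron_params <- function(v_rest = -70, v_threshold = -60, r_m = 200,
                          tau_m = 20, spike_peak_mv = 30, spike_sigma_ms = 0.4,
                          refractory_ms = 3) {
  check_positive(r_m, "r_m"); check_positive(tau_m, "tau_m")
  if (v_threshold <= v_rest) abort("`v_threshold` must exceed `v_rest`.")
  list(v_rest = v_rest, v_threshold = v_threshold, r_m = r_m, tau_m = tau_m,
       spike_peak_mv = spike_peak_mv, spike_sigma_ms = spike_sigma_ms,
       refractory_ms = refractory_ms)
}

#' Analytic rheobase of a leaky integrate-and-fire neuron on a current grid
#'
#' Smallest grid current strictly exceeding
#' `(v_threshold - v_rest) / r_m` (the asymptotic depolarization equals the
#' threshold exactly at the critical current and is never crossed).
#'
#' @param params a [neuron_params()] list.
#' @param step_pA grid spacing, pA (default 10).
#' @param max_pA grid maximum, pA (default 100).
#' @return rheobase in pA, or `NA` if above the grid.
#' @export
analytic_rheobase <- function(params, step_pA = 10, max_pA = 100) {
  i_crit <- (params$v_threshold - params$v_rest) / params$r_m * 1000  # pA
  g <- (floor(i_crit / step_pA) + 1) * step_pA
  if (g > max_pA) NA_real_ else g
}

## integrate one current-clamp sweep; current_pA may be a scalar (applied
## over [step_on_s, step_off_s)) or a full per-sample vector
lif_sweep <- function(params, current_pA, duration_s, fs,
                      step_on_s = 0.1, step_off_s = duration_s - 0.1,
                      noise_sd_mv = 0) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  i_t <- if (length(current_pA) == n) current_pA else
    ifelse(t >= step_on_s & t < step_off_s, current_pA, 0)
  dt_ms <- 1000 / fs
  v <- numeric(n); v[1] <- params$v_rest
  spike_idx <- integer()
  refr_n <- round(params$refractory_ms / dt_ms)
  hold <- 0L
  for (k in 2:n) {
    if (hold > 0L) { v[k] <- params$v_rest; hold <- hold - 1L; next }
    dv <- (-(v[k - 1] - params$v_rest) + i_t[k - 1] * params$r_m / 1000) /
      params$tau_m * dt_ms
    v[k] <- v[k - 1] + dv
    if (v[k] >= params$v_threshold) {
      spike_idx <- c(spike_idx, k)
      hold <- refr_n
      v[k] <- params$v_threshold
    }
  }
  ## paste the stereotyped spike waveform at each threshold crossing
  sig_n <- params$spike_sigma_ms / dt_ms
  half <- ceiling(4 * sig_n)
  kern_idx <- -half:half
  for (si in spike_idx) {
    idx <- si + kern_idx
    ok <- idx >= 1 & idx <= n
    bump <- (params$spike_peak_mv - params$v_threshold) *
      exp(-kern_idx[ok]^2 / (2 * sig_n^2))
    v[idx[ok]] <- pmax(v[idx[ok]], params$v_threshold + bump)
  }
  if (noise_sd_mv > 0) v <- v + rnorm(n, 0, noise_sd_mv)
  tibble(time_s = t, v_mV = v, command_pA = i_t)
}

#' Simulate a family of current-step sweeps (F-I protocol)
#'
#' Eleven 0-100 pA steps in 10 pA increments by default.
#'
#' @param params a [neuron_params()] list.
#' @param steps_pA injected step currents (default `seq(0, 100, 10)`).
#' @param duration_s sweep length, seconds (default 0.7 with the step over
#'   `[0.1, 0.6)`).
#' @param fs sampling rate, Hz (default 10000).
#' @param noise_sd_mv additive voltage noise SD, mV.
#' @param seed integer seed.
#' @return list with `sweeps` (long tibble `step_pA`, `time_s`, `v_mV`,
#'   `command_pA`; `fs` attribute) and `truth` (list with the parameters and
#'   the analytic rheobase).
#' @export
simulate_fi_sweeps <- function(params = neuron_params(),
                               steps_pA = seq(0, 100, 10), duration_s = 0.7,
                               fs = 10000, noise_sd_mv = 0, seed = 1) {
  sw <- with_seed(seed, purrr::map_dfr(steps_pA, function(i_pA) {
    dplyr::mutate(lif_sweep(params, i_pA, duration_s, fs,
                            step_on_s = 0.1, step_off_s = 0.6,
                            noise_sd_mv = noise_sd_mv),
                  step_pA = i_pA, .before = 1)
  }))
  attr(sw, "fs") <- fs
  grid <- if (length(steps_pA) > 1) diff(steps_pA)[1] else 10
  list(sweeps = sw,
       truth = list(params = params,
                    rheobase_pA = analytic_rheobase(params, step_pA = grid,
                                                    max_pA = max(steps_pA))))
}

#' Simulate a passive membrane test-pulse sweep
#'
#' A 50 ms hyperpolarizing current step sized to give a -5 mV steady-state
#' deflection (current clamp); the voltage response is the ideal RC charging
#' curve with time constant `tau_m`.
#'
#' @param params a [neuron_params()] list.
#' @param step_mv target steady-state deflection, mV (default -5).
#' @param step_dur_s step duration, seconds (default 0.05).
#' @param fs sampling rate, Hz.
#' @param noise_sd_mv additive voltage noise SD, mV.
#' @param seed integer seed.
#' @return list with `sweep` tibble (`time_s`, `v_mV`, `command_pA`, `fs`
#'   attribute) and `truth` (r_m MOhm, tau_m ms, capacitance_pF, step_pA).
#' @export
simulate_test_pulse <- function(params = neuron_params(), step_mv = -5,
                                step_dur_s = 0.05, fs = 20000,
                                noise_sd_mv = 0, seed = 1) {
  step_pA <- step_mv / params$r_m * 1000
  pre_s <- 0.02
  dur <- pre_s + step_dur_s + 0.05
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  on <- t >= pre_s & t < pre_s + step_dur_s
  tau_s <- params$tau_m / 1000
  v <- rep(params$v_rest, n)
  v[on] <- params$v_rest + step_mv * (1 - exp(-(t[on] - pre_s) / tau_s))
  after <- t >= pre_s + step_dur_s
  v_end <- params$v_rest + step_mv * (1 - exp(-step_dur_s / tau_s))
  v[after] <- params$v_rest + (v_end - params$v_rest) *
    exp(-(t[after] - (pre_s + step_dur_s)) / tau_s)
  if (noise_sd_mv > 0) v <- with_seed(seed, v + rnorm(n, 0, noise_sd_mv))
  sweep <- tibble(time_s = t, v_mV = v,
                  command_pA = ifelse(on, step_pA, 0))
  attr(sweep, "fs") <- fs
  attr(sweep, "step_window_s") <- c(pre_s, pre_s + step_dur_s)
  list(sweep = sweep,
       truth = list(r_m = params$r_m, tau_m = params$tau_m,
                    capacitance_pF = params$tau_m / params$r_m * 1000,
                    step_pA = step_pA))
}

#' Simulate a miniature-PSC voltage-clamp trace
#'
#' Poisson events with Gaussian-distributed amplitudes and a
#' double-exponential synaptic kernel ride on band-limited baseline noise.
#'
#' @param duration_s trace length, seconds.
#' @param rate_hz mean event rate (Poisson).
#' @param amp_mean_pA,amp_sd_pA event amplitude distribution, pA (magnitude).
#' @param polarity `"negative"` (inward, mEPSC at -70 mV) or `"positive"`
#'   (outward, mIPSC at +10 mV).
#' @param tau_rise_ms,tau_decay_ms synaptic kernel time constants.
#' @param noise_sd_pA baseline current noise SD (band-limited to 1 kHz).
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return list with `trace` tibble (`time_s`, `i_pA`, `fs` attribute) and
#'   `truth` tibble (`onset_s`, `peak_time_s`, `amplitude_pA` signed).
#' @export
simulate_minis <- function(duration_s, rate_hz, amp_mean_pA = 20,
                           amp_sd_pA = 2, polarity = c("negative", "positive"),
                           tau_rise_ms = 1, tau_decay_ms = 5,
                           noise_sd_pA = 2, fs = 10000, seed) {
  polarity <- match.arg(polarity)
  check_positive(duration_s, "duration_s")
  if (rate_hz < 0) abort("`rate_hz` must be >= 0.")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  sgn <- if (polarity == "negative") -1 else 1
  with_seed(seed, {
    n_ev <- rpois(1, rate_hz * duration_s)
    onsets <- sort(runif(n_ev, 0.05, max(duration_s - 0.05, 0.05)))
    amps <- abs(rnorm(n_ev, amp_mean_pA, amp_sd_pA))
    kt <- seq(0, tau_decay_ms * 8 / 1000, by = 1 / fs)
    kern <- exp(-kt / (tau_decay_ms / 1000)) - exp(-kt / (tau_rise_ms / 1000))
    t_peak <- kt[which.max(kern)]
    kern <- kern / max(kern)
    i <- if (noise_sd_pA > 0) noise_sd_pA * band_limited_noise(n, fs, 1000) else rep(0, n)
    for (j in seq_len(n_ev)) {
      i0 <- round(onsets[j] * fs) + 1L
      idx <- i0:min(i0 + length(kern) - 1L, n)
      i[idx] <- i[idx] + sgn * amps[j] * kern[seq_along(idx)]
    }
  })
  trace <- tibble(time_s = t, i_pA = i)
  attr(trace, "fs") <- fs
  list(trace = trace,
       truth = tibble(onset_s = onsets, peak_time_s = onsets + t_peak,
                      amplitude_pA = sgn * amps))
}

#' Simulate an optically evoked EPSC amplitude series for LTP analysis
#'
#' Per-sweep amplitudes at a fixed stimulation interval, with a
#' multiplicative step change at the induction time.
#'
#' @param baseline_min baseline duration, minutes (default 10).
#' @param post_min post-induction duration, minutes (default 30).
#' @param sweep_interval_s time between evoked responses (default 10).
#' @param base_amp_pA mean baseline amplitude, pA.
#' @param potentiation_ratio post/pre amplitude ratio (1.5 = 150% of
#'   baseline).
#' @param noise_cv multiplicative amplitude noise (coefficient of
#'   variation).
#' @param seed integer seed.
#' @return list with `amplitudes` tibble (`time_min`, `amplitude_pA`),
#'   `induction_time_min`, and `truth` (the ratio).
#' @export
simulate_ltp <- function(baseline_min = 10, post_min = 30,
                         sweep_interval_s = 10, base_amp_pA = 100,
                         potentiation_ratio = 1.5, noise_cv = 0.05, seed) {
  t_min <- seq(sweep_interval_s, (baseline_min + post_min) * 60,
               by = sweep_interval_s) / 60
  amp <- ifelse(t_min <= baseline_min, base_amp_pA,
                base_amp_pA * potentiation_ratio)
  if (noise_cv > 0) {
    amp <- with_seed(seed, amp * (1 + rnorm(length(amp), 0, noise_cv)))
  }
  list(amplitudes = tibble(time_min = t_min, amplitude_pA = amp),
       induction_time_min = baseline_min,
       truth = list(potentiation_ratio = potentiation_ratio))
}
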