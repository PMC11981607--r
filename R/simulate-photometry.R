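## Synthetic two-channel photometry with known ground truth.
##
## Both channels share a single-exponential bleaching decay and a slow
## (< 2 Hz) multiplicative motion artifact; calcium transients
## (double-exponential kernels) are added to the 465 nm channel only, so the
## isosbestic subtraction has something real to remove. Measurement noise is
## band-limited rather than white: photometry front-ends low-pass their
## streams, and genuinely independent samples at kilohertz rates would make
## any per-sample threshold rule meaningless.

#' Simulate a two-channel fiber-photometry session
#'
#' @param duration_s session length in seconds.
#' @param fs sampling rate in Hz (default 1017).
#' @param transient_rate mean calcium-transient rate, events per second
#'   (Poisson event times).
#' @param transient_amp transient peak amplitude in multiples of the noise
#'   standard deviation (default 5).
#' @param tau_rise_s,tau_decay_s transient kernel time constants, seconds
#'   (defaults 0.01 and 0.15, matching fast GCaMP8-family indicator
#'   kinetics).
#' @param bleach_tau_s photobleaching time constant shared by both channels.
#' @param motion_sd motion-artifact standard deviation as a fraction of
#'   baseline fluorescence (multiplicative, common to both channels).
#' @param noise_sd measurement noise SD in fluorescence units (added
#'   independently per channel, band-limited to `noise_bw_hz`).
#' @param noise_bw_hz noise bandwidth in Hz (default 50).
#' @param f465_base,f405_base baseline fluorescence of each channel (a.u.).
#' @param seed integer seed; output is bit-identical across calls with the
#'   same seed.
#' @return list with `session` (a [photometry_session()]) and `truth`, a
#'   tibble of injected events (`onset_s`, `peak_time_s`, `amplitude` in
#'   fluorescence units).
#' @export
simulate_photometry <- function(duration_s, fs = 1017, transient_rate = 0.3,
                                transient_amp = 5, tau_rise_s = 0.01,
                                tau_decay_s = 0.15, bleach_tau_s = 600,
                                motion_sd = 0.0005, noise_sd = 0.5,
                                noise_bw_hz = 50, f465_base = 100,
                                f405_base = 90, seed) {
  check_positive(duration_s, "duration_s")
  check_positive(fs, "fs")
  if (transient_rate < 0) abort("`transient_rate` must be >= 0.")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    bleach <- exp(-t / bleach_tau_s)
    motion <- if (motion_sd > 0) motion_sd * band_limited_noise(n, fs, 2) else rep(0, n)
    shared <- bleach * (1 + motion)

    n_ev <- rpois(1, transient_rate * duration_s)
    onsets <- sort(runif(n_ev, 0, max(duration_s - 3 * tau_decay_s, 0)))

    ## double-exponential kernel normalized to unit peak
    kt <- seq(0, tau_decay_s * 6, by = 1 / fs)
    kern <- exp(-kt / tau_decay_s) - exp(-kt / tau_rise_s)
    t_peak <- kt[which.max(kern)]
    kern <- kern / max(kern)

    transients <- rep(0, n)
    amp_au <- transient_amp * noise_sd
    for (on in onsets) {
      i0 <- round(on * fs) + 1L
      idx <- i0:min(i0 + length(kern) - 1L, n)
      transients[idx] <- transients[idx] + amp_au * kern[seq_along(idx)]
    }

    e465 <- if (noise_sd > 0) noise_sd * band_limited_noise(n, fs, noise_bw_hz) else rep(0, n)
    e405 <- if (noise_sd > 0) noise_sd * band_limited_noise(n, fs, noise_bw_hz) else rep(0, n)

    f465 <- f465_base * shared + transients + e465
    f405 <- f405_base * shared + e405
  })

  truth <- tibble(onset_s = onsets, peak_time_s = onsets + t_peak,
                  amplitude = rep(amp_au, length(onsets)))
  list(session = photometry_session(t, f465, f405, fs = fs),
       truth = truth)
}
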