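# spike detection, F-I/rheobase, AP threshold and half-width, passive
# properties, minis, connectivity, LTP normalization

test_that("spike detection finds template spikes and nothing on flat traces", {
  expect_identical(detect_spikes(rep(-70, 5000), 10000), integer())

  p <- neuron_params()
  sw <- simulate_fi_sweeps(p, steps_pA = 100, seed = 1)$sweeps
  n100 <- length(detect_spikes(sw$v_mV, 10000))
  expect_gt(n100, 0)

  # doubling the sampling rate preserves the spike count
  sw2 <- simulate_fi_sweeps(p, steps_pA = 100, fs = 20000, seed = 1)$sweeps
  expect_identical(length(detect_spikes(sw2$v_mV, 20000)), n100)
})

test_that("F-I curve counts spikes per step and locates the rheobase", {
  p <- neuron_params(v_rest = -70, v_threshold = -60, r_m = 250)
  sim <- simulate_fi_sweeps(p, seed = 2)
  fi <- fi_curve(sim$sweeps)
  expect_identical(nrow(fi), 11L)
  expect_true(all(diff(fi$n_spikes) >= 0))
  # analytic: 10 mV / 250 MOhm = 40 pA exactly on the grid, so the first
  # step that strictly exceeds it fires: 50 pA
  expect_identical(attr(fi, "rheobase_pA"), 50)
  expect_identical(attr(fi, "rheobase_pA"), sim$truth$rheobase_pA)

  # no spikes anywhere: rheobase absent
  quiet <- simulate_fi_sweeps(neuron_params(v_threshold = -30), seed = 1)
  expect_true(is.na(attr(fi_curve(quiet$sweeps), "rheobase_pA")))

  # missing steps are reported
  expect_error(fi_curve(sim$sweeps[sim$sweeps$step_pA != 50, ]), "50")
})

test_that("rheobase equals the strict grid-rounded analytic value on random draws", {
  for (s in 1:8) {
    p <- withr::with_seed(s, neuron_params(
      v_threshold = -70 + runif(1, 4, 14),
      r_m = runif(1, 120, 350), tau_m = runif(1, 10, 28)))
    sim <- simulate_fi_sweeps(p, seed = s)
    expect_identical(attr(fi_curve(sim$sweeps), "rheobase_pA"),
                     analytic_rheobase(p))
  }
})

test_that("AP threshold is found at the slope criterion", {
  sp <- make_linear_spike()
  pk <- detect_spikes(sp$v, sp$fs)
  expect_length(pk, 1L)
  th <- ap_threshold(sp$v, sp$fs, pk)
  # one-sample discretization bound at the fast upstroke slope
  bound <- sp$slope_fast * 1000 / sp$fs + 1e-9
  expect_lt(abs(th - sp$v_knee), bound + 5)  # central diff spans the knee
  expect_gt(th, sp$v_knee - bound - 5)

  # halving fs at most doubles the worst-case discretization error
  sp2 <- make_linear_spike(fs = 10000)
  th2 <- ap_threshold(sp2$v, sp2$fs, detect_spikes(sp2$v, sp2$fs))
  expect_lt(abs(th2 - sp2$v_knee), 2 * (bound + 5) + 1e-9)

  # slow subthreshold ramp never reaches the slope criterion: flagged NA
  expect_warning(thr <- ap_threshold(c(rep(-70, 400), seq(-70, 5, length.out = 600)),
                                     1000, 1000),
                 "criterion")
  expect_true(is.na(thr))
})

test_that("half-width matches closed-form widths", {
  # symmetric triangular spike of 2 ms base: half-width 1 ms
  fs <- 100000
  up <- seq(-60, 40, length.out = fs / 1000 + 1)
  v <- c(rep(-60, 100), up, rev(up)[-1], rep(-60, 100))
  pk <- which.max(v)
  hw <- ap_half_width(v, fs, pk, threshold_mv = -60)
  expect_equal(hw, 1, tolerance = 2 / (fs / 1000))

  # Gaussian template: FWHM = 2 sqrt(2 ln 2) sigma within one sample
  sig <- 0.0004
  t <- seq(0, 0.02, by = 1 / 50000)
  vg <- -70 + 100 * exp(-(t - 0.01)^2 / (2 * sig^2))
  pkg_ <- detect_spikes(vg, 50000)
  hwg <- ap_half_width(vg, 50000, pkg_[1], threshold_mv = -70)
  expect_equal(hwg, 2 * sqrt(2 * log(2)) * sig * 1000,
               tolerance = 1000 / 50000)

  # degenerate spike (peak at threshold) is flagged
  expect_warning(bad <- ap_half_width(rep(-60, 100), 1000, 50,
                                      threshold_mv = -60), "Malformed")
  expect_true(is.na(bad))
})

test_that("passive properties recover an ideal RC to stated tolerances", {
  tp <- simulate_test_pulse()   # R 200 MOhm, tau 20 ms
  pp <- passive_props(tp$sweep)
  expect_lt(abs(pp$r_m_mohm - 200) / 200, 0.01)
  expect_lt(abs(pp$tau_m_ms - 20) / 20, 0.02)
  expect_equal(pp$capacitance_pF, 100, tolerance = 3)

  # noisy RC: median R error under 5% across seeds
  errs <- vapply(1:20, function(s) {
    p <- passive_props(simulate_test_pulse(noise_sd_mv = 0.2, seed = s)$sweep)
    abs(p$r_m_mohm - 200) / 200
  }, numeric(1))
  expect_lt(median(errs), 0.05)

  # zero-amplitude step errors
  flat <- tp$sweep
  flat$v_mV <- rep(-70, nrow(flat)); flat$command_pA <- 0
  expect_error(passive_props(flat), "Zero")
})

test_that("mini detection recovers rate and amplitude and is threshold-monotone", {
  r <- vapply(1:10, function(s) {
    sim <- simulate_minis(60, 2, seed = s)
    ms <- detect_minis(sim$trace)
    c(ms$frequency_hz, mean(ms$events$amplitude_pA))
  }, numeric(2))
  expect_lt(abs(mean(r[1, ]) - 2) / 2, 0.15)
  expect_lt(abs(mean(r[2, ]) - 20) / 20, 0.10)

  # flat trace: nothing
  flat <- tibble::tibble(time_s = (0:9999) / 1e4, i_pA = 0)
  attr(flat, "fs") <- 1e4
  expect_identical(nrow(detect_minis(flat)$events), 0L)

  # frequency decreasing in detection threshold
  sim <- simulate_minis(30, 2, seed = 3)
  freqs <- vapply(c(6, 10, 14, 18),
                  function(th) detect_minis(sim$trace, threshold_pA = th)$frequency_hz,
                  numeric(1))
  expect_true(all(diff(freqs) <= 0))

  # opposite polarities on the same trace find disjoint events
  neg <- detect_minis(sim$trace, "negative")
  pos <- detect_minis(sim$trace, "positive", threshold_pA = 6)
  expect_length(intersect(round(neg$events$time_s, 3),
                          round(pos$events$time_s, 3)), 0)
})

test_that("connectivity classification reproduces cohort percentages", {
  resp <- tibble::tibble(
    neuron = 1:63,
    excitatory = c(rep(TRUE, 22), rep(FALSE, 33), rep(TRUE, 8)),
    inhibitory = c(rep(TRUE, 22), rep(TRUE, 33), rep(FALSE, 8)))
  cc <- classify_connectivity(resp)
  pct <- cc$percentages
  expect_equal(pct$percent[pct$class == "both"], 34.9)
  expect_equal(pct$percent[pct$class == "inhibitory_only"], 52.4)
  expect_equal(pct$percent[pct$class == "excitatory_only"], 12.7)
  expect_equal(sum(pct$percent), 100, tolerance = 0.1)

  # one responsive neuron: 100%
  one <- classify_connectivity(tibble::tibble(neuron = 1, excitatory = TRUE,
                                              inhibitory = TRUE))
  expect_equal(one$percentages$percent[1], 100)

  # all non-responders: flagged, zero percentages
  expect_warning(
    none <- classify_connectivity(tibble::tibble(neuron = 1:4,
                                                 excitatory = FALSE,
                                                 inhibitory = FALSE)),
    "zero")
  expect_true(all(none$percentages$percent == 0))

  # NA responses exclude the neuron and are counted
  resp$excitatory[5] <- NA
  cc2 <- classify_connectivity(resp)
  expect_identical(cc2$n_excluded, 1L)
  expect_identical(cc2$n_classified, 62L)
})

test_that("LTP normalization returns percent of baseline", {
  # post equals baseline: 100% in every bin
  flat <- tibble::tibble(time_min = seq(0.5, 40, by = 0.5),
                         amplitude_pA = 80)
  lf <- ltp_normalize(flat)
  expect_true(all(abs(lf$binned$percent_baseline - 100) < 1e-12))
  expect_equal(mean(lf$normalized$percent_baseline[flat$time_min <= 10]), 100)

  # constructed 1.5x step: ~150% at the reported minutes
  sim <- simulate_ltp(potentiation_ratio = 1.5, seed = 4)
  ln <- ltp_normalize(sim$amplitudes, sim$induction_time_min)
  expect_equal(ln$at_minutes$percent_baseline, rep(150, 4), tolerance = 0.05 * 150)

  # scaling all amplitudes leaves the normalized series unchanged
  scaled <- dplyr::mutate(sim$amplitudes, amplitude_pA = amplitude_pA * 3)
  expect_equal(ltp_normalize(scaled, 10)$normalized$percent_baseline,
               ln$normalized$percent_baseline)

  expect_error(ltp_normalize(dplyr::mutate(flat, amplitude_pA = 0)), "Zero")
})
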