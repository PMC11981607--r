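# isosbestic correction, dF/F, baseline selection, transient detection,
# z-scoring, peri-event matrices

test_that("isosbestic fit subtracts the fitted control channel", {
  n <- 2000; t <- (0:(n - 1)) / 1000
  # constant channels: corrected signal is identically zero
  s0 <- photometry_session(t, rep(5, n), rep(5, n), fs = 1000)
  f0 <- fit_isosbestic(s0, degree = 2)
  expect_equal(f0$f465_corrected, rep(0, n), tolerance = 1e-10)

  # exact line: degree-1 fit reproduces it to machine precision
  line <- 2 + 3 * t
  s1 <- photometry_session(t, 10 + 0 * t, line, fs = 1000)
  f1 <- fit_isosbestic(s1, degree = 1)
  expect_equal(f1$f405_fit, line, tolerance = 1e-9)
  expect_equal(f1$f465_corrected, 10 - line, tolerance = 1e-9)

  # degree 0 subtracts the channel mean
  f2 <- fit_isosbestic(s1, degree = 0)
  expect_equal(f2$f405_fit, rep(mean(line), n))
})

test_that("dF/F is the corrected signal over the fitted control", {
  n <- 1000; t <- (0:(n - 1)) / 1000
  s <- fit_isosbestic(photometry_session(t, rep(110, n), rep(100, n), fs = 1000),
                      degree = 0)
  d <- compute_dff(s)
  expect_equal(d$dff, rep(0.10, n), tolerance = 1e-12)

  # equal channels give zero; scaling both channels leaves dF/F unchanged
  se <- fit_isosbestic(photometry_session(t, rep(100, n), rep(100, n), fs = 1000), 0)
  expect_equal(compute_dff(se)$dff, rep(0, n))
  s2 <- fit_isosbestic(photometry_session(t, rep(220, n), rep(200, n), fs = 1000), 0)
  expect_equal(compute_dff(s2)$dff, compute_dff(s)$dff)

  # non-positive denominator is a hard error naming indices
  sneg <- fit_isosbestic(photometry_session(t, rep(1, n), rep(-2, n), fs = 1000), 0)
  expect_error(compute_dff(sneg), "Non-positive")
})

test_that("baseline window draw is seeded, bounded, and unbiased", {
  dff <- make_dff(withr::with_seed(9, rnorm(40 * 1017)))
  b1 <- select_baseline(dff, seed = 5)
  b2 <- select_baseline(dff, seed = 5)
  expect_identical(b1, b2)
  dur <- b1$window[2] - b1$window[1]
  expect_gte(dur, 5); expect_lte(dur, 10)

  # pure uniform draw (single candidate) on a standard-normal trace:
  # mean of mu near 0, mean of sigma near 1
  draws <- vapply(1:200, function(s) {
    b <- select_baseline(dff, seed = s, n_candidates = 1)
    c(b$mu, b$sigma)
  }, numeric(2))
  expect_lt(abs(mean(draws[1, ])), 0.05)
  expect_lt(abs(mean(draws[2, ]) - 1), 0.05)

  # short trace errors; constant trace flags degenerate sigma
  expect_error(select_baseline(make_dff(rnorm(100)), seed = 1), "shorter")
  expect_warning(select_baseline(make_dff(rep(1, 8 * 1017)), seed = 1),
                 "zero variance")
})

test_that("transient detection honors the strict mu + 3 sigma boundary", {
  # trace whose maximum is exactly at threshold: zero events
  fs <- 1017
  x <- rep(0, 5 * fs)
  x[2000:2100] <- 3  # exactly mu + 3 sigma with mu = 0, sigma = 1
  tr <- detect_transients(make_dff(x), mu = 0, sigma = 1)
  expect_identical(tr$n_events, 0L)
  expect_identical(tr$frequency_hz, 0)

  # nudged above threshold: one event
  x[2000:2100] <- 3 + 1e-9
  expect_identical(detect_transients(make_dff(x), 0, 1)$n_events, 1L)

  expect_error(detect_transients(make_dff(x), 0, 0), "sigma")
})

test_that("detected events match a brute-force per-sample scan", {
  fs <- 500
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(5000))
    pulses <- withr::with_seed(100 + s, sort(sample(500:4500, 5)))
    for (p in pulses) x[p:(p + 30)] <- 5
    tr <- detect_transients(make_dff(x, fs), mu = 0, sigma = 1,
                            merge_gap_s = 0, min_duration_s = 0)
    # oracle: scan samples, count maximal strictly-above runs
    above <- x > 3
    runs_oracle <- sum(diff(c(FALSE, above)) == 1)
    expect_identical(tr$n_events, as.integer(runs_oracle))
  }
})

test_that("five injected square pulses are recovered at the injected times", {
  fs <- 1017
  x <- withr::with_seed(42, rnorm(20 * fs))
  at <- c(2, 5, 9, 13, 17)
  for (a in at) x[round(a * fs):(round(a * fs) + 150)] <- 5
  # white-noise floor: no merging, duration filter alone separates the
  # 150-sample pulses from single-sample noise crossings
  tr <- detect_transients(make_dff(x, fs), mu = 0, sigma = 1,
                          merge_gap_s = 0, min_duration_s = 0.02)
  expect_identical(tr$n_events, 5L)
  expect_true(all(abs(tr$events$time_s - at) < 0.2))
  expect_true(all(tr$events$amplitude > 3))
})

test_that("pipeline recovers injected transient times within 100 ms", {
  matched <- vapply(1:10, function(s) {
    sim <- simulate_photometry(120, transient_rate = 0.3, seed = s)
    res <- analyze_photometry(sim$session, seed = s + 500)
    mean(vapply(sim$truth$peak_time_s, function(pt)
      any(abs(res$transients$events$time_s - pt) < 0.1), logical(1)))
  }, numeric(1))
  expect_gte(mean(matched), 0.9)
})

test_that("raising the threshold multiplier never increases the event count", {
  # well-separated transients of graded amplitude: each either survives or
  # drops out as the threshold rises
  for (s in 1:10) {
    fs <- 500
    x <- withr::with_seed(s, 0.3 * rnorm(30 * fs))
    amps <- withr::with_seed(100 + s, runif(8, 3.2, 6.5))
    at <- seq(2, 28, length.out = 8)
    for (i in seq_along(at)) {
      j <- round(at[i] * fs)
      x[j:(j + 60)] <- amps[i]
    }
    d <- make_dff(x, fs)
    n <- vapply(c(3, 4, 5, 6), function(k)
      detect_transients(d, 0, 1, k = k)$n_events, integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("z-scoring normalizes and is affine invariant", {
  x <- withr::with_seed(3, rnorm(6000, 2, 4))
  z <- zscore_trace(make_dff(x))$z
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  z2 <- zscore_trace(make_dff(5 * x + 7))$z
  expect_equal(z2, z, tolerance = 1e-9)

  # direct arithmetic oracle on [0, 0, 0, 4]
  z4 <- zscore_trace(make_dff(c(0, 0, 0, 4)))$z
  expect_equal(z4, (c(0, 0, 0, 4) - 1) / 2)

  expect_error(zscore_trace(make_dff(rep(1, 100))), "zero")
})

test_that("peri-event matrix aligns trials and drops incomplete windows", {
  fs <- 100
  z <- rep(0, 30 * fs)
  events <- c(5, 12, 20)
  for (e in events) z[round(e * fs) + 1] <- 4   # impulse exactly at event time
  trace <- make_dff(z, fs); trace$z <- trace$dff
  pem <- peri_event_matrix(trace, events, pre_s = 2, post_s = 2)
  expect_identical(nrow(pem$matrix), 3L)
  expect_equal(pem$peaks$peak_latency_s, rep(0, 3))
  expect_equal(pem$peaks$peak, rep(4, 3))
  expect_identical(pem$n_dropped, 0L)

  # event too close to the trace start is dropped and counted
  pem2 <- peri_event_matrix(trace, c(1, events), pre_s = 2, post_s = 2)
  expect_identical(nrow(pem2$matrix), 3L)
  expect_identical(pem2$n_dropped, 1L)

  # constant zero trace: all rows and peaks zero
  z0 <- make_dff(rep(0, 1000), fs); z0$z <- 0
  pem0 <- peri_event_matrix(z0, c(5), pre_s = 1, post_s = 1)
  expect_true(all(pem0$matrix == 0))

  expect_error(peri_event_matrix(trace, c(0.1), pre_s = 2, post_s = 2), "window")
})

test_that("z-scoring commutes with peri-event extraction as an affine map", {
  fs <- 200
  x <- withr::with_seed(11, cumsum(rnorm(20 * fs)) / 10)
  d <- make_dff(x, fs)
  zd <- zscore_trace(d)
  events <- c(4, 9, 15)
  p_raw <- peri_event_matrix(dplyr::mutate(d, z = .data$dff), events, 1, 1)
  p_z <- peri_event_matrix(zd, events, 1, 1)
  expect_equal(p_z$matrix, (p_raw$matrix - mean(x)) / sd(x), tolerance = 1e-10)
})

test_that("tidy and glance summarize a transient set", {
  x <- rep(0, 3000); x[1000:1100] <- 5
  tr <- detect_transients(make_dff(x), 0, 1)
  expect_s3_class(tidy(tr), "tbl_df")
  g <- glance(tr)
  expect_identical(g$n_events, 1L)
  expect_equal(g$threshold, 3)
})
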