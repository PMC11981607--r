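## Fiber-photometry pipeline: isosbestic correction, dF/F, randomized-baseline
## transient detection, session z-scoring, peri-event matrices.
##
## A photometry session is a tibble with columns `time_s`, `f465`, `f405` and
## an `fs` attribute (Hz). The 405 nm isosbestic channel is calcium-
## independent and shares bleaching and motion artifacts with the 465 nm
## calcium-dependent channel, so a polynomial fit of the 405 channel against
## time serves as the artifact/decay estimate.

#' Construct a photometry session tibble
#'
#' @param time_s strictly increasing sample times in seconds.
#' @param f465 calcium-dependent (465 nm) fluorescence, arbitrary units.
#' @param f405 isosbestic (405 nm) fluorescence, arbitrary units.
#' @param fs sampling rate in Hz (default 1017, the acquisition rate of the
#'   supported recording system).
#' @param labels optional named list of session metadata (animal id, day,
#'   condition ...), stored as an attribute.
#' @return tibble of class `photometry_session`.
#' @export
photometry_session <- function(time_s, f465, f405, fs = 1017, labels = list()) {
  check_positive(fs, "fs")
  if (length(f465) != length(f405) || length(time_s) != length(f465)) {
    abort("`time_s`, `f465` and `f405` must have equal lengths.")
  }
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  out <- tibble(time_s = as.numeric(time_s), f465 = as.numeric(f465),
                f405 = as.numeric(f405))
  attr(out, "fs") <- fs
  attr(out, "labels") <- labels
  class(out) <- c("photometry_session", class(out))
  out
}

#' Sampling rate of a session or trace
#' @param x an object carrying an `fs` attribute.
#' @return sampling rate in Hz.
#' @export
sampling_rate <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("Object has no `fs` (sampling rate) attribute.")
  fs
}

#' Fit the isosbestic control channel and subtract it from the signal channel
#'
#' Fits a degree-`degree` polynomial of the 405 nm channel against time
#' (limiting the influence of slow fluorescence decay), then subtracts the
#' fitted control curve from the 465 nm channel.
#'
#' @param session a [photometry_session()] tibble.
#' @param degree polynomial degree (>= 0; default 2 captures monotone decay
#'   with curvature).
#' @return the session tibble with added columns `f405_fit` (fitted control
#'   curve) and `f465_corrected` (`f465 - f405_fit`); the fit coefficients are
#'   stored in attribute `isosbestic_fit`.
#' @export
fit_isosbestic <- function(session, degree = 2) {
  if (!is.numeric(degree) || degree < 0 || degree != round(degree)) {
    abort("`degree` must be a non-negative integer.")
  }
  if (!all(is.finite(session$f405)) || !all(is.finite(session$f465))) {
    abort("Channels contain non-finite values.")
  }
  tc <- session$time_s - mean(session$time_s)  # centered for conditioning
  if (degree == 0) {
    fit_vals <- rep(mean(session$f405), nrow(session))
    coefs <- mean(session$f405)
  } else {
    fit <- lm(session$f405 ~ stats::poly(tc, degree, raw = TRUE))
    if (anyNA(coef(fit))) {
      abort("Degenerate isosbestic fit: singular polynomial design matrix.")
    }
    fit_vals <- as.numeric(predict(fit))
    coefs <- coef(fit)
  }
  out <- dplyr::mutate(session, f405_fit = fit_vals,
                       f465_corrected = .data$f465 - fit_vals)
  attr(out, "fs") <- attr(session, "fs")
  attr(out, "labels") <- attr(session, "labels")
  attr(out, "isosbestic_fit") <- list(degree = degree, coefficients = coefs)
  class(out) <- class(session)
  out
}

#' Compute dF/F from an isosbestic-corrected session
#'
#' dF/F = (F465 - F405_fit) / F405_fit pointwise, where F405_fit is the fitted
#' control curve. The smooth fitted curve (not the raw noisy 405 channel) is
#' used as the denominator so that control-channel noise is not injected into
#' the ratio.
#'
#' @param session output of [fit_isosbestic()].
#' @return tibble of class `dff_trace` with columns `time_s`, `dff`; carries
#'   `fs` and the fit metadata.
#' @export
compute_dff <- function(session) {
  if (is.null(session$f405_fit)) {
    abort("Run `fit_isosbestic()` before `compute_dff()`.")
  }
  bad <- which(session$f405_fit <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Non-positive fitted denominator at %d sample(s); first indices: %s",
      length(bad), paste(head(bad, 5), collapse = ", ")))
  }
  out <- tibble(time_s = session$time_s,
                dff = (session$f465 - session$f405_fit) / session$f405_fit)
  attr(out, "fs") <- attr(session, "fs")
  attr(out, "isosbestic_fit") <- attr(session, "isosbestic_fit")
  class(out) <- c("dff_trace", class(out))
  out
}

#' Select a random baseline window and return its statistics
#'
#' Candidate windows of duration drawn uniformly from
#' `[duration_range_s[1], duration_range_s[2]]` seconds are placed uniformly
#' at random within the trace (seeded); the window with the lowest mean is
#' kept as the baseline -- a baseline segment is by definition one without
#' calcium transients, and transients can only raise the window mean, so the
#' lowest-mean candidate operationalizes "a randomly selected baseline
#' segment" without manual curation. With `n_candidates = 1` the function
#' reduces to a single pure uniform draw. The chosen window's mean (mu) and
#' standard deviation (sigma) define the detection threshold
#' `mu + k * sigma`.
#'
#' @param dff a `dff_trace` tibble.
#' @param duration_range_s window duration bounds in seconds (default 5-10 s).
#' @param seed integer seed; the draw is fully reproducible.
#' @param n_candidates number of seeded candidate windows (default 20).
#' @return list with `mu`, `sigma`, `window` (`c(start_s, end_s)`, half-open).
#' @export
select_baseline <- function(dff, duration_range_s = c(5, 10), seed,
                            n_candidates = 20) {
  total <- diff(range(dff$time_s)) + 1 / sampling_rate(dff)
  if (total < duration_range_s[1]) {
    abort(sprintf("Trace (%.2f s) is shorter than the minimum baseline duration (%g s).",
                  total, duration_range_s[1]))
  }
  stopifnot(n_candidates >= 1)
  draws <- with_seed(seed, {
    dur <- runif(n_candidates, duration_range_s[1], min(duration_range_s[2], total))
    start <- runif(n_candidates, 0, total - dur) + dff$time_s[1]
    list(dur = dur, start = start)
  })
  cands <- purrr::map2(draws$start, draws$dur, function(start, dur) {
    idx <- dff$time_s >= start & dff$time_s < start + dur
    list(mu = mean(dff$dff[idx]), sigma = sd(dff$dff[idx]),
         window = c(start, start + dur))
  })
  best <- cands[[which.min(purrr::map_dbl(cands, "mu"))]]
  if (!is.finite(best$sigma) || best$sigma == 0) {
    warn("Baseline window has zero variance; detection threshold is degenerate.")
  }
  best
}

#' Detect calcium transients exceeding mu + k * sigma
#'
#' An event is a maximal contiguous run of samples strictly above
#' `mu + k * sigma`; runs separated by less than `merge_gap_s` are merged, and
#' events shorter than `min_duration_s` are discarded. Event time is the time
#' of the within-event peak.
#'
#' @param dff a `dff_trace` tibble.
#' @param mu,sigma baseline mean and standard deviation (from
#'   [select_baseline()]); `sigma` must be positive.
#' @param k threshold multiplier (default 3).
#' @param merge_gap_s merge gap in seconds (default 0.02, about twice the
#'   noise correlation time: it reunites noise-fragmented runs of one
#'   transient without bridging distinct transients of a fast indicator).
#' @param min_duration_s minimum total supra-threshold time per event in
#'   seconds (default 0.03; brief noise excursions at kilohertz sampling are
#'   discarded, while true transients stay above threshold about twice as
#'   long).
#' @param amplitude one of `"peak_minus_mu"` (default; peak dF/F minus the
#'   baseline mean), `"peak"` (raw peak dF/F) or `"peak_z"` (peak in baseline
#'   sigma units).
#' @return object of class `transient_set`: list with `events` tibble
#'   (`time_s`, `onset_s`, `offset_s`, `amplitude`), `mu`, `sigma`,
#'   `threshold`, `frequency_hz`, `duration_s`, `n_events`.
#' @export
detect_transients <- function(dff, mu, sigma, k = 3, merge_gap_s = 0.02,
                              min_duration_s = 0.03,
                              amplitude = c("peak_minus_mu", "peak", "peak_z")) {
  amplitude <- match.arg(amplitude)
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be positive.")
  thr <- mu + k * sigma
  runs <- find_runs(dff$dff > thr, dff$time_s,
                    merge_gap_s = merge_gap_s, min_duration_s = min_duration_s)
  ev <- purrr::pmap_dfr(runs, function(start_idx, end_idx, onset_s, offset_s, ...) {
    seg <- dff$dff[start_idx:end_idx]
    pk <- which.max(seg)
    peak_val <- seg[pk]
    amp <- switch(amplitude,
                  peak_minus_mu = peak_val - mu,
                  peak = peak_val,
                  peak_z = (peak_val - mu) / sigma)
    tibble(time_s = dff$time_s[start_idx + pk - 1L],
           onset_s = onset_s, offset_s = offset_s, amplitude = amp)
  })
  if (nrow(runs) == 0) {
    ev <- tibble(time_s = numeric(), onset_s = numeric(),
                 offset_s = numeric(), amplitude = numeric())
  }
  duration <- diff(range(dff$time_s)) + 1 / sampling_rate(dff)
  structure(
    list(events = ev, mu = mu, sigma = sigma, threshold = thr, k = k,
         amplitude_type = amplitude, frequency_hz = nrow(ev) / duration,
         duration_s = duration, n_events = nrow(ev)),
    class = "transient_set")
}

#' @export
print.transient_set <- function(x, ...) {
  cat(sprintf("<transient_set> %d events in %.1f s (%.3f Hz); threshold mu + %g sigma = %.4g\n",
              x$n_events, x$duration_s, x$frequency_hz, x$k, x$threshold))
  invisible(x)
}

#' Z-score a trace against its whole-session mean and SD
#'
#' @param dff a `dff_trace` tibble (or any tibble with a `dff` column).
#' @return the input with an added `z` column (session mean 0, SD 1).
#' @export
zscore_trace <- function(dff) {
  s <- sd(dff$dff)
  if (!is.finite(s) || s == 0) abort("Session standard deviation is zero; cannot z-score.")
  out <- dplyr::mutate(dff, z = (.data$dff - mean(.data$dff)) / s)
  attr(out, "fs") <- attr(dff, "fs")
  class(out) <- class(dff)
  out
}

#' Build a trials-by-time peri-event matrix of z-scored signal
#'
#' Extracts a window `[-pre_s, post_s]` of signal around each event time;
#' events whose windows fall outside the trace are dropped (and counted).
#' Column 0 of the time axis corresponds to the event time.
#'
#' @param trace tibble with `time_s` and a signal column.
#' @param event_times_s event times in seconds.
#' @param pre_s,post_s window extent before/after the event, seconds.
#' @param signal_col name of the signal column (default `"z"`).
#' @return object of class `peri_event_matrix`: list with `matrix`
#'   (trials x time), `time_offset_s`, `peaks` tibble (`event_time_s`,
#'   `peak`, `peak_latency_s` per kept trial), `n_dropped`.
#' @export
peri_event_matrix <- function(trace, event_times_s, pre_s, post_s,
                              signal_col = "z") {
  if (!signal_col %in% names(trace)) {
    abort(sprintf("Column `%s` not found; z-score the trace first or set `signal_col`.",
                  signal_col))
  }
  fs <- sampling_rate(trace)
  x <- trace[[signal_col]]
  n <- length(x)
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  offsets <- seq(-n_pre, n_post) / fs
  rows <- list(); kept <- numeric(); dropped <- 0L
  for (et in event_times_s) {
    ci <- which.min(abs(trace$time_s - et))
    if (ci - n_pre < 1 || ci + n_post > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- x[(ci - n_pre):(ci + n_post)]
    kept <- c(kept, et)
  }
  if (!length(rows)) abort("No event has a complete peri-event window.")
  m <- do.call(rbind, rows)
  pk_idx <- apply(m, 1, which.max)
  peaks <- tibble(event_time_s = kept,
                  peak = m[cbind(seq_len(nrow(m)), pk_idx)],
                  peak_latency_s = offsets[pk_idx])
  structure(list(matrix = m, time_offset_s = offsets, peaks = peaks,
                 window = c(pre_s = pre_s, post_s = post_s),
                 n_dropped = dropped),
            class = "peri_event_matrix")
}

#' @export
print.peri_event_matrix <- function(x, ...) {
  cat(sprintf("<peri_event_matrix> %d trials x %d samples, window [-%g, %g] s, %d dropped\n",
              nrow(x$matrix), ncol(x$matrix), x$window[["pre_s"]],
              x$window[["post_s"]], x$n_dropped))
  invisible(x)
}

#' Run the full photometry pipeline on a session
#'
#' Convenience wrapper: isosbestic fit, dF/F, random baseline, transient
#' detection, z-scoring.
#'
#' @inheritParams fit_isosbestic
#' @inheritParams detect_transients
#' @param seed seed for the random baseline draw.
#' @param ... passed on to [detect_transients()].
#' @return list with `dff` (z-scored dF/F trace), `baseline`, `transients`.
#' @export
analyze_photometry <- function(session, seed, degree = 2, k = 3, ...) {
  dff <- compute_dff(fit_isosbestic(session, degree = degree))
  bl <- select_baseline(dff, seed = seed)
  tr <- detect_transients(dff, mu = bl$mu, sigma = bl$sigma, k = k, ...)
  list(dff = zscore_trace(dff), baseline = bl, transients = tr)
}
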