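## broom-style tidy() / glance() methods for the package's result objects.

#' @export
tidy.transient_set <- function(x, ...) x$events

#' @export
glance.transient_set <- function(x, ...) {
  tibble(n_events = x$n_events, frequency_hz = x$frequency_hz,
         mean_amplitude = if (x$n_events) mean(x$events$amplitude) else NA_real_,
         mu = x$mu, sigma = x$sigma, threshold = x$threshold,
         duration_s = x$duration_s)
}

#' @export
tidy.peri_event_matrix <- function(x, ...) {
  m <- x$matrix
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    tibble(trial = i, time_offset_s = x$time_offset_s, z = m[i, ])
  })
}

#' @export
glance.peri_event_matrix <- function(x, ...) {
  tibble(n_trials = nrow(x$matrix), n_dropped = x$n_dropped,
         mean_peak = mean(x$peaks$peak),
         mean_peak_latency_s = mean(x$peaks$peak_latency_s))
}

#' @export
tidy.occupancy_summary <- function(x, ...) x$zone_times

#' @export
glance.occupancy_summary <- function(x, ...) {
  tibble(duration_s = x$duration_s, total_distance_mm = x$total_distance_mm,
         n_outside = x$n_outside)
}

#' @export
tidy.mini_set <- function(x, ...) x$events

#' @export
glance.mini_set <- function(x, ...) {
  tibble(polarity = x$polarity, n_events = nrow(x$events),
         frequency_hz = x$frequency_hz,
         mean_amplitude_pA = if (nrow(x$events)) mean(x$events$amplitude_pA) else NA_real_,
         duration_s = x$duration_s)
}

#' @export
tidy.connectivity_call <- function(x, ...) x$percentages

#' @export
glance.connectivity_call <- function(x, ...) {
  tibble(n_classified = x$n_classified, n_responsive = x$n_responsive,
         n_excluded = x$n_excluded)
}

#' @export
tidy.ltp_timecourse <- function(x, ...) x$binned

#' @export
glance.ltp_timecourse <- function(x, ...) {
  tibble(baseline_mean_pA = x$baseline_mean_pA,
         plateau_percent = mean(utils::tail(x$binned$percent_baseline, 10)))
}

#' @export
tidy.group_report <- function(x, ...) x$summary

#' @export
glance.group_report <- function(x, ...) x$test
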