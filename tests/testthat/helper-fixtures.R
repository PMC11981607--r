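# fixtures built in code; no data files

# wrap a numeric vector as a dff trace at a given sampling rate
make_dff <- function(values, fs = 1017) {
  out <- tibble::tibble(time_s = (seq_along(values) - 1) / fs,
                        dff = as.numeric(values))
  attr(out, "fs") <- fs
  class(out) <- c("dff_trace", class(out))
  out
}

# synthetic action potential with a piecewise-linear upstroke: slow ramp
# (slope_slow V/s) to v_knee, fast ramp (slope_fast V/s) to v_peak, then a
# symmetric linear repolarization
make_linear_spike <- function(fs = 20000, v_rest = -70, v_knee = -52,
                              v_peak = 30, slope_slow = 10, slope_fast = 100) {
  dt <- 1 / fs
  seg <- function(from, to, slope_v_per_s) {
    n <- ceiling((to - from) / (slope_v_per_s * 1000) / dt)
    seq(from, to, length.out = n + 1)[-1]
  }
  v <- c(rep(v_rest, 50),
         seg(v_rest, v_knee, slope_slow),
         seg(v_knee, v_peak, slope_fast),
         rev(seg(v_rest, v_peak, slope_fast))[-1],
         rep(v_rest, 50))
  list(v = v, fs = fs, v_knee = v_knee, v_peak = v_peak,
       slope_fast = slope_fast)
}

# draw a varied scripted-event mix that fits inside duration_s
draw_event_mix <- function(seed, duration_s = 180) {
  withr::with_seed(seed, {
    kinds <- c("pause_then_return_run", "pause_then_return_walk",
               "pause_then_exit_open", "open_to_closed_run",
               "open_to_closed_walk", "fast_run")
    n_max <- max(1, floor((duration_s - 35) / 25) + 1)
    n <- sample(2:min(6, n_max), 1)
    scripted_events(sample(kinds, n, replace = TRUE),
                    time_s = 20 + (seq_len(n) - 1) * 25)
  })
}
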