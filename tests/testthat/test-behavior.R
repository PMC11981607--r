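# speed computation, occupancy, preference indices, event detectors, pupil

make_traj <- function(x, y, fps = 30, arena = "epm") {
  as_trajectory(tibble::tibble(time_s = (seq_along(x) - 1) / fps,
                               x_mm = x, y_mm = y),
                fps = fps, arena = arena)
}

test_that("speed is zero at rest and exact for uniform motion", {
  st <- compute_speed(make_traj(rep(0, 100), rep(-150, 100)))
  expect_equal(st$speed_mm_s, rep(0, 100))

  # uniform 100 mm/s along x (away from the smoothing-window edges)
  n <- 300
  un <- compute_speed(make_traj(100 * (0:(n - 1)) / 30, rep(0, n)))
  expect_equal(un$speed_mm_s[8:(n - 7)], rep(100, n - 14), tolerance = 1e-6)
  expect_length(un$speed_mm_s, n)

  expect_error(compute_speed(make_traj(1, 1)), "two frames")
})

test_that("doubling the frame rate preserves the speed profile", {
  dur <- 10
  xf <- function(t) 120 * sin(2 * pi * t / 5)
  t30 <- seq(0, dur, by = 1 / 30); t60 <- seq(0, dur, by = 1 / 60)
  v30 <- compute_speed(make_traj(xf(t30), rep(0, length(t30)), fps = 30))
  v60 <- compute_speed(make_traj(xf(t60), rep(0, length(t60)), fps = 60))
  v60_at_30 <- approx(v60$time_s, v60$speed_mm_s, xout = v30$time_s)$y
  mid <- 10:(nrow(v30) - 10)
  expect_equal(v30$speed_mm_s[mid], v60_at_30[mid], tolerance = 0.05)
})

test_that("occupancy conserves time and counts debounced entries", {
  # stay in the closed arm: zero open time, zero open entries
  st <- make_traj(rep(0, 300), rep(-150, 300))
  occ <- zone_occupancy(st)
  zt <- tidy(occ)
  expect_equal(zt$time_s[zt$zone == "open_arm_1"], 0)
  expect_identical(zt$entries[zt$zone == "open_arm_1"], 0L)
  expect_equal(sum(zt$time_s), occ$duration_s, tolerance = 1 / 30)
  expect_equal(occ$total_distance_mm, 0)

  # four scripted open-arm entries are counted as four
  ev <- scripted_events(rep("arm_entry", 4), c(20, 45, 70, 95))
  sim <- simulate_trajectory("epm", 115, events = ev, seed = 1)
  occ2 <- zone_occupancy(sim$trajectory)
  zt2 <- tidy(occ2)
  expect_identical(zt2$entries[zt2$zone == "open_arm_1"], 4L)
  expect_equal(sum(zt2$time_s), occ2$duration_s, tolerance = 1 / 30)
})

test_that("total distance matches the smoothed polyline length", {
  sim <- simulate_trajectory("epm", 120, events = draw_event_mix(4, 120), seed = 4)
  occ <- zone_occupancy(sim$trajectory)
  # oracle: polyline length of the same smoothed path
  k <- round(0.2 * 30)
  sm <- function(v) stats::filter(c(rep(v[1], 3), v, rep(v[length(v)], 3)),
                                  rep(1 / 7, 7), sides = 2)[4:(length(v) + 3)]
  xs <- sm(sim$trajectory$x_mm); ys <- sm(sim$trajectory$y_mm)
  oracle <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  expect_equal(occ$total_distance_mm, oracle, tolerance = 0.01 * oracle)
})

test_that("preference indices are plain ratios with flagged degenerate cases", {
  expect_equal(preference_index(10, 10, "tct")$index, 1)
  expect_equal(preference_index(6, 2, "spt")$index, 0.75)
  z <- preference_index(5, 0, "tct")
  expect_false(z$defined)
  expect_true(is.na(z$index))
})

test_that("fast running uses a strict threshold with debouncing", {
  spd <- function(v) {
    tr <- tibble::tibble(time_s = (seq_along(v) - 1) / 30, speed_mm_s = v)
    tr
  }
  # constant sub-threshold speed: none
  expect_identical(nrow(detect_fast_running(spd(rep(100, 300)))), 0L)
  # speed touching exactly 400: not counted ("exceeding" is strict)
  expect_identical(nrow(detect_fast_running(spd(rep(400, 300)))), 0L)
  expect_identical(nrow(detect_fast_running(spd(rep(400 + 1e-9, 300)))), 1L)

  # two bouts separated by 5 s of walking: two episodes; brute-force oracle
  v <- rep(100, 600)
  v[100:130] <- 600; v[280:310] <- 600
  ev <- detect_fast_running(spd(v))
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$peak_speed, c(600, 600))
  oracle_runs <- sum(diff(c(FALSE, v > 400)) == 1)
  expect_identical(nrow(ev), as.integer(oracle_runs))
})

test_that("fast-running count is monotone in threshold and merge gap", {
  # well-separated bouts with graded peaks over a quiet walking floor
  v <- withr::with_seed(8, 100 + abs(rnorm(3000, 0, 20)))
  peaks <- withr::with_seed(9, runif(8, 420, 700))
  at <- seq(100, 2800, length.out = 8)
  for (i in seq_along(at)) v[at[i]:(at[i] + 20)] <- peaks[i]
  tr <- tibble::tibble(time_s = (seq_along(v) - 1) / 30, speed_mm_s = v)
  n_thr <- vapply(c(350, 400, 450, 500, 600),
                  function(th) nrow(detect_fast_running(tr, threshold = th)),
                  numeric(1))
  expect_true(all(diff(n_thr) <= 0))
  n_gap <- vapply(c(0, 0.1, 0.2, 0.5, 2),
                  function(g) nrow(detect_fast_running(tr, merge_gap = g)),
                  numeric(1))
  expect_true(all(diff(n_gap) <= 0))  # larger gaps merge more, never split
})

test_that("center-pause outcomes are classified by destination and speed", {
  # never enters the center: no events
  quiet <- compute_speed(simulate_trajectory("epm", 30, seed = 1)$trajectory)
  expect_identical(nrow(classify_center_pause_outcomes(quiet)), 0L)

  ev <- scripted_events(c("pause_then_return_run", "pause_then_exit_open"),
                        c(20, 50))
  sim <- simulate_trajectory("epm", 70, events = ev, seed = 2)
  traj <- compute_speed(sim$trajectory)
  out <- classify_center_pause_outcomes(traj)
  expect_identical(out$kind, c("pause_then_return_run", "pause_then_exit_open"))
  tr_pause <- sim$truth[grepl("pause", sim$truth$kind), ]
  expect_true(all(abs(out$onset_s - tr_pause$onset_s) <= 2 / 30 + 1e-9))

  # walking exits to the closed arm are labeled walk
  evw <- scripted_events("pause_then_return_walk", 20)
  simw <- simulate_trajectory("epm", 40, events = evw, seed = 3)
  outw <- classify_center_pause_outcomes(compute_speed(simw$trajectory))
  expect_identical(outw$kind, "pause_then_return_walk")

  expect_error(
    classify_center_pause_outcomes(
      compute_speed(simulate_trajectory("open_field", 20, seed = 1)$trajectory)),
    "EPM")
})

test_that("open-to-closed transitions are directional and labeled by speed", {
  # no open-arm visit: no events
  quiet <- compute_speed(simulate_trajectory("epm", 30, seed = 1)$trajectory)
  expect_identical(nrow(detect_open_to_closed_transitions(quiet)), 0L)

  ev <- scripted_events(c("open_to_closed_run", "open_to_closed_walk"),
                        c(20, 50))
  sim <- simulate_trajectory("epm", 70, events = ev, seed = 4)
  traj <- compute_speed(sim$trajectory)
  out <- detect_open_to_closed_transitions(traj)
  tr_o2c <- sim$truth[grepl("open_to_closed", sim$truth$kind), ]
  expect_identical(out$kind, tr_o2c$kind)
  expect_true(all(abs(out$onset_s - tr_o2c$onset_s) <= 2 / 30 + 1e-9))

  # a closed -> open entry alone emits nothing
  eve <- scripted_events("arm_entry", 15)
  sime <- simulate_trajectory("epm", 25, events = eve, seed = 5)
  # drop the frames after the dwell so the return leg is not included
  keep <- sime$trajectory$time_s <= 17
  part <- as_trajectory(sime$trajectory[keep, ], fps = 30, arena = "epm")
  expect_identical(nrow(detect_open_to_closed_transitions(compute_speed(part))), 0L)
})

test_that("pupil timecourse normalizes to the pre period", {
  fps <- 30; n <- 30 * fps
  t <- (0:(n - 1)) / fps
  base <- tibble::tibble(
    time_s = t,
    pupil_left_x = -1, pupil_left_y = 0, pupil_right_x = 1, pupil_right_y = 0,
    pupil_top_x = 0, pupil_top_y = 1, pupil_bottom_x = 0, pupil_bottom_y = -1,
    eyelid_top_x = 0, eyelid_top_y = 2, eyelid_bottom_x = 0, eyelid_bottom_y = -2)

  # constant keypoints: normalized size 1 at all three timepoints
  pc <- pupil_timecourse(base)
  expect_equal(pc$samples$pupil_diameter, rep(1, 3))
  expect_equal(pc$samples$eye_size, rep(1, 3))

  # x1.5 dilation during the light window: light sample = 1.5 (area 2.25)
  dil <- base
  light <- t >= 10 & t < 20
  for (col in grep("pupil_.*_(x|y)$", names(dil), value = TRUE)) {
    dil[[col]][light] <- dil[[col]][light] * 1.5
  }
  pd <- pupil_timecourse(dil)
  expect_equal(pd$samples$pupil_diameter,
               c(1, 1.5, 1), tolerance = 1e-10)
  expect_equal(pd$samples$pupil_area[2], 2.25, tolerance = 1e-10)

  # a 2 s low-likelihood gap is an error naming the gap
  gap <- base
  gap$pupil_left_likelihood <- 1
  gap$pupil_left_likelihood[t >= 3 & t < 5] <- 0
  expect_error(pupil_timecourse(gap), "gap")
})
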