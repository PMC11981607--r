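## Synthetic arena trajectories with scripted, fully known behavioral events.
##
## The animal is modelled as a point moving along straight legs between
## waypoints with trapezoidal speed profiles (linear ramps of `ramp_s`
## seconds, then a cruise). Between events it dwells at an arena anchor.
## In the plus maze, legs are routed through the center square so the path
## never leaves the arms. Every event the constructed path realizes --
## scripted ones and incidental ones created by transit legs (e.g. walking
## back from an open arm crosses open -> closed) -- is logged in the ground
## truth, so detectors can be held to exact recovery.

#' Helper: scripted-event table for [simulate_trajectory()]
#'
#' @param kind character vector of event kinds: `fast_run`,
#'   `pause_then_return_run`, `pause_then_return_walk`,
#'   `pause_then_exit_open`, `open_to_closed_run`, `open_to_closed_walk`,
#'   `arm_entry`.
#' @param time_s time (seconds) at which the event proper begins.
#' @param arm target arm for `arm_entry` (default `"open_arm_1"`).
#' @return tibble understood by [simulate_trajectory()].
#' @export
scripted_events <- function(kind, time_s, arm = NA_character_) {
  tibble(kind = kind, time_s = time_s,
         arm = dplyr::coalesce(arm, "open_arm_1"))
}

## distance covered at offset t into a trapezoidal profile
trap_s <- function(t, L, v, r, T) {
  a <- v / r
  t <- pmin(pmax(t, 0), T)
  ifelse(t <= r, a * t^2 / 2,
         ifelse(t <= T - r, a * r^2 / 2 + v * (t - r),
                L - a * (T - t)^2 / 2))
}

## one straight leg; returns positions sampled at the frame grid plus timing
make_leg <- function(from, to, v_peak, ramp_s, fps) {
  L <- sqrt(sum((to - from)^2))
  if (L < 1e-9) return(list(pos = matrix(numeric(0), ncol = 2), dur = 0,
                            v_actual = 0, ramp_s = ramp_s, T_true = 0))
  if (L >= v_peak * ramp_s) {
    v <- v_peak; T <- L / v_peak + ramp_s; r <- ramp_s
  } else {                                   # short leg: triangular profile
    a <- v_peak / ramp_s
    v <- sqrt(L * a); T <- 2 * v / a; r <- T / 2
  }
  n <- max(1L, ceiling(T * fps))
  tt <- seq_len(n) / fps
  s <- trap_s(tt, L, v, r, T)
  dir <- (to - from) / L
  pos <- cbind(from[1] + dir[1] * s, from[2] + dir[2] * s)
  pos[n, ] <- to
  list(pos = pos, dur = n / fps, v_actual = v, ramp_s = r, T_true = T)
}

#' Simulate an arena trajectory with scripted behavioral events
#'
#' @param arena arena name, see [arena_zones()].
#' @param duration_s session length, seconds.
#' @param fps frame rate (default 30).
#' @param events scripted-event table from [scripted_events()] (may be empty).
#' @param walk_speed cruise speed of walking legs, mm/s (default 150; must be
#'   below the 400 mm/s fast-running threshold).
#' @param run_speed cruise speed of running legs, mm/s (default 600).
#' @param ramp_s accel/decel ramp duration, seconds.
#' @param pause_s dwell duration of scripted center pauses, seconds.
#' @param jitter_mm isotropic Gaussian position jitter, mm (default 0).
#' @param seed integer seed (used only for jitter, but required so the
#'   reproducibility contract is uniform across generators).
#' @return list with `trajectory` (tibble `time_s`, `x_mm`, `y_mm`,
#'   `true_speed`, `regime`, with `fps`/`arena` attributes) and `truth`, a
#'   tibble of realized events (`kind`, `onset_s`, `offset_s`, `peak_speed`).
#' @export
simulate_trajectory <- function(arena = "epm", duration_s, fps = 30,
                                events = scripted_events(character(), numeric()),
                                walk_speed = 150, run_speed = 600,
                                ramp_s = 0.1, pause_s = 0.8, jitter_mm = 0,
                                seed = 1) {
  check_positive(duration_s, "duration_s")
  check_positive(fps, "fps")
  zones <- arena_zones(arena)
  if (walk_speed >= 400) abort("`walk_speed` must stay below the 400 mm/s running threshold.")
  epm_only <- c("pause_then_return_run", "pause_then_return_walk",
                "pause_then_exit_open", "open_to_closed_run",
                "open_to_closed_walk", "arm_entry")
  if (arena != "epm" && any(events$kind %in% epm_only)) {
    abort("Maze-specific scripted events require `arena = \"epm\"`.")
  }
  if (nrow(events) && (any(events$time_s < 0) || any(events$time_s > duration_s))) {
    abort("Scripted event times must lie inside [0, duration_s].")
  }

  anchor <- switch(arena, epm = c(0, -150), open_field = c(-200, -150),
                   two_chamber = c(-125, 0), three_chamber = c(-180, 0))
  dash_path <- switch(arena,
    epm = list(c(0, -200), c(0, 200)),
    open_field = list(c(-200, -150), c(200, -150)),
    two_chamber = list(c(-200, 0), c(200, 0)),
    three_chamber = list(c(-200, 0), c(200, 0)))

  ## in the plus maze, route legs through the center square when the start
  ## and end points do not share an arm corridor
  route <- function(from, to) {
    if (arena != "epm") return(list(to))
    band <- function(v) abs(v) <= 25
    if ((band(from[1]) && band(to[1])) || (band(from[2]) && band(to[2]))) {
      list(to)
    } else {
      list(c(0, 0), to)
    }
  }

  pos_list <- list(); leg_tab <- list()
  cur <- anchor; cur_t <- 0

  add_leg <- function(to, v, role, event_id, kind = NA_character_) {
    for (wp in route(cur, to)) {
      lg <- make_leg(cur, wp, v, ramp_s, fps)
      if (nrow(lg$pos) == 0) next
      pos_list[[length(pos_list) + 1L]] <<- lg$pos
      leg_tab[[length(leg_tab) + 1L]] <<- tibble(
        role = role, event_id = event_id, kind = kind,
        v_peak = lg$v_actual, ramp_s = lg$ramp_s,
        start_s = cur_t, end_s = cur_t + lg$dur, T_true = lg$T_true)
      cur_t <<- cur_t + lg$dur
      cur <<- wp
    }
    invisible(NULL)
  }
  add_dwell <- function(dur_s, role = "dwell", event_id = NA_integer_) {
    n <- round(dur_s * fps)
    if (n <= 0) return(invisible(NULL))
    pos_list[[length(pos_list) + 1L]] <<- matrix(rep(cur, each = n), ncol = 2)
    leg_tab[[length(leg_tab) + 1L]] <<- tibble(
      role = role, event_id = event_id, kind = NA_character_,
      v_peak = 0, ramp_s = 0, start_s = cur_t, end_s = cur_t + n / fps,
      T_true = n / fps)
    cur_t <<- cur_t + n / fps
    invisible(NULL)
  }
  seg_time <- function(from, to, v) {
    L <- sqrt(sum((to - from)^2))
    if (L < 1e-9) 0 else if (L >= v * ramp_s) L / v + ramp_s else 2 * sqrt(L * ramp_s / v)
  }
  transit_time <- function(from, wps, v) {
    tt <- 0; p <- from
    for (w in wps) for (seg in route(p, w)) { tt <- tt + seg_time(p, seg, v); p <- seg }
    tt
  }

  arm_point <- function(arm) switch(arm,
    open_arm_1 = c(150, 0), open_arm_2 = c(-150, 0),
    closed_arm_1 = c(0, -150), closed_arm_2 = c(0, 150),
    abort(sprintf("Unknown arm `%s`.", arm)))

  ev <- events[order(events$time_s), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    kind <- ev$kind[i]; et <- ev$time_s[i]
    pre <- switch(kind,
      fast_run = list(dash_path[[1]]),
      pause_then_return_run = ,
      pause_then_return_walk = ,
      pause_then_exit_open = list(c(0, 0)),
      open_to_closed_run = ,
      open_to_closed_walk = list(c(150, 0)),
      arm_entry = list(),
      abort(sprintf("Unknown scripted event kind `%s`.", kind)))
    slack <- et - (cur_t + transit_time(cur, pre, walk_speed))
    if (slack < -2 / fps) {
      abort(sprintf("Scripted `%s` at %.2f s cannot be reached in time.", kind, et))
    }
    add_dwell(max(slack, 0))
    for (wp in pre) add_leg(wp, walk_speed, "transit", i)
    ## the event proper
    if (kind == "fast_run") {
      add_leg(dash_path[[2]], run_speed, "dash", i, kind)
      add_leg(anchor, walk_speed, "transit", i)
    } else if (kind %in% c("pause_then_return_run", "pause_then_return_walk",
                           "pause_then_exit_open")) {
      add_dwell(pause_s, role = "pause", event_id = i)
      if (kind == "pause_then_return_run") {
        add_leg(c(0, -255), run_speed, "exit", i, kind)
        add_leg(anchor, walk_speed, "transit", i)
      } else if (kind == "pause_then_return_walk") {
        add_leg(c(0, -150), walk_speed, "exit", i, kind)
      } else {
        add_leg(c(150, 0), walk_speed, "exit", i, kind)
        add_leg(anchor, walk_speed, "return_from_open", i)
      }
    } else if (kind %in% c("open_to_closed_run", "open_to_closed_walk")) {
      add_dwell(0.5, role = "predash", event_id = i)
      v <- if (kind == "open_to_closed_run") run_speed else walk_speed
      add_leg(c(0, 0), v, "o2c_dash", i, kind)
      add_leg(c(0, -200), v, "o2c_dash", i, kind)
      add_leg(anchor, walk_speed, "transit", i)
    } else if (kind == "arm_entry") {
      add_leg(arm_point(ev$arm[i]), walk_speed, "entry", i, kind)
      add_dwell(1, role = "entry_dwell", event_id = i)
      add_leg(anchor, walk_speed,
              if (startsWith(ev$arm[i], "open")) "return_from_open" else "transit", i)
    }
  }
  n_total <- round(duration_s * fps)
  pos <- do.call(rbind, c(list(matrix(anchor, ncol = 2)), pos_list))
  if (nrow(pos) > n_total + 1) {
    abort("Scripted events do not fit inside `duration_s`.")
  }
  if (nrow(pos) < n_total) {
    pos <- rbind(pos, matrix(rep(cur, each = n_total - nrow(pos)), ncol = 2))
  }
  pos <- pos[seq_len(n_total), , drop = FALSE]
  if (jitter_mm > 0) {
    pos <- with_seed(seed, pos + matrix(rnorm(length(pos), 0, jitter_mm), ncol = 2))
  }
  t <- (seq_len(n_total) - 1) / fps
  step <- sqrt(rowSums((pos - rbind(pos[1, , drop = FALSE],
                                    pos[-n_total, , drop = FALSE]))^2))
  true_speed <- step * fps
  if (n_total > 1) true_speed[1] <- true_speed[2]

  traj <- tibble(time_s = t, x_mm = pos[, 1], y_mm = pos[, 2],
                 true_speed = true_speed,
                 regime = ifelse(true_speed >= 400, "run", "walk"))
  attr(traj, "fps") <- fps
  attr(traj, "arena") <- arena
  class(traj) <- c("trajectory", class(traj))

  legs <- if (length(leg_tab)) dplyr::bind_rows(leg_tab) else
    tibble(role = character(), event_id = integer(), kind = character(),
           v_peak = numeric(), ramp_s = numeric(), start_s = numeric(),
           end_s = numeric(), T_true = numeric())

  list(trajectory = traj, truth = derive_truth(legs, traj, zones, ev))
}

## assemble the ground-truth event table from the leg annotations and the
## sampled positions (zone crossings are read off the samples themselves, so
## truth and detectors share one definition of "crossing")
derive_truth <- function(legs, traj, zones, ev) {
  out <- list()
  thr <- 400
  fps <- attr(traj, "fps")
  za <- assign_zones(traj$x_mm, traj$y_mm, zones)$zone
  open_v <- startsWith(za, "open_arm")
  closed_v <- startsWith(za, "closed_arm")

  add <- function(kind, onset, offset, peak) {
    out[[length(out) + 1L]] <<- tibble(kind = kind, onset_s = onset,
                                       offset_s = offset, peak_speed = peak)
  }
  ## analytic first/last time a (possibly multi-leg) dash exceeds 400 mm/s
  add_fast_run <- function(dl) {
    first <- dl[1, ]; last <- dl[nrow(dl), ]
    if (max(dl$v_peak) <= thr) return(invisible(NULL))
    add("fast_running",
        first$start_s + first$ramp_s * thr / first$v_peak,
        last$start_s + last$T_true - last$ramp_s * thr / last$v_peak,
        max(dl$v_peak))
  }
  o2c_from_range <- function(i0, i1, peak, kind) {
    idx <- i0:i1
    op <- idx[open_v[idx]]; cl <- idx[closed_v[idx]]
    if (!length(op)) return(invisible(NULL))
    cl_after <- cl[cl > min(op)]
    if (!length(cl_after)) return(invisible(NULL))
    last_open <- max(op[op < min(cl_after)])
    add(kind, traj$time_s[last_open + 1L], traj$time_s[min(cl_after)], peak)
  }
  idx_of <- function(ts) pmin(pmax(round(ts * fps) + 1L, 1L), nrow(traj))

  for (eid in unique(stats::na.omit(legs$event_id))) {
    sub <- legs[!is.na(legs$event_id) & legs$event_id == eid, , drop = FALSE]
    kind <- ev$kind[eid]
    if (kind == "fast_run") {
      add_fast_run(sub[sub$role == "dash", , drop = FALSE])
    } else if (kind %in% c("pause_then_return_run", "pause_then_return_walk",
                           "pause_then_exit_open")) {
      lg <- sub[sub$role == "exit", ][1, ]
      add(kind, lg$start_s, lg$end_s, lg$v_peak)
      add_fast_run(sub[sub$role == "exit", , drop = FALSE])
    } else if (kind %in% c("open_to_closed_run", "open_to_closed_walk")) {
      dl <- sub[sub$role == "o2c_dash", , drop = FALSE]
      rng <- idx_of(c(min(sub$start_s), max(dl$end_s)))
      o2c_from_range(rng[1], rng[2], max(dl$v_peak), kind)
      add_fast_run(dl)
    } else if (kind == "arm_entry") {
      lg <- sub[sub$role == "entry", ][1, ]
      rng <- idx_of(c(lg$start_s, max(sub$end_s)))
      in_arm <- which(za[rng[1]:rng[2]] == ev$arm[eid]) + rng[1] - 1L
      if (length(in_arm)) add("arm_entry", traj$time_s[min(in_arm)],
                              traj$time_s[max(in_arm)], lg$v_peak)
    }
  }
  ## incidental open -> closed walks created by return transits
  rfo <- legs[legs$role == "return_from_open", , drop = FALSE]
  for (g in unique(rfo$event_id)) {
    sub <- rfo[rfo$event_id == g, , drop = FALSE]
    rng <- idx_of(c(min(sub$start_s), max(sub$end_s)))
    o2c_from_range(rng[1], rng[2], max(sub$v_peak), "open_to_closed_walk")
  }
  if (!length(out)) {
    return(tibble(kind = character(), onset_s = numeric(),
                  offset_s = numeric(), peak_speed = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$onset_s)
}
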