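## File adapters. All files are UTF-8 CSV with header rows (JSON for nested
## structures); the writers emit exactly the dialects the readers accept, so
## simulate -> write -> read -> analyze round-trips without glue code.

#' Read / write a two-channel photometry CSV
#'
#' Columns `time_s,f465,f405`.
#'
#' @param path file path.
#' @param fs sampling rate in Hz (default 1017).
#' @return [read_photometry_csv()]: a [photometry_session()] tibble.
#' @export
read_photometry_csv <- function(path, fs = 1017) {
  df <- read_checked(path, c("time_s", "f465", "f405"))
  photometry_session(df$time_s, df$f465, df$f405, fs = fs)
}

#' @rdname read_photometry_csv
#' @param session a photometry session tibble.
#' @export
write_photometry_csv <- function(session, path) {
  readr::write_csv(session[, c("time_s", "f465", "f405")], path)
  invisible(path)
}

#' Read / write a 2-D tracking CSV
#'
#' Columns `time_s,x_mm,y_mm`.
#'
#' @param path file path.
#' @param fps frame rate, Hz.
#' @param arena arena name (see [arena_zones()]).
#' @return [read_tracking_csv()]: a trajectory tibble.
#' @export
read_tracking_csv <- function(path, fps = 30, arena = "epm") {
  df <- read_checked(path, c("time_s", "x_mm", "y_mm"))
  as_trajectory(df, fps = fps, arena = arena)
}

#' @rdname read_tracking_csv
#' @param traj a trajectory tibble.
#' @export
write_tracking_csv <- function(traj, path) {
  readr::write_csv(traj[, c("time_s", "x_mm", "y_mm")], path)
  invisible(path)
}

#' Read / write a sweep CSV
#'
#' Columns `time_s,value,command`; `value` is voltage (mV, current clamp) or
#' current (pA, voltage clamp) depending on `mode`.
#'
#' @param path file path.
#' @param fs sampling rate, Hz.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @return [read_sweep_csv()]: tibble with `time_s`, `v_mV`/`i_pA`,
#'   `command_pA`/`command_mV` and an `fs` attribute.
#' @export
read_sweep_csv <- function(path, fs, mode = c("current_clamp", "voltage_clamp")) {
  mode <- match.arg(mode)
  df <- read_checked(path, c("time_s", "value", "command"))
  out <- if (mode == "current_clamp") {
    tibble(time_s = df$time_s, v_mV = df$value, command_pA = df$command)
  } else {
    tibble(time_s = df$time_s, i_pA = df$value, command_mV = df$command)
  }
  attr(out, "fs") <- fs
  out
}

#' @rdname read_sweep_csv
#' @param sweep a sweep tibble (`v_mV` or `i_pA` plus a command column).
#' @export
write_sweep_csv <- function(sweep, path) {
  value <- sweep$v_mV %||% sweep$i_pA
  command <- sweep$command_pA %||% sweep$command_mV %||% rep(0, nrow(sweep))
  readr::write_csv(tibble(time_s = sweep$time_s, value = value,
                          command = command), path)
  invisible(path)
}

#' Read / write pose keypoints in the multi-row-header pose-estimation CSV
#' dialect
#'
#' The standard three-row header (scorer / bodyparts / coords) over a frame
#' index column and one x/y/likelihood triple per body part.
#'
#' @param path file path.
#' @param fps frame rate, Hz, used to convert frame index to `time_s`.
#' @return [read_pose_csv()]: tibble with `time_s` and `<part>_x`,
#'   `<part>_y`, `<part>_likelihood` columns; attribute `fs`.
#' @export
read_pose_csv <- function(path, fps) {
  check_positive(fps, "fps")
  hdr <- readr::read_lines(path, n_max = 3)
  if (length(hdr) < 3 || !startsWith(hdr[2], "bodyparts") ||
      !startsWith(hdr[3], "coords")) {
    abort("Not a multi-row-header pose CSV (expected scorer/bodyparts/coords rows).")
  }
  parts <- strsplit(hdr[2], ",")[[1]][-1]
  coords <- strsplit(hdr[3], ",")[[1]][-1]
  body <- readr::read_csv(path, skip = 3,
                          col_names = c("frame", paste0(parts, "_", coords)),
                          show_col_types = FALSE)
  dplyr::mutate(body, time_s = .data$frame / fps, .before = 1) |>
    dplyr::select(-"frame") -> out
  attr(out, "fs") <- fps
  out
}

#' @rdname read_pose_csv
#' @param keypoints wide keypoint tibble (`<part>_x`/`_y` and optional
#'   `_likelihood` columns plus `time_s`).
#' @param scorer scorer label written in the first header row.
#' @export
write_pose_csv <- function(keypoints, path, fps = NULL, scorer = "stresskit") {
  fps <- fps %||% sampling_rate(keypoints)
  parts <- unique(sub("_(x|y|likelihood)$", "",
                      grep("_(x|y|likelihood)$", names(keypoints), value = TRUE)))
  for (p in parts) {
    lk <- paste0(p, "_likelihood")
    if (!lk %in% names(keypoints)) keypoints[[lk]] <- 1
  }
  cols <- as.vector(t(outer(parts, c("_x", "_y", "_likelihood"), paste0)))
  lines <- c(
    paste(c("scorer", rep(scorer, length(cols))), collapse = ","),
    paste(c("bodyparts", rep(parts, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))), collapse = ","))
  body <- cbind(frame = round(keypoints$time_s * fps),
                as.data.frame(keypoints[, cols]))
  readr::write_lines(lines, path)
  readr::write_csv(body, path, append = TRUE)
  invisible(path)
}

#' Read / write arena zone polygons as JSON
#'
#' @param path file path.
#' @return [read_zones_json()]: named list of polygon matrices (mm).
#' @export
read_zones_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  zones <- purrr::map(raw$zones, ~ as.matrix(.x))
  attr(zones, "arena") <- raw$arena %||% "custom"
  zones
}

#' @rdname read_zones_json
#' @param zones named list of polygon matrices (see [arena_zones()]).
#' @export
write_zones_json <- function(zones, path) {
  jsonlite::write_json(
    list(arena = attr(zones, "arena") %||% "custom",
         zones = purrr::map(zones, ~ unname(as.matrix(.x)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a behavioral event table as CSV
#'
#' Columns `kind,onset_s,offset_s,peak_speed`.
#'
#' @param events events tibble.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(events[, c("kind", "onset_s", "offset_s", "peak_speed")], path)
  invisible(path)
}

## read a CSV and check the schema, reporting problem rows with line numbers
read_checked <- function(path, need) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[, need]))
  if (length(bad)) {
    abort(sprintf("%s: malformed/missing values on data line(s): %s", path,
                  paste(head(bad + 1L, 5), collapse = ", ")))
  }
  df
}
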