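## Pupillometry from pose keypoints: normalized pupil and eye size around a
## light-stimulation schedule (10 s pre / 10 s light / 10 s post by default),
## sampled at the conventional 5 / 15 / 25 s statistical timepoints.

#' Pupil and eye size timecourse from keypoints
#'
#' Pupil size is measured two ways per frame: diameter = mean pairwise
#' distance of opposing pupil-boundary points, and area = ellipse area from
#' the two opposing-pair diameters. Eye size is the eyelid top-bottom
#' distance. All series are normalized to their pre-period mean. Keypoints
#' whose likelihood falls below `likelihood_min` are linearly interpolated
#' when the gap is at most `max_gap_s`; longer gaps are an error.
#'
#' @param keypoints tibble with `time_s` and, per tracked point `p`, columns
#'   `p_x`, `p_y`, `p_likelihood`. Pupil points: `pupil_left`, `pupil_right`,
#'   `pupil_top`, `pupil_bottom`; eyelid points: `eyelid_top`,
#'   `eyelid_bottom`.
#' @param light_on_s,light_off_s light window bounds, seconds (default 10-20).
#' @param sample_at_s timepoints at which normalized values are reported
#'   (default `c(pre = 5, light = 15, post = 25)`).
#' @param likelihood_min keypoint confidence threshold (default 0.9).
#' @param max_gap_s maximum interpolatable low-confidence gap (default 0.5).
#' @return list with `timecourse` tibble (`time_s`, `pupil_diameter`,
#'   `pupil_area`, `eye_size`, each normalized to the pre-period mean) and
#'   `samples` tibble (`phase`, `time_s`, `pupil_diameter`, `pupil_area`,
#'   `eye_size`).
#' @export
pupil_timecourse <- function(keypoints, light_on_s = 10, light_off_s = 20,
                             sample_at_s = c(pre = 5, light = 15, post = 25),
                             likelihood_min = 0.9, max_gap_s = 0.5) {
  pts <- c("pupil_left", "pupil_right", "pupil_top", "pupil_bottom",
           "eyelid_top", "eyelid_bottom")
  need <- c("time_s", paste0(rep(pts, each = 2), c("_x", "_y")))
  miss <- setdiff(need, names(keypoints))
  if (length(miss)) abort(sprintf("Missing keypoint column(s): %s",
                                  paste(miss, collapse = ", ")))
  t <- keypoints$time_s
  get <- function(col) {
    v <- keypoints[[col]]
    lk_col <- sub("_(x|y)$", "_likelihood", col)
    lk <- keypoints[[lk_col]]
    if (!is.null(lk)) {
      bad <- lk < likelihood_min
      if (any(bad)) {
        runs <- find_runs(bad, t)
        too_long <- runs$offset_s - runs$onset_s > max_gap_s
        if (any(too_long)) {
          abort(sprintf(
            "Low-likelihood gap of %.2f s starting at %.2f s exceeds max_gap_s = %g.",
            max(runs$offset_s - runs$onset_s), runs$onset_s[which(too_long)[1]],
            max_gap_s))
        }
        v[bad] <- approx(t[!bad], v[!bad], xout = t[bad], rule = 2)$y
      }
    }
    v
  }
  d <- function(p, q) {
    sqrt((get(paste0(p, "_x")) - get(paste0(q, "_x")))^2 +
         (get(paste0(p, "_y")) - get(paste0(q, "_y")))^2)
  }
  d_h <- d("pupil_left", "pupil_right")
  d_v <- d("pupil_top", "pupil_bottom")
  diameter <- (d_h + d_v) / 2
  area <- pi * (d_h / 2) * (d_v / 2)
  eye <- d("eyelid_top", "eyelid_bottom")

  pre <- t < light_on_s
  if (!any(pre)) abort("No frames before `light_on_s`; cannot normalize to pre period.")
  norm <- function(x) x / mean(x[pre])
  tc <- tibble(time_s = t, pupil_diameter = norm(diameter),
               pupil_area = norm(area), eye_size = norm(eye))
  samples <- purrr::imap_dfr(as.list(sample_at_s), function(ts, phase) {
    i <- which.min(abs(t - ts))
    tibble(phase = phase, time_s = t[i], pupil_diameter = tc$pupil_diameter[i],
           pupil_area = tc$pupil_area[i], eye_size = tc$eye_size[i])
  })
  list(timecourse = tc, samples = samples)
}
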