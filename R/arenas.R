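## Arena zone geometry. Coordinates are millimetres with the origin at the
## arena center, x rightward, y upward. Each zone is a closed polygon stored
## as a two-column matrix (mm); zones share boundaries but do not overlap.

rect_poly <- function(x0, x1, y0, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Standard arena zone geometries
#'
#' Builds named zone polygons for the supported apparatus types, using the
#' standard bench dimensions: an elevated plus maze with two open and two
#' closed arms of 250 x 50 mm around a 50 x 50 mm center; a 500 x 400 mm
#' open-field box (center zone = central half of each side); and two- or
#' three-chamber boxes partitioning the same 500 x 400 mm floor.
#'
#' @param arena one of `"epm"`, `"open_field"`, `"two_chamber"`,
#'   `"three_chamber"`.
#' @return named list of polygon matrices (mm), with attribute `arena`.
#' @export
arena_zones <- function(arena = c("epm", "open_field", "two_chamber",
                                  "three_chamber")) {
  arena <- match.arg(arena)
  z <- switch(arena,
    epm = list(
      center      = rect_poly(-25, 25, -25, 25),
      open_arm_1  = rect_poly(25, 275, -25, 25),    # +x
      open_arm_2  = rect_poly(-275, -25, -25, 25),  # -x
      closed_arm_1 = rect_poly(-25, 25, -275, -25), # -y
      closed_arm_2 = rect_poly(-25, 25, 25, 275)    # +y
    ),
    open_field = list(
      center    = rect_poly(-125, 125, -100, 100),
      periphery = rect_poly(-250, 250, -200, 200)   # checked after center
    ),
    two_chamber = list(
      chamber_left  = rect_poly(-250, 0, -200, 200),
      chamber_right = rect_poly(0, 250, -200, 200)
    ),
    three_chamber = list(
      chamber_left   = rect_poly(-250, -250 / 3, -200, 200),
      chamber_center = rect_poly(-250 / 3, 250 / 3, -200, 200),
      chamber_right  = rect_poly(250 / 3, 250, -200, 200)
    ))
  attr(z, "arena") <- arena
  z
}

#' Assign each point to a named zone
#'
#' Point-in-polygon tests are delegated to `mgcv::in.out`; zones are tried in
#' list order, so an enclosing zone listed later (e.g. open-field periphery)
#' catches points missed by earlier zones. Points outside every zone are
#' assigned to the nearest zone and counted.
#'
#' @param x,y coordinates in mm.
#' @param zones named list of polygons from [arena_zones()].
#' @return list with `zone` (character vector) and `n_outside`.
#' @export
assign_zones <- function(x, y, zones) {
  pts <- cbind(x, y)
  zone <- rep(NA_character_, nrow(pts))
  for (nm in names(zones)) {
    p <- zones[[nm]]
    todo <- is.na(zone)
    if (!any(todo)) break
    ## in.out treats boundary inconsistently; nudge test includes boundary via
    ## a tiny outward tolerance on the polygon
    inside <- mgcv::in.out(rbind(p, p[1, , drop = FALSE]),
                           pts[todo, , drop = FALSE])
    zone[which(todo)[inside]] <- nm
  }
  n_out <- sum(is.na(zone))
  if (n_out > 0) {
    centers <- t(vapply(zones, colMeans, numeric(2)))
    for (i in which(is.na(zone))) {
      d <- sqrt((centers[, 1] - pts[i, 1])^2 + (centers[, 2] - pts[i, 2])^2)
      zone[i] <- names(zones)[which.min(d)]
    }
  }
  list(zone = zone, n_outside = n_out)
}
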