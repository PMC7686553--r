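## Trajectory container and synthetic trajectory generation (scripted
## waypoints or random walk) in open-field, cylinder and Y-maze arenas.

#' Y-maze geometry
#'
#' Three arms radiating from a common centre. Defaults match a conventional
#' custom-built maze: arm length 30 cm, arm width 7 cm, equal 120 degree
#' angles.
#'
#' @param arm_length arm length, cm
#' @param arm_width arm width, cm
#' @param angles_deg arm axis angles (degrees, counter-clockwise from +x)
#' @param arm_names labels of the arms
#' @return list of class `ymaze_geometry`
#' @export
ymaze_geometry <- function(arm_length = 30, arm_width = 7,
                           angles_deg = c(90, 210, 330),
                           arm_names = c("A", "B", "C")) {
  stopifnot(length(angles_deg) == length(arm_names), arm_length > 0,
            arm_width > 0)
  structure(list(kind = "ymaze", arm_length = arm_length,
                 arm_width = arm_width,
                 angles = angles_deg * pi / 180, arm_names = arm_names),
            class = "ymaze_geometry")
}

#' Circular arena geometry (open field or cylinder)
#' @param kind `"open_field"` or `"cylinder"`
#' @param radius arena radius, cm
#' @export
circle_geometry <- function(kind = c("open_field", "cylinder"), radius = 20) {
  kind <- match.arg(kind)
  stopifnot(radius > 0)
  structure(list(kind = kind, radius = radius), class = "circle_geometry")
}

## is each (x, y) inside the arena (+ tolerance)?
point_in_arena <- function(x, y, geometry, tol = 1e-6) {
  if (inherits(geometry, "circle_geometry"))
    return(sqrt(x^2 + y^2) <= geometry$radius + tol)
  if (inherits(geometry, "ymaze_geometry")) {
    ok <- rep(FALSE, length(x))
    for (a in geometry$angles) {
      proj <- x * cos(a) + y * sin(a)
      perp <- -x * sin(a) + y * cos(a)
      ok <- ok | (proj >= -tol & proj <= geometry$arm_length + tol &
                    abs(perp) <= geometry$arm_width / 2 + tol)
    }
    return(ok)
  }
  stop("unknown arena geometry")
}

#' Construct a trajectory object
#'
#' @param t timestamps, seconds (strictly increasing)
#' @param x,y coordinates of the central body point, cm
#' @param geometry arena geometry ([circle_geometry()] or [ymaze_geometry()])
#' @param frame_rate sampling rate, Hz
#' @return data frame of class `trajectory` with columns `t`, `x`, `y`
#' @export
trajectory <- function(t, x, y, geometry, frame_rate = 25) {
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  if (!all(point_in_arena(x, y, geometry, tol = 1e-6)))
    stop("trajectory leaves the arena")
  structure(data.frame(t = t, x = x, y = y),
            class = c("trajectory", "data.frame"),
            geometry = geometry, frame_rate = frame_rate)
}

#' Generate a scripted or random-walk trajectory
#'
#' In scripted mode the path visits `waypoints` in order at constant `speed`;
#' the sampled trajectory passes through every waypoint exactly (waypoint
#' arrival times are included in the sample grid). In random mode a
#' persistent-heading random walk is reflected inside the arena.
#'
#' @param kind arena kind: `"open_field"`, `"cylinder"` or `"ymaze"`
#' @param waypoints optional data frame with columns `x`, `y` (cm); supplying
#'   it selects scripted mode
#' @param speed locomotion speed, cm/s
#' @param duration random-walk duration, s
#' @param frame_rate sampling rate, Hz
#' @param turn_sd per-step heading change sd (radians) of the random walk
#' @param seed integer seed (random mode)
#' @param geometry optional arena geometry; a default is built from `kind`
#' @return a [trajectory()] object
#' @export
generate_trajectory <- function(kind = c("open_field", "cylinder", "ymaze"),
                                waypoints = NULL, speed = 5, duration = 600,
                                frame_rate = 25, turn_sd = 0.4, seed = 1L,
                                geometry = NULL) {
  kind <- match.arg(kind)
  if (is.null(geometry))
    geometry <- switch(kind,
                       open_field = circle_geometry("open_field", 20),
                       cylinder = circle_geometry("cylinder", 5),
                       ymaze = ymaze_geometry())
  if (!is.null(waypoints)) {
    if (nrow(waypoints) < 2L) stop("scripted mode needs >= 2 waypoints")
    if (!all(point_in_arena(waypoints$x, waypoints$y, geometry)))
      stop("waypoint outside arena")
    seg <- sqrt(diff(waypoints$x)^2 + diff(waypoints$y)^2)
    t_wp <- c(0, cumsum(seg / speed))
    keep <- c(TRUE, seg > 0)            # drop zero-length legs
    t_wp <- t_wp[keep]
    wx <- waypoints$x[keep]; wy <- waypoints$y[keep]
    ts <- sort(unique(c(seq(0, max(t_wp), by = 1 / frame_rate), t_wp)))
    x <- stats::approx(t_wp, wx, xout = ts)$y
    y <- stats::approx(t_wp, wy, xout = ts)$y
    return(trajectory(ts, x, y, geometry, frame_rate))
  }
  ## random walk
  with_seed(seed, {
    n <- max(2L, round(duration * frame_rate) + 1L)
    ts <- (seq_len(n) - 1L) / frame_rate
    x <- numeric(n); y <- numeric(n)
    if (inherits(geometry, "ymaze_geometry")) { x[1L] <- 0; y[1L] <- 0 }
    heading <- stats::runif(1, 0, 2 * pi)
    step <- speed / frame_rate
    for (i in 2L:n) {
      placed <- FALSE
      for (try in 1:25) {
        heading <- heading + stats::rnorm(1, 0, turn_sd)
        nx <- x[i - 1L] + step * cos(heading)
        ny <- y[i - 1L] + step * sin(heading)
        if (point_in_arena(nx, ny, geometry)) { placed <- TRUE; break }
        heading <- stats::runif(1, 0, 2 * pi)
      }
      if (!placed) { nx <- x[i - 1L]; ny <- y[i - 1L] }
      x[i] <- nx; y[i] <- ny
    }
    trajectory(ts, x, y, geometry, frame_rate)
  })
}

#' Build waypoints for a scripted sequence of Y-maze arm visits
#'
#' Each visit goes centre -> arm (to the stated penetration depth) -> centre,
#' which is the pattern the arm-entry extractor expects.
#'
#' @param geometry a [ymaze_geometry()]
#' @param visits character vector of arm names to visit, in order
#' @param depths penetration depth of each visit as a fraction of arm length
#' @return data frame of waypoints usable with [generate_trajectory()]
#' @export
ymaze_visit_waypoints <- function(geometry, visits, depths = NULL) {
  if (is.null(depths)) depths <- rep(0.9, length(visits))
  stopifnot(length(depths) == length(visits),
            all(visits %in% geometry$arm_names))
  wp <- data.frame(x = 0, y = 0)
  for (i in seq_along(visits)) {
    a <- geometry$angles[match(visits[i], geometry$arm_names)]
    r <- depths[i] * geometry$arm_length
    wp <- rbind(wp, data.frame(x = r * cos(a), y = r * sin(a)),
                data.frame(x = 0, y = 0))
  }
  wp
}

#' Write a trajectory as CSV with a provenance header
#' @param traj a [trajectory()] object
#' @param path output path
#' @export
write_trajectory <- function(traj, path) {
  g <- attr(traj, "geometry")
  write_table_with_provenance(
    as.data.frame(traj), path,
    provenance = list(units = "t:s, x:cm, y:cm",
                      frame_rate_hz = attr(traj, "frame_rate"),
                      arena = g$kind))
}
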