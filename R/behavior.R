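## Trajectory-derived behavioural metrics: binned distance, epoch velocity,
## rotation counting, Y-maze arm-entry extraction and spontaneous
## alternation scoring.

#' Distance moved per time bin
#'
#' Sums Euclidean step lengths inside consecutive bins of `bin_s` seconds
#' (default 600 s = 10 min). A step from `t[i]` to `t[i+1]` is attributed to
#' the bin containing `t[i]`, which makes distances exactly additive across
#' bin boundaries aligned with sample times.
#'
#' @param traj a [trajectory()]
#' @param bin_s bin width, seconds
#' @return data frame `bin_start_s`, `bin_end_s`, `distance_cm`, `partial`
#'   (TRUE when the recording ends inside the bin)
#' @export
binned_distance <- function(traj, bin_s = 600) {
  n <- nrow(traj)
  if (n < 2L) {
    warning("single-sample trajectory: zero distance")
    return(data.frame(bin_start_s = 0, bin_end_s = bin_s, distance_cm = 0,
                      partial = TRUE))
  }
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  bin <- floor(traj$t[-n] / bin_s)
  bins <- 0:max(bin)
  dist <- vapply(bins, function(b) sum(step[bin == b]), numeric(1))
  data.frame(bin_start_s = bins * bin_s, bin_end_s = (bins + 1) * bin_s,
             distance_cm = dist,
             partial = (bins + 1) * bin_s > max(traj$t) + 1e-9)
}

#' Mean velocity per epoch
#'
#' @param traj a [trajectory()]
#' @param epochs data frame with columns `start_s`, `end_s`
#' @return data frame with `start_s`, `end_s`, `distance_cm`,
#'   `velocity_cm_s`
#' @export
epoch_velocity <- function(traj, epochs) {
  n <- nrow(traj)
  if (n < 2L) stop("need >= 2 samples")
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  t0 <- traj$t[-n]
  out <- epochs
  out$distance_cm <- vapply(seq_len(nrow(epochs)), function(i)
    sum(step[t0 >= epochs$start_s[i] & t0 < epochs$end_s[i]]), numeric(1))
  out$velocity_cm_s <- out$distance_cm / (epochs$end_s - epochs$start_s)
  out
}

#' Count full-circle rotations in a trajectory
#'
#' One rotation is counted per accumulated 360 degrees of unwrapped heading
#' change in a consistent direction; a heading reversal of more than 90
#' degrees against the accumulated direction resets the accumulator.
#' Rotations are counted unsigned (a clockwise and a counter-clockwise loop
#' are two rotations). Displacements below `noise_floor_cm` are skipped when
#' computing headings, and a candidate rotation only counts when the path
#' points it covers span a radius of at least `min_radius_cm` around their
#' centroid.
#'
#' @param traj a [trajectory()]
#' @param min_radius_cm minimal spatial extent of a counted rotation
#' @param noise_floor_cm displacement threshold for heading estimation
#'   (default 0.5 cm)
#' @return integer rotation count
#' @export
count_rotations <- function(traj, min_radius_cm = 2, noise_floor_cm = 0.5) {
  ## resample the path at anchors at least noise_floor apart, so jitter and
  ## finely sampled smooth motion both yield stable headings
  n <- nrow(traj)
  if (n < 3L) return(0L)
  anchor <- 1L
  last <- 1L
  for (i in 2L:n) {
    if (sqrt((traj$x[i] - traj$x[last])^2 +
               (traj$y[i] - traj$y[last])^2) >= noise_floor_cm) {
      anchor <- c(anchor, i)
      last <- i
    }
  }
  if (length(anchor) < 4L) return(0L)
  pts_x <- traj$x[anchor]; pts_y <- traj$y[anchor]
  heads <- atan2(diff(pts_y), diff(pts_x))
  pts_x <- pts_x[-1L]; pts_y <- pts_y[-1L]
  dh <- diff(heads)
  dh <- ((dh + pi) %% (2 * pi)) - pi   # wrap to (-pi, pi]
  ## a sampled open loop accumulates 2*pi minus up to a few heading steps;
  ## allow that discretisation shortfall when closing a rotation
  full_turn <- 2 * pi - min(0.35, 3 * stats::median(abs(dh)))
  count <- 0L
  acc <- 0
  start <- 1L
  spans_radius <- function(i0, i1) {
    xs <- pts_x[i0:i1]; ys <- pts_y[i0:i1]
    max(sqrt((xs - mean(xs))^2 + (ys - mean(ys))^2)) >= min_radius_cm
  }
  for (i in seq_along(dh)) {
    if (acc != 0 && sign(dh[i]) != 0 && sign(dh[i]) != sign(acc) &&
        abs(dh[i]) > pi / 2) {
      acc <- 0; start <- i
    }
    acc <- acc + dh[i]
    if (abs(acc) >= full_turn) {
      if (spans_radius(start, i + 1L)) count <- count + 1L
      acc <- acc - sign(acc) * 2 * pi
      start <- i
    }
  }
  count
}

#' Extract the arm-entry sequence from a Y-maze trajectory
#'
#' An arm visit is a maximal run of samples inside one arm beyond the centre
#' region (points within one arm-width of the origin are centre). The visit
#' registers as an entry when the central body point penetrates at least
#' `depth_rule` of the arm length; shallower excursions are ignored.
#' Repeated passages from the centre back into the same arm collapse into a
#' single arm exploration.
#'
#' @param traj a [trajectory()] recorded in a [ymaze_geometry()] arena
#' @param geometry the maze geometry (defaults to the trajectory's arena)
#' @param depth_rule entry threshold as a fraction of arm length
#'   (default 0.2)
#' @return data frame of class `arm_entry_sequence` with columns `arm`,
#'   `t_entry`, `depth` (max penetration, fraction of arm length)
#' @export
extract_arm_entries <- function(traj, geometry = NULL, depth_rule = 0.2) {
  if (is.null(geometry)) geometry <- attr(traj, "geometry")
  if (!inherits(geometry, "ymaze_geometry"))
    stop("extract_arm_entries needs a Y-maze geometry")
  n <- nrow(traj)
  proj <- sapply(geometry$angles, function(a)
    traj$x * cos(a) + traj$y * sin(a))
  perp <- sapply(geometry$angles, function(a)
    -traj$x * sin(a) + traj$y * cos(a))
  in_arm <- proj >= 0 & proj <= geometry$arm_length &
    abs(perp) <= geometry$arm_width / 2
  ## assign each sample to the arm with the deepest valid projection;
  ## samples within one arm width of the origin are the centre region
  arm_idx <- apply(ifelse(in_arm, proj, -Inf), 1L, which.max)
  depth <- proj[cbind(seq_len(n), arm_idx)] / geometry$arm_length
  centre <- sqrt(traj$x^2 + traj$y^2) <= geometry$arm_width
  state <- ifelse(centre | !in_arm[cbind(seq_len(n), arm_idx)], 0L, arm_idx)
  ## maximal runs of a nonzero state are candidate visits
  entries <- NULL
  i <- 1L
  while (i <= n) {
    if (state[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] == state[i]) j <- j + 1L
    dmax <- max(depth[i:j])
    if (dmax >= depth_rule)
      entries <- rbind(entries,
                       data.frame(arm = geometry$arm_names[state[i]],
                                  t_entry = traj$t[i], depth = dmax,
                                  stringsAsFactors = FALSE))
    i <- j + 1L
  }
  if (is.null(entries))
    entries <- data.frame(arm = character(0), t_entry = numeric(0),
                          depth = numeric(0), stringsAsFactors = FALSE)
  ## consecutive same-arm entries are a single arm exploration
  if (nrow(entries) > 1L) {
    keep <- c(TRUE, entries$arm[-1L] != entries$arm[-nrow(entries)])
    entries <- entries[keep, , drop = FALSE]
    rownames(entries) <- NULL
  }
  class(entries) <- c("arm_entry_sequence", class(entries))
  entries
}

#' Score spontaneous alternations from an arm-entry sequence
#'
#' Total alternations are the arm changes in the collapsed entry sequence.
#' A successful alternation is a sliding window of three consecutive entries
#' visiting three distinct arms; the alternation percentage is successful
#' windows over (entries - 2) x 100. Animals below `min_alternations`
#' changes are flagged for exclusion.
#'
#' @param entries an `arm_entry_sequence` (or character vector of arms)
#' @param min_alternations exclusion threshold on total alternations
#'   (default 20)
#' @return list with `total_alternations`, `successful_alternations`,
#'   `alternation_pct` (NA when fewer than 3 entries) and `excluded`
#' @export
score_alternations <- function(entries, min_alternations = 20) {
  arms <- if (is.data.frame(entries)) entries$arm else as.character(entries)
  n <- length(arms)
  total <- max(0L, n - 1L)
  if (n >= 3L) {
    wins <- vapply(seq_len(n - 2L), function(i)
      length(unique(arms[i:(i + 2L)])) == 3L, logical(1))
    successful <- sum(wins)
    pct <- 100 * successful / (n - 2L)
  } else {
    successful <- 0L
    pct <- NA_real_
  }
  list(total_alternations = total,
       successful_alternations = as.integer(successful),
       alternation_pct = pct,
       excluded = total < min_alternations)
}

#' One-row behavioural summary of a trajectory
#'
#' Convenience wrapper producing the per-animal metric row (total distance,
#' mean velocity, rotations, and alternation scores for Y-maze recordings).
#'
#' @param traj a [trajectory()]
#' @param bin_s distance bin width, s
#' @return one-row data frame
#' @export
behavior_summary <- function(traj, bin_s = 600) {
  bd <- binned_distance(traj, bin_s)
  total <- sum(bd$distance_cm)
  dur <- max(traj$t) - min(traj$t)
  out <- data.frame(total_distance_cm = total,
                    mean_velocity_cm_s = if (dur > 0) total / dur else 0,
                    rotations = count_rotations(traj))
  g <- attr(traj, "geometry")
  if (inherits(g, "ymaze_geometry")) {
    sc <- score_alternations(extract_arm_entries(traj, g))
    out$total_alternations <- sc$total_alternations
    out$successful_alternations <- sc$successful_alternations
    out$alternation_pct <- sc$alternation_pct
    out$excluded <- sc$excluded
  }
  out
}
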