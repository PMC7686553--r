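## Soma-centered 2D Sholl analysis of the non-isolated microglial skeleton:
## supercover pixel rings, crossing counts as 8-connected clusters of
## skeleton pixels on the ring, identity (y = x) baseline, and zone
## statistics for the single-cell (0-20 um) vs inter-cellular (20-40 um)
## territories.

## ring-pixel and ring-adjacency cache, keyed by integer pixel radius
.ring_cache <- new.env(parent = emptyenv())

#' Pixel ring of an integer-radius rasterized circle (supercover)
#'
#' Returns the offsets (dx, dy) of the rasterized circle of radius `r_px`
#' around a centre pixel, ordered by angle: every pixel whose closed unit
#' square is touched by the continuous circle of radius `r_px` (the
#' supercover circle). This choice guarantees that any 8-connected branch
#' running from inside the circle to outside shares at least one pixel with
#' the ring, so no crossing can slip between diagonal ring pixels. Radius 0
#' is the centre pixel itself.
#'
#' @param r_px integer radius in pixels
#' @return integer matrix with columns `dx`, `dy`
#' @export
circle_ring <- function(r_px) {
  r_px <- as.integer(r_px)
  if (r_px < 0L) stop("radius must be >= 0")
  if (r_px == 0L) return(cbind(dx = 0L, dy = 0L))
  key <- as.character(r_px)
  hit <- get0(key, envir = .ring_cache)
  if (!is.null(hit)) return(hit$ring)
  g <- seq(-r_px - 1L, r_px + 1L)
  axg <- abs(g)
  ## nearest / farthest distance from the origin to each pixel's unit square
  dmin <- sqrt(outer(pmax(axg - 0.5, 0)^2, pmax(axg - 0.5, 0)^2, "+"))
  dmax <- sqrt(outer((axg + 0.5)^2, (axg + 0.5)^2, "+"))
  sel <- which(dmin <= r_px & r_px <= dmax, arr.ind = TRUE)
  pts <- cbind(g[sel[, 1L]], g[sel[, 2L]])
  ang <- atan2(pts[, 2L], pts[, 1L])
  ring <- pts[order(ang), , drop = FALSE]
  colnames(ring) <- c("dx", "dy")
  ## 8-adjacency edges among ring pixels (precomputed once per radius)
  n <- nrow(ring)
  dmat_x <- abs(outer(ring[, 1L], ring[, 1L], "-"))
  dmat_y <- abs(outer(ring[, 2L], ring[, 2L], "-"))
  adj <- which(dmat_x <= 1L & dmat_y <= 1L &
                 upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  assign(key, list(ring = ring, edges = adj), envir = .ring_cache)
  ring
}

ring_edges <- function(r_px) {
  circle_ring(r_px)  # ensure cached
  get(as.character(as.integer(r_px)), envir = .ring_cache)$edges
}

#' Soma-centered 2D Sholl analysis of a skeleton
#'
#' For each radius on the grid `seq(dr, r_max, dr)` the number of crossings
#' is counted as the number of 8-connected clusters of skeleton pixels lying
#' on the rasterized circle of that radius around the centre (see
#' [circle_ring()] for the ring definition).
#' Applied to a non-isolated skeleton network the profile grows roughly
#' linearly with radius as further cells' branches enter larger circles;
#' see [identity_baseline()] for the y = x adjusted view.
#'
#' Radii whose circle leaves the image are computed on the in-bounds arc and
#' flagged in the `partial` column.
#'
#' @param skeleton logical matrix from [skeletonize()] (any binary matrix
#'   works)
#' @param center centre in micrometres, length 2 (pixel-centre convention)
#' @param r_max maximum radius, um (default 40)
#' @param dr radius step, um (default 1)
#' @param voxel_size in-plane pixel size, um (scalar; in-plane isotropy is
#'   assumed)
#' @return data frame of class `sholl_profile` with columns `radius_um`,
#'   `crossings`, `partial`; attributes `center`, `dr`, `sholl_dim` (= "2D")
#' @export
sholl_2d <- function(skeleton, center, r_max = 40, dr = 1, voxel_size = 0.5) {
  if (length(dim(skeleton)) != 2L) stop("skeleton must be a 2D matrix")
  if (!(r_max >= dr && dr > 0)) stop("need r_max >= dr > 0")
  d <- dim(skeleton)
  cpx <- floor(center[1L] / voxel_size) + 1L
  cpy <- floor(center[2L] / voxel_size) + 1L
  if (cpx < 1L || cpx > d[1L] || cpy < 1L || cpy > d[2L])
    stop("center outside image")
  radii <- seq(dr, r_max, by = dr)
  crossings <- integer(length(radii))
  partial <- logical(length(radii))
  for (i in seq_along(radii)) {
    r_px <- max(1L, as.integer(round(radii[i] / voxel_size)))
    ring <- circle_ring(r_px)
    px <- cpx + ring[, 1L]; py <- cpy + ring[, 2L]
    inb <- px >= 1L & px <= d[1L] & py >= 1L & py <= d[2L]
    partial[i] <- !all(inb)
    if (!any(inb)) next
    fg_ring <- rep(FALSE, nrow(ring))
    fg_ring[inb] <- skeleton[cbind(px[inb], py[inb])]
    nf <- sum(fg_ring)
    if (nf == 0L) next
    ed <- ring_edges(r_px)
    keep <- fg_ring[ed[, 1L]] & fg_ring[ed[, 2L]]
    map <- integer(nrow(ring)); map[fg_ring] <- seq_len(nf)
    crossings[i] <- uf_count(nf, cbind(map[ed[keep, 1L]],
                                       map[ed[keep, 2L]]))
  }
  out <- data.frame(radius_um = radii, crossings = crossings,
                    partial = partial)
  attr(out, "center") <- center
  attr(out, "dr") <- dr
  attr(out, "sholl_dim") <- "2D"
  attr(out, "voxel_size") <- voxel_size
  class(out) <- c("sholl_profile", class(out))
  out
}

#' Identity-baseline adjustment of a Sholl profile
#'
#' Adds `baseline_adjusted = crossings - radius_um`: the deviation of the
#' network profile from the identity function y = x, which is the natural
#' baseline of a non-isolated skeleton whose crossing count grows linearly
#' with the radius. A pure transformation; `crossings` is untouched.
#'
#' @param profile a `sholl_profile` from [sholl_2d()]
#' @return the profile with a `baseline_adjusted` column
#' @export
identity_baseline <- function(profile) {
  if (!identical(attr(profile, "sholl_dim"), "2D"))
    stop("identity baseline applies to 2D profiles")
  profile$baseline_adjusted <- profile$crossings - profile$radius_um
  profile
}

#' Zone means of a Sholl profile
#'
#' @param profile a `sholl_profile`
#' @param zones 2-column matrix of half-open `[lo, hi)` zone bounds in um;
#'   default `(0, 20)` and `(20, 40)`
#' @return numeric vector of per-zone mean crossings
#' @export
sholl_zone_means <- function(profile, zones = default_sholl_zones()) {
  apply(zones, 1L, function(z) {
    sel <- profile$radius_um >= z[1L] & profile$radius_um < z[2L]
    if (!any(sel)) return(NA_real_)
    mean(profile$crossings[sel])
  })
}

#' Default Sholl zones: single-cell (0-20 um) and inter-cellular (20-40 um)
#' @export
default_sholl_zones <- function() {
  z <- rbind(c(0, 20), c(20, 40))
  rownames(z) <- c("single_cell", "intercellular")
  z
}

#' Zone statistics and two-group rank tests for grouped Sholl profiles
#'
#' Computes per-centre mean crossings inside each zone and compares the two
#' groups zone-wise with a two-sided Mann-Whitney U test (exact when both
#' groups have at most 8 centres and the data are tie-free, otherwise the
#' tie-corrected normal approximation).
#'
#' @param profiles list of `sholl_profile` objects (one per centre)
#' @param groups factor/character of group labels, one per profile (exactly
#'   two levels)
#' @param zones zone bounds matrix as in [sholl_zone_means()]
#' @return list with `summary` (data frame group x zone: n, mean, sem) and
#'   `tests` (data frame zone, U, p_value, method)
#' @export
zone_statistics <- function(profiles, groups, zones = default_sholl_zones()) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("zone_statistics compares exactly 2 groups")
  if (length(profiles) != length(groups))
    stop("one group label per profile required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 centers")
  zm <- t(vapply(profiles, sholl_zone_means, numeric(nrow(zones)),
                 zones = zones))
  zone_names <- rownames(zones)
  if (is.null(zone_names)) zone_names <- paste0("zone", seq_len(nrow(zones)))
  colnames(zm) <- zone_names
  sem <- function(v) sd(v) / sqrt(length(v))
  summ <- do.call(rbind, lapply(zone_names, function(zn) {
    data.frame(zone = zn, group = levels(groups),
               n = as.integer(table(groups)),
               mean = tapply(zm[, zn], groups, mean),
               sem = tapply(zm[, zn], groups, sem),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  tests <- do.call(rbind, lapply(zone_names, function(zn) {
    a <- zm[groups == levels(groups)[1L], zn]
    b <- zm[groups == levels(groups)[2L], zn]
    mw <- mann_whitney(a, b)
    data.frame(zone = zn, U = mw$statistic, p_value = mw$p_value,
               method = mw$method, stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(summary = summ, tests = tests, zone_means = zm)
}

#' Write per-centre Sholl profiles as CSV
#' @param profiles list of `sholl_profile`
#' @param path output path
#' @param center_ids optional ids (default sequence)
#' @export
write_sholl_profiles <- function(profiles, path, center_ids = NULL) {
  if (is.null(center_ids)) center_ids <- seq_along(profiles)
  rows <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (is.null(p$baseline_adjusted)) p <- identity_baseline(p)
    data.frame(center_id = center_ids[i], radius_um = p$radius_um,
               crossings = p$crossings, adjusted = p$baseline_adjusted)
  }))
  write_table_with_provenance(rows, path,
                              provenance = list(analysis = "sholl_2d",
                                                crossing_definition =
            "8-connected clusters of skeleton pixels on the supercover circle ring"))
}
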