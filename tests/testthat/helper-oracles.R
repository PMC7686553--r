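## Independent brute-force oracles for the Sholl machinery, written naively
## (loops and queues) so they share no code with the package implementation.

## Supercover circle ring of integer radius r, recomputed naively: scan the
## bounding box pixel by pixel and keep offsets whose closed unit square is
## touched by the continuous circle (nearest corner/edge distance <= r <=
## farthest corner distance).
oracle_ring <- function(r) {
  if (r == 0L) return(matrix(c(0L, 0L), ncol = 2))
  pts <- matrix(integer(0), ncol = 2)
  for (dx in (-r - 1L):(r + 1L)) {
    for (dy in (-r - 1L):(r + 1L)) {
      near <- sqrt(max(abs(dx) - 0.5, 0)^2 + max(abs(dy) - 0.5, 0)^2)
      far <- sqrt((abs(dx) + 0.5)^2 + (abs(dy) + 0.5)^2)
      if (near <= r && r <= far)
        pts <- rbind(pts, c(dx, dy))
    }
  }
  pts
}

## naive BFS cluster count over explicit coordinates (2 or 3 columns),
## 8-connected in 2D / 26-connected in 3D
oracle_cluster_count <- function(coords) {
  n <- nrow(coords)
  if (n == 0L) return(0L)
  seen <- rep(FALSE, n)
  adjacent <- function(i, j) {
    all(abs(coords[i, ] - coords[j, ]) <= 1L) && i != j
  }
  count <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    count <- count + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      for (j in seq_len(n)) {
        if (!seen[j] && adjacent(cur, j)) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  count
}

## brute-force 2D Sholl: circle walk with naive cluster counting
oracle_sholl_2d <- function(skel, center_um, r_max, dr, vs) {
  d <- dim(skel)
  cpx <- floor(center_um[1L] / vs) + 1L
  cpy <- floor(center_um[2L] / vs) + 1L
  radii <- seq(dr, r_max, by = dr)
  out <- integer(length(radii))
  for (i in seq_along(radii)) {
    r_px <- max(1L, as.integer(round(radii[i] / vs)))
    ring <- oracle_ring(r_px)
    keep <- matrix(integer(0), ncol = 2)
    for (k in seq_len(nrow(ring))) {
      px <- cpx + ring[k, 1L]
      py <- cpy + ring[k, 2L]
      if (px >= 1L && px <= d[1L] && py >= 1L && py <= d[2L] &&
          skel[px, py])
        keep <- rbind(keep, c(px, py))
    }
    out[i] <- oracle_cluster_count(keep)
  }
  data.frame(radius_um = radii, crossings = out)
}

## brute-force 3D shell Sholl: exhaustive shell membership + BFS flood fill
oracle_sholl_3d <- function(mask, center_um, vs, r_max, dr) {
  d <- dim(mask)
  radii <- seq(dr, r_max, by = dr)
  out <- integer(length(radii))
  fg <- which(mask > 0)
  if (length(fg)) {
    pos <- arrayInd(fg, d)
    dist <- sqrt(((pos[, 1L] - 0.5) * vs[1L] - center_um[1L])^2 +
                   ((pos[, 2L] - 0.5) * vs[2L] - center_um[2L])^2 +
                   ((pos[, 3L] - 0.5) * vs[3L] - center_um[3L])^2)
    for (i in seq_along(radii)) {
      sel <- dist >= radii[i] - dr / 2 & dist < radii[i] + dr / 2
      out[i] <- oracle_cluster_count(pos[sel, , drop = FALSE])
    }
  }
  data.frame(radius_um = radii, components = out)
}

## random sparse branchy skeleton for property tests: a few random polylines
## rasterised at 1 px, plus salt pixels
random_test_skeleton <- function(n_px = 128L, n_lines = 6L, salt = 30L) {
  m <- matrix(FALSE, n_px, n_px)
  for (l in seq_len(n_lines)) {
    x <- runif(1, 1, n_px); y <- runif(1, 1, n_px)
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, n_px / 4, n_px)
    tt <- seq(0, 1, length.out = ceiling(len * 2))
    px <- round(x + tt * len * cos(ang))
    py <- round(y + tt * len * sin(ang))
    ok <- px >= 1 & px <= n_px & py >= 1 & py <= n_px
    m[cbind(px[ok], py[ok])] <- TRUE
  }
  idx <- sample.int(n_px * n_px, salt)
  m[idx] <- TRUE
  m
}

## random blobby binary mask (for skeletonization topology tests)
random_arbor_mask <- function(n_px = 80L, n_blobs = 5L) {
  m <- matrix(FALSE, n_px, n_px)
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, 10, n_px - 10); cy <- runif(1, 10, n_px - 10)
    for (a in seq_len(3L)) {
      ang <- runif(1, 0, 2 * pi); len <- runif(1, 5, 25)
      tt <- seq(0, 1, length.out = 50)
      px <- round(cx + tt * len * cos(ang))
      py <- round(cy + tt * len * sin(ang))
      ok <- px >= 2 & px <= n_px - 1 & py >= 2 & py <= n_px - 1
      for (dx in -1:1) for (dy in -1:1)
        m[cbind(px[ok] + dx, py[ok] + dy)] <- TRUE
    }
  }
  m
}

## small test layout: a single cortical band filling the field
test_layout <- function(fx = 200, fy = 200, fz = 10) {
  cortex_layout(layer_widths = c("V" = fx), field_size = c(fx, fy, fz),
                voxel_size = c(0.5, 0.5, 1))
}
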