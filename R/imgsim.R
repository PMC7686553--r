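## Synthetic cortical field generator: layered cortex geometry, elliptical
## nuclei straddling the c-Fos++ thresholds, and a branching microglial
## network whose single-cell (0-20 um) and inter-cellular (20-40 um) zones
## are controlled independently. Every rendered object is recorded in the
## ground truth before noise is added.

#' Cortical layer layout
#'
#' Describes the layered geometry of a coronal cortical field: consecutive
#' layer bands of given widths starting at `midline_offset` micrometres from
#' the medial (pial/midline) edge of the image, which runs along the x axis.
#' Default widths follow the conventional mouse mPFC ranges (I: 120-140,
#' carried as the midpoint 130; II/III: 80; V: 320-350, midpoint 335;
#' VI: minimum 280, carried as 280).
#'
#' @param layer_widths named numeric vector of strictly positive widths (um),
#'   in medial-to-distal order
#' @param field_size numeric length 2 or 3: physical extent (um) per axis
#' @param voxel_size numeric, um per pixel per axis (default 0.5 um in-plane,
#'   1 um axial)
#' @param midline_offset distance (um) from the image edge to the start of the
#'   first layer
#' @return an object of class `cortex_layout`
#' @export
cortex_layout <- function(layer_widths = c("I" = 130, "II/III" = 80,
                                           "V" = 335, "VI" = 280),
                          field_size = c(900, 400, 10),
                          voxel_size = c(0.5, 0.5, 1),
                          midline_offset = 0) {
  if (is.null(names(layer_widths)) || any(!nzchar(names(layer_widths))))
    stop("layer_widths must be named")
  if (any(layer_widths <= 0)) stop("layer widths must be strictly positive")
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  if (length(field_size) != length(voxel_size))
    stop("field_size and voxel_size must have the same length")
  if (midline_offset < 0) stop("midline_offset must be >= 0")
  if (midline_offset + sum(layer_widths) > field_size[1L] + 1e-9)
    stop("sum of layer widths exceeds the field x-extent")
  structure(list(layer_widths = layer_widths,
                 field_size = as.numeric(field_size),
                 voxel_size = as.numeric(voxel_size),
                 midline_offset = as.numeric(midline_offset)),
            class = "cortex_layout")
}

## layer band starts/ends (um from image edge); half-open [start, end)
layer_bands <- function(layout) {
  w <- layout$layer_widths
  start <- layout$midline_offset + c(0, cumsum(w))[seq_along(w)]
  data.frame(layer = names(w), start = start, end = start + as.numeric(w),
             stringsAsFactors = FALSE)
}

## layer label of a medial-distal position (um); "beyond_VI" past the last band
layer_of <- function(x_um, layout) {
  b <- layer_bands(layout)
  lab <- rep("beyond_VI", length(x_um))
  for (k in seq_len(nrow(b)))
    lab[x_um >= b$start[k] & x_um < b$end[k]] <- b$layer[k]
  lab[x_um < b$start[1L]] <- b$layer[1L]  # pial margin folds into layer I
  lab
}

#' Simulation parameters for the cortical field generator
#'
#' Class intensity distributions are free parameters of the simulation (the
#' classification thresholds are the only fixed anchors); defaults put the
#' `cfos_plus` population under the intensity arm of the default thresholds
#' and the `cfos_plusplus` population above both arms, with truncation
#' margins wide enough that rendering quantisation cannot flip a label.
#'
#' @param nucleus_count named integer vector with entries `negative`,
#'   `cfos_plus`, `cfos_plusplus`
#' @param intensity_mean,intensity_sd per-class mean-gray distribution
#'   (means must be ordered negative < cfos_plus < cfos_plusplus)
#' @param area_mean,area_sd per-class projected-area distribution (um^2)
#' @param thresholds a [threshold_pair()] used to certify ground-truth labels
#' @param noise_sd additive Gaussian noise sd (intensity units), clipped at 0
#' @param soma_density microglial somata per mm^2
#' @param single_cell_radius radius (um) of the single-cell arborisation zone
#' @param intercell_branch_density dimensionless multiplier on the number of
#'   inter-cellular processes per soma
#' @param intercell_base_segments inter-cellular processes per soma at
#'   density multiplier 1
#' @param activation_attraction number of extra short branches placed within
#'   `attraction_radius` of every activated (c-Fos positive) nucleus
#' @param attraction_radius radius (um) of the preferential-branch zone
#' @param n_primary primary branches per soma
#' @param branch_step_um segment step length (um) of the branch random walk
#' @param branch_prob per-step probability of spawning a sub-branch
#' @param tortuosity_sd sd (radians) of the per-step heading change
#' @param branch_thickness_um rendered branch thickness (um)
#' @param seed integer seed; all draws of one generator call flow from it
#' @return an object of class `sim_params`
#' @export
sim_params <- function(nucleus_count = c(negative = 20, cfos_plus = 15,
                                         cfos_plusplus = 15),
                       intensity_mean = c(negative = 280, cfos_plus = 310,
                                          cfos_plusplus = 520),
                       intensity_sd = c(negative = 25, cfos_plus = 25,
                                        cfos_plusplus = 40),
                       area_mean = c(negative = 150, cfos_plus = 260,
                                     cfos_plusplus = 290),
                       area_sd = c(negative = 20, cfos_plus = 25,
                                   cfos_plusplus = 30),
                       thresholds = threshold_pair(200, 400),
                       noise_sd = 0,
                       soma_density = 0,
                       single_cell_radius = 20,
                       intercell_branch_density = 1,
                       intercell_base_segments = 12,
                       activation_attraction = 0,
                       attraction_radius = 8,
                       n_primary = 4,
                       branch_step_um = 2,
                       branch_prob = 0.12,
                       tortuosity_sd = 0.35,
                       branch_thickness_um = 1,
                       seed = 1L) {
  cls <- c("negative", "cfos_plus", "cfos_plusplus")
  for (v in list(nucleus_count, intensity_mean, intensity_sd, area_mean,
                 area_sd))
    if (!all(cls %in% names(v))) stop("per-class parameters must name all of ",
                                      paste(cls, collapse = ", "))
  if (any(nucleus_count < 0) || soma_density < 0 ||
      intercell_branch_density < 0 || activation_attraction < 0)
    stop("counts and densities must be >= 0")
  if (!(intensity_mean["negative"] < intensity_mean["cfos_plus"] &&
        intensity_mean["cfos_plus"] < intensity_mean["cfos_plusplus"]))
    stop("class intensity means must be ordered negative < cfos_plus < cfos_plusplus")
  structure(list(nucleus_count = nucleus_count[cls],
                 intensity_mean = intensity_mean[cls],
                 intensity_sd = intensity_sd[cls],
                 area_mean = area_mean[cls], area_sd = area_sd[cls],
                 thresholds = thresholds, noise_sd = noise_sd,
                 soma_density = soma_density,
                 single_cell_radius = single_cell_radius,
                 intercell_branch_density = intercell_branch_density,
                 intercell_base_segments = intercell_base_segments,
                 activation_attraction = activation_attraction,
                 attraction_radius = attraction_radius,
                 n_primary = n_primary, branch_step_um = branch_step_um,
                 branch_prob = branch_prob, tortuosity_sd = tortuosity_sd,
                 branch_thickness_um = branch_thickness_um,
                 seed = as.integer(seed)),
            class = "sim_params")
}

## truncated normal by rejection (bounds far from the mean are never used here)
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x > lower & x < upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

## paint a disc/offset brush of pixel coordinates into a slice of `arr`
paint_pixels <- function(arr, px, py, pz, value) {
  d <- dim(arr)
  ok <- px >= 1L & px <= d[1L] & py >= 1L & py <= d[2L] &
    pz >= 1L & pz <= d[3L]
  if (!any(ok)) return(arr)
  idx <- cbind(px[ok], py[ok], pz[ok])
  arr[idx] <- pmax(arr[idx], value)
  arr
}

## render one tapered ellipse; returns list(arr, n_px, mean_factor)
render_ellipse <- function(arr, cx, cy, zi, area_um2, vs, peak_level = NULL,
                           target_mean = NULL) {
  q <- stats::runif(1, 0.75, 1)                 # axis ratio
  a <- sqrt(area_um2 / (pi * q)); b <- a * q    # semi-axes, um
  th <- stats::runif(1, 0, pi)
  d <- dim(arr)
  ix <- seq(max(1L, floor((cx - a) / vs[1L])),
            min(d[1L], ceiling((cx + a) / vs[1L]) + 1L))
  iy <- seq(max(1L, floor((cy - a) / vs[2L])),
            min(d[2L], ceiling((cy + a) / vs[2L]) + 1L))
  if (!length(ix) || !length(iy))
    return(list(arr = arr, n_px = 0L, level = 0))
  gx <- (ix - 0.5) * vs[1L] - cx
  gy <- (iy - 0.5) * vs[2L] - cy
  u <- outer(gx, rep(1, length(iy))) * cos(th) +
    outer(rep(1, length(ix)), gy) * sin(th)
  v <- -outer(gx, rep(1, length(iy))) * sin(th) +
    outer(rep(1, length(ix)), gy) * cos(th)
  d2 <- (u / a)^2 + (v / b)^2
  inside <- d2 <= 1
  n_px <- sum(inside)
  if (n_px == 0L) return(list(arr = arr, n_px = 0L, level = 0))
  ## bounded radial taper: factor in [0.85, 1], rescaled so the object mean
  ## equals the drawn class mean exactly (keeps ground-truth labels sound)
  taper <- 1 - 0.15 * d2[inside]
  level <- if (!is.null(target_mean)) target_mean / mean(taper) else peak_level
  wi <- which(inside, arr.ind = TRUE)
  idx <- cbind(ix[wi[, 1L]], iy[wi[, 2L]], rep(zi, n_px))
  arr[idx] <- pmax(arr[idx], level * taper)
  list(arr = arr, n_px = n_px, level = level)
}

## render polyline segments (um coordinates) into a 3D array with thickness;
## fully vectorized across segments
render_segments <- function(arr, segs, vs, thickness_um, value) {
  if (is.null(segs) || nrow(segs) == 0L) return(arr)
  r_px <- max(1L, round(thickness_um / vs[1L] / 2))
  off <- expand.grid(dx = -r_px:r_px, dy = -r_px:r_px)
  off <- off[off$dx^2 + off$dy^2 <= r_px^2, ]
  d <- dim(arr)
  len <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)
  np <- pmax(2L, ceiling(len / (0.4 * vs[1L])))
  sid <- rep(seq_len(nrow(segs)), np)          # segment of each sample point
  tt <- (sequence(np) - 1) / (np[sid] - 1)
  xs <- segs$x0[sid] + tt * (segs$x1 - segs$x0)[sid]
  ys <- segs$y0[sid] + tt * (segs$y1 - segs$y0)[sid]
  zs <- segs$z0[sid] + tt * (segs$z1 - segs$z0)[sid]
  px <- floor(xs / vs[1L]) + 1L
  py <- floor(ys / vs[2L]) + 1L
  pz <- pmin(pmax(floor(zs / vs[3L]) + 1L, 1L), d[3L])
  ax <- rep(px, nrow(off)) + rep(off$dx, each = length(px))
  ay <- rep(py, nrow(off)) + rep(off$dy, each = length(py))
  az <- rep(pz, nrow(off))
  ok <- ax >= 1L & ax <= d[1L] & ay >= 1L & ay <= d[2L]
  lin <- ax[ok] + (ay[ok] - 1L) * d[1L] + (az[ok] - 1L) * d[1L] * d[2L]
  lin <- unique(lin)
  arr[lin] <- pmax(arr[lin], value)
  arr
}

## random-walk branch from (x0, y0) with sub-branch spawning; appends
## numeric rows (x0, y0, z0, x1, y1, z1) to the accumulator list `acc`
walk_branch <- function(acc, x0, y0, z0, angle, max_r, origin, step, tort,
                        branch_prob) {
  ## explicit stack instead of recursion: (x, y, z, angle, depth)
  todo <- list(c(x0, y0, z0, angle, 0))
  while (length(todo)) {
    st <- todo[[length(todo)]]
    todo[[length(todo)]] <- NULL
    x <- st[1L]; y <- st[2L]; z <- st[3L]; ang <- st[4L]; depth <- st[5L]
    for (s in seq_len(60L)) {
      ang <- ang + stats::rnorm(1, 0, tort)
      nx <- x + step * cos(ang); ny <- y + step * sin(ang)
      nz <- z + stats::rnorm(1, 0, 0.3)
      if (sqrt((nx - origin[1L])^2 + (ny - origin[2L])^2) > max_r) break
      acc[[length(acc) + 1L]] <- c(x, y, z, nx, ny, nz)
      if (depth < 2 && stats::runif(1) < branch_prob) {
        side <- sample(c(-1, 1), 1L) * stats::runif(1, 0.4, 1.2)
        todo[[length(todo) + 1L]] <- c(nx, ny, nz, ang + side, depth + 1)
      }
      x <- nx; y <- ny; z <- nz
    }
  }
  acc
}

#' Generate a synthetic 3-channel cortical image stack with ground truth
#'
#' Renders (1) a nuclear channel (`neun`) holding every nucleus, (2) an
#' activation channel (`cfos`) holding the c-Fos positive nuclei at their
#' class intensities, and (3) a microglial channel (`p2y12`) holding somata,
#' single-cell arbors confined to `single_cell_radius`, inter-cellular
#' processes confined to the 1-2 radius annulus of the territory between
#' cells, and (optionally) extra branches near activated nuclei. All draws
#' flow from `params$seed`; identical parameters give bit-identical output.
#'
#' Ground-truth labels are certified against the rendered objects: the
#' recorded area is the rendered pixel count converted to um^2 and the
#' recorded mean gray is the exact object mean before noise, so at
#' `noise_sd = 0` every label is reproducible from the stated thresholds.
#'
#' @param params a [sim_params()] object
#' @param layout a [cortex_layout()] object
#' @return a list with elements `stack` (an [image_stack()]) and `truth`
#'   (list with `nuclei`, `somata`, `branches` data frames and `seed`)
#' @export
generate_cortex_stack <- function(params, layout) {
  stopifnot(inherits(params, "sim_params"), inherits(layout, "cortex_layout"))
  fs <- layout$field_size
  vs <- layout$voxel_size
  if (length(fs) == 2L) { fs <- c(fs, vs[2L]); vs <- c(vs, vs[2L]) }
  d <- pmax(1L, round(fs / vs))
  with_seed(params$seed, {
    neun <- array(0, dim = d); cfos <- array(0, dim = d)
    p2y12 <- array(0, dim = d)
    thr <- params$thresholds

    ## ---- nuclei -----------------------------------------------------------
    counts <- params$nucleus_count
    n_total <- sum(counts)
    margin <- 12
    if (n_total > 0 && (fs[1L] <= 2 * margin || fs[2L] <= 2 * margin))
      stop("field too small for requested object counts")
    min_sep <- 24
    centers <- matrix(numeric(0), ncol = 2L)
    tries <- 0L
    while (nrow(centers) < n_total) {
      cand <- c(stats::runif(1, margin, fs[1L] - margin),
                stats::runif(1, margin, fs[2L] - margin))
      ok <- nrow(centers) == 0L ||
        min(sqrt((centers[, 1L] - cand[1L])^2 +
                   (centers[, 2L] - cand[2L])^2)) >= min_sep
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_total))
        stop("field too small for requested object counts")
    }
    cls <- rep(names(counts), counts)
    nuclei <- NULL
    if (n_total > 0) {
      z_um <- stats::runif(n_total, 0, fs[3L])
      zi <- pmin(pmax(floor(z_um / vs[3L]) + 1L, 1L), d[3L])
      for (i in seq_len(n_total)) {
        cl <- cls[i]
        if (cl == "cfos_plus") {
          ## fails the intensity arm by construction
          inten <- rtrunc_norm(1, params$intensity_mean[cl],
                               params$intensity_sd[cl],
                               upper = thr$min_intensity * 0.96)
          area <- rtrunc_norm(1, params$area_mean[cl], params$area_sd[cl],
                              lower = 120)
        } else if (cl == "cfos_plusplus") {
          inten <- rtrunc_norm(1, params$intensity_mean[cl],
                               params$intensity_sd[cl],
                               lower = thr$min_intensity * 1.1)
          area <- rtrunc_norm(1, params$area_mean[cl], params$area_sd[cl],
                              lower = thr$min_area * 1.12)
        } else {
          inten <- rtrunc_norm(1, params$intensity_mean[cl],
                               params$intensity_sd[cl], lower = 100)
          area <- rtrunc_norm(1, params$area_mean[cl], params$area_sd[cl],
                              lower = 70)
        }
        ## every nucleus appears in the nuclear channel
        rn <- render_ellipse(neun, centers[i, 1L], centers[i, 2L], zi[i],
                             area, vs,
                             target_mean = if (cl == "negative") inten
                                           else params$intensity_mean["negative"])
        neun <- rn$arr
        n_px <- rn$n_px
        mean_gray <- NA_real_
        if (cl != "negative") {
          rc <- render_ellipse(cfos, centers[i, 1L], centers[i, 2L], zi[i],
                               area, vs, target_mean = inten)
          cfos <- rc$arr
          n_px <- rc$n_px
          mean_gray <- inten
        }
        area_meas <- n_px * vs[1L] * vs[2L]
        label <- if (cl == "negative") "negative"
                 else if (area_meas > thr$min_area &&
                          mean_gray > thr$min_intensity) "cfos_plusplus"
                 else "cfos_plus"
        nuclei <- rbind(nuclei, data.frame(
          id = i, x_um = centers[i, 1L], y_um = centers[i, 2L], z_um = z_um[i],
          area_um2 = area_meas, mean_gray = mean_gray,
          activation_class = label,
          layer = layer_of(centers[i, 1L], layout),
          attracted = FALSE, stringsAsFactors = FALSE))
      }
    } else {
      nuclei <- data.frame(id = integer(0), x_um = numeric(0),
                           y_um = numeric(0), z_um = numeric(0),
                           area_um2 = numeric(0), mean_gray = numeric(0),
                           activation_class = character(0),
                           layer = character(0), attracted = logical(0),
                           stringsAsFactors = FALSE)
    }

    ## ---- microglia --------------------------------------------------------
    somata <- data.frame(x_um = numeric(0), y_um = numeric(0),
                         z_um = numeric(0))
    acc_single <- list(); acc_inter <- list(); acc_attr <- list()
    if (params$soma_density > 0) {
      spacing <- 1000 / sqrt(params$soma_density)   # um, quasi-regular grid
      nx_g <- floor(fs[1L] / spacing + 1e-9)
      ny_g <- floor(fs[2L] / spacing + 1e-9)
      if (nx_g < 1L || ny_g < 1L)
        stop("field too small for the requested soma density")
      gx <- (fs[1L] - (nx_g - 1L) * spacing) / 2 + spacing * (0:(nx_g - 1L))
      gy <- (fs[2L] - (ny_g - 1L) * spacing) / 2 + spacing * (0:(ny_g - 1L))
      grid <- expand.grid(x = gx, y = gy)
      jit <- 0.2 * spacing
      sx <- pmin(pmax(grid$x + stats::runif(nrow(grid), -jit, jit), 3),
                 fs[1L] - 3)
      sy <- pmin(pmax(grid$y + stats::runif(nrow(grid), -jit, jit), 3),
                 fs[2L] - 3)
      sz <- stats::runif(nrow(grid), 0.3 * fs[3L], 0.7 * fs[3L])
      somata <- data.frame(x_um = sx, y_um = sy, z_um = sz)
      r1 <- params$single_cell_radius
      r2 <- 2 * params$single_cell_radius
      for (s in seq_len(nrow(somata))) {
        org <- c(somata$x_um[s], somata$y_um[s])
        ## single-cell arborisation: primary branches, truncated at r1
        base_ang <- stats::runif(1, 0, 2 * pi)
        for (b in seq_len(params$n_primary)) {
          ang <- base_ang + 2 * pi * (b - 1) / params$n_primary +
            stats::rnorm(1, 0, 0.2)
          acc_single <- walk_branch(acc_single,
                                    org[1L] + 2 * cos(ang),
                                    org[2L] + 2 * sin(ang),
                                    somata$z_um[s], ang, r1, org,
                                    params$branch_step_um,
                                    params$tortuosity_sd,
                                    params$branch_prob)
        }
        ## inter-cellular processes: confined to the territory between cells
        ## (distance to *every* soma >= r1 plus a margin absorbing the
        ## rendered branch thickness, distance to this soma <= r2)
        rmarg <- r1 + 2 * params$branch_thickness_um
        nb_f <- params$intercell_base_segments * params$intercell_branch_density
        nb <- floor(nb_f) + stats::rbinom(1L, 1L, nb_f - floor(nb_f))
        for (b in seq_len(nb)) {
          phi <- stats::runif(1, 0, 2 * pi)
          rho <- stats::runif(1, rmarg + 1, r2 - 1)
          x <- org[1L] + rho * cos(phi); y <- org[2L] + rho * sin(phi)
          dmin <- min(sqrt((somata$x_um - x)^2 + (somata$y_um - y)^2))
          if (dmin < rmarg) next
          z <- somata$z_um[s]
          ang <- phi + pi / 2 * sample(c(-1, 1), 1L) + stats::rnorm(1, 0, 0.3)
          nsteps <- sample(3:6, 1L)
          for (st in seq_len(nsteps)) {
            ang <- ang + stats::rnorm(1, 0, params$tortuosity_sd)
            nx2 <- x + params$branch_step_um * cos(ang)
            ny2 <- y + params$branch_step_um * sin(ang)
            nz2 <- z + stats::rnorm(1, 0, 0.3)
            rr <- sqrt((nx2 - org[1L])^2 + (ny2 - org[2L])^2)
            dmin <- if (nrow(somata)) min(sqrt((somata$x_um - nx2)^2 +
                                                 (somata$y_um - ny2)^2)) else Inf
            if (rr < rmarg || rr > r2 - 0.5 || dmin < rmarg) break
            acc_inter[[length(acc_inter) + 1L]] <- c(x, y, z, nx2, ny2, nz2)
            x <- nx2; y <- ny2; z <- nz2
          }
        }
      }
      ## somata discs
      for (s in seq_len(nrow(somata))) {
        rs <- render_ellipse(p2y12, somata$x_um[s], somata$y_um[s],
                             pmin(pmax(floor(somata$z_um[s] / vs[3L]) + 1L,
                                       1L), d[3L]),
                             area_um2 = pi * 2.5^2, vs, target_mean = 600)
        p2y12 <- rs$arr
      }
    }

    ## preferential branches near activated nuclei
    if (params$activation_attraction > 0 && nrow(nuclei) > 0) {
      act <- which(nuclei$activation_class != "negative")
      for (i in act) {
        nuclei$attracted[i] <- TRUE
        for (b in seq_len(params$activation_attraction)) {
          phi <- stats::runif(1, 0, 2 * pi)
          rho <- stats::runif(1, 1, 0.6 * params$attraction_radius)
          x <- nuclei$x_um[i] + rho * cos(phi)
          y <- nuclei$y_um[i] + rho * sin(phi)
          z <- nuclei$z_um[i]
          ang <- stats::runif(1, 0, 2 * pi)
          for (st in seq_len(3L)) {
            nx2 <- x + params$branch_step_um * cos(ang)
            ny2 <- y + params$branch_step_um * sin(ang)
            if (sqrt((nx2 - nuclei$x_um[i])^2 + (ny2 - nuclei$y_um[i])^2) >
                params$attraction_radius) break
            acc_attr[[length(acc_attr) + 1L]] <- c(x, y, z, nx2, ny2, z)
            x <- nx2; y <- ny2
            ang <- ang + stats::rnorm(1, 0, params$tortuosity_sd)
          }
        }
      }
    }

    to_df <- function(acc, zone) {
      if (!length(acc)) return(NULL)
      m <- do.call(rbind, acc)
      data.frame(x0 = m[, 1L], y0 = m[, 2L], z0 = m[, 3L], x1 = m[, 4L],
                 y1 = m[, 5L], z1 = m[, 6L], zone = zone,
                 stringsAsFactors = FALSE)
    }
    branches <- rbind(to_df(acc_single, "single_cell"),
                      to_df(acc_inter, "intercell"),
                      to_df(acc_attr, "attraction"))
    if (is.null(branches))
      branches <- data.frame(x0 = numeric(0), y0 = numeric(0),
                             z0 = numeric(0), x1 = numeric(0),
                             y1 = numeric(0), z1 = numeric(0),
                             zone = character(0), stringsAsFactors = FALSE)
    if (nrow(branches) > 0)
      p2y12 <- render_segments(p2y12, branches, vs,
                               params$branch_thickness_um, 400)

    ## ---- noise ------------------------------------------------------------
    if (params$noise_sd > 0) {
      for (nm in c("neun", "cfos", "p2y12")) {
        a <- get(nm)
        a <- pmax(a + stats::rnorm(length(a), 0, params$noise_sd), 0)
        assign(nm, array(a, dim = d))
      }
    }

    stack <- image_stack(list(neun = neun, cfos = cfos, p2y12 = p2y12), vs)
    list(stack = stack,
         truth = list(nuclei = nuclei, somata = somata, branches = branches,
                      seed = params$seed, params = params, layout = layout))
  })
}

#' Write simulation parameters to a YAML config file
#' @param params a [sim_params()] object
#' @param path output path
#' @export
write_sim_config <- function(params, path) {
  p <- unclass(params)
  p$thresholds <- list(min_area = p$thresholds$min_area,
                       min_intensity = p$thresholds$min_intensity)
  yaml::write_yaml(lapply(p, function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

#' Read simulation parameters from a YAML config file
#' @param path config path written by [write_sim_config()]
#' @return a [sim_params()] object
#' @export
read_sim_config <- function(path) {
  p <- yaml::read_yaml(path)
  unl <- function(x) unlist(x)
  sim_params(nucleus_count = unl(p$nucleus_count),
             intensity_mean = unl(p$intensity_mean),
             intensity_sd = unl(p$intensity_sd),
             area_mean = unl(p$area_mean), area_sd = unl(p$area_sd),
             thresholds = threshold_pair(p$thresholds$min_area,
                                         p$thresholds$min_intensity),
             noise_sd = p$noise_sd, soma_density = p$soma_density,
             single_cell_radius = p$single_cell_radius,
             intercell_branch_density = p$intercell_branch_density,
             intercell_base_segments = p$intercell_base_segments,
             activation_attraction = p$activation_attraction,
             attraction_radius = p$attraction_radius,
             n_primary = p$n_primary, branch_step_um = p$branch_step_um,
             branch_prob = p$branch_prob, tortuosity_sd = p$tortuosity_sd,
             branch_thickness_um = p$branch_thickness_um, seed = p$seed)
}
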