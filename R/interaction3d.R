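## Neuron-centered quantification of microglial branch recruitment:
## 2D Sholl on the skeleton grouped by activation status, 3D spherical-shell
## Sholl on the thresholded membrane volume, and soma-contact fractions.

#' Neuron-centered 2D Sholl profiles grouped by activation status
#'
#' Runs [sholl_2d()] from every neuronal centre and groups the profiles by
#' status (`activated` = c-Fos positive vs `inactive` = NeuN positive /
#' c-Fos negative). A per-radius two-group Mann-Whitney comparison is
#' attached; status x radius interaction testing is left to
#' [two_way_anova_bonferroni()] on the returned long table.
#'
#' @param skeleton binary skeleton matrix
#' @param centers data frame with columns `x_um`, `y_um`, `status`
#'   (values `"activated"` / `"inactive"`)
#' @param r_max maximum radius, um
#' @param dr radius step, um
#' @param voxel_size in-plane pixel size, um
#' @return list with `profiles` (long data frame: center_id, status,
#'   radius_um, crossings), `mean_by_status` (status x radius means), and
#'   `per_radius_tests` (radius_um, p_value)
#' @export
neuron_sholl_2d <- function(skeleton, centers, r_max = 15, dr = 1,
                            voxel_size = 0.5) {
  stopifnot(all(c("x_um", "y_um", "status") %in% names(centers)))
  if (!all(centers$status %in% c("activated", "inactive")))
    stop("status must be 'activated' or 'inactive'")
  profs <- lapply(seq_len(nrow(centers)), function(i)
    sholl_2d(skeleton, c(centers$x_um[i], centers$y_um[i]), r_max, dr,
             voxel_size))
  long <- do.call(rbind, lapply(seq_along(profs), function(i)
    data.frame(center_id = i, status = centers$status[i],
               radius_um = profs[[i]]$radius_um,
               crossings = profs[[i]]$crossings,
               stringsAsFactors = FALSE)))
  mean_by_status <- aggregate(crossings ~ status + radius_um, long, mean)
  radii <- sort(unique(long$radius_um))
  tests <- do.call(rbind, lapply(radii, function(r) {
    a <- long$crossings[long$radius_um == r & long$status == "activated"]
    b <- long$crossings[long$radius_um == r & long$status == "inactive"]
    p <- if (length(a) >= 2L && length(b) >= 2L)
      mann_whitney(a, b)$p_value else NA_real_
    data.frame(radius_um = r, p_value = p)
  }))
  list(profiles = long, mean_by_status = mean_by_status,
       per_radius_tests = tests)
}

#' Neuron-centered 3D Sholl analysis of a thresholded membrane volume
#'
#' For each radius `r` on the grid `seq(dr, r_max, dr)` the spherical shell
#' collects the foreground voxels whose centre distance from the Sholl
#' centre lies in `[r - dr/2, r + dr/2)` (Euclidean distance in
#' micrometres, so per-axis anisotropy is respected), and the reported count
#' is the number of 26-connected clusters of those voxels -- each cluster is
#' one branch piercing the shell.
#'
#' The analysis refuses volumes thinner than `2 * r_max` along z unless
#' `allow_border = TRUE`; shells that extend beyond the volume are then
#' computed on the in-bounds fraction and flagged.
#'
#' @param mask3d logical/0-1 3D array (thresholded membrane channel)
#' @param center centre in micrometres, length 3
#' @param voxel_size um per voxel along each axis, length 3
#' @param r_max maximum radius, um (default 15)
#' @param dr shell thickness, um (default 1)
#' @param allow_border accept centres whose largest shell leaves the volume
#' @return data frame of class `sholl_profile` with columns `radius_um`,
#'   `components`, `partial`; attribute `sholl_dim` = "3D"
#' @export
sholl_3d <- function(mask3d, center, voxel_size, r_max = 15, dr = 1,
                     allow_border = FALSE) {
  d <- dim(mask3d)
  if (length(d) != 3L) stop("mask3d must be a 3D array")
  if (length(center) != 3L || length(voxel_size) != 3L)
    stop("center and voxel_size must have length 3")
  z_extent <- d[3L] * voxel_size[3L]
  if (!allow_border && z_extent < 2 * r_max)
    stop("volume thinner than 2 * r_max along z; pass allow_border = TRUE to force")
  cpx <- floor(center / voxel_size) + 1L
  if (any(cpx < 1L) || any(cpx > d)) stop("center outside volume")
  ## squared distance (um) of every voxel centre from the Sholl centre
  ax <- ((seq_len(d[1L]) - 0.5) * voxel_size[1L] - center[1L])^2
  ay <- ((seq_len(d[2L]) - 0.5) * voxel_size[2L] - center[2L])^2
  az <- ((seq_len(d[3L]) - 0.5) * voxel_size[3L] - center[3L])^2
  fg <- which(mask3d > 0)
  radii <- seq(dr, r_max, by = dr)
  comp <- integer(length(radii))
  partial <- logical(length(radii))
  ## distance of the centre to each face of the volume, um
  border_dist <- min(center[1L], d[1L] * voxel_size[1L] - center[1L],
                     center[2L], d[2L] * voxel_size[2L] - center[2L],
                     center[3L], d[3L] * voxel_size[3L] - center[3L])
  if (length(fg)) {
    pos <- arrayInd(fg, d)
    dist <- sqrt(ax[pos[, 1L]] + ay[pos[, 2L]] + az[pos[, 3L]])
    shell <- as.integer(floor(dist / dr + 0.5))   # [r - dr/2, r + dr/2)
    for (i in seq_along(radii)) {
      k <- as.integer(round(radii[i] / dr))
      partial[i] <- (radii[i] + dr / 2) > border_dist
      sel <- shell == k
      if (!any(sel)) next
      comp[i] <- count_clusters(pos[sel, , drop = FALSE])
    }
  } else {
    partial <- (radii + dr / 2) > border_dist
  }
  out <- data.frame(radius_um = radii, components = comp, partial = partial)
  attr(out, "center") <- center
  attr(out, "dr") <- dr
  attr(out, "sholl_dim") <- "3D"
  class(out) <- c("sholl_profile", class(out))
  out
}

#' Select neuronal centres eligible for 3D analysis
#'
#' Keeps centres lying in the central `central_um` band of the volume's
#' z-extent, so that every shell up to `r_max` stays inside the stack.
#'
#' @param centers data frame with `z_um`
#' @param z_extent_um total z extent of the volume, um
#' @param central_um width of the central eligibility band, um (default 15)
#' @return the data frame restricted to eligible centres
#' @export
filter_central_z <- function(centers, z_extent_um, central_um = 15) {
  lo <- (z_extent_um - central_um) / 2
  hi <- z_extent_um - lo
  centers[centers$z_um >= lo & centers$z_um <= hi, , drop = FALSE]
}

#' Soma-contact fraction of activated nuclei
#'
#' A nucleus counts as contacting a microglial soma when its mask, dilated
#' by `dilation_um`, overlaps the soma mask; equivalently, when the minimum
#' distance from any nucleus pixel to the soma mask is at most
#' `dilation_um`. The default margin of one pixel approximates direct
#' physical apposition.
#'
#' @param nucleus_labels integer label matrix of the activated nuclei (e.g.
#'   the `"labels"` attribute of [detect_nuclei()] subset to activated ids)
#' @param ids integer vector of activated nucleus labels to assess
#' @param soma_mask logical matrix of microglial somata on the same grid
#' @param voxel_size in-plane pixel size, um
#' @param dilation_um contact margin, um (default: one pixel)
#' @return fraction in `[0, 1]` of assessed nuclei in contact
#' @export
soma_contact_fraction <- function(nucleus_labels, ids, soma_mask,
                                  voxel_size = 0.5, dilation_um = NULL) {
  if (!identical(dim(nucleus_labels), dim(soma_mask)))
    stop("nucleus and soma masks must share the grid")
  if (length(ids) == 0L)
    stop("empty activated set: contact fraction undefined")
  if (is.null(dilation_um)) dilation_um <- voxel_size
  if (sum(soma_mask > 0) == 0L) return(0)
  ## distance (px) of every non-soma pixel to the nearest soma pixel
  dt <- EBImage::distmap(EBImage::Image(1 - (soma_mask > 0)))
  dt <- as.matrix(dt) * voxel_size
  contacted <- vapply(ids, function(id) {
    px <- which(nucleus_labels == id)
    if (!length(px)) return(NA)
    min(dt[px]) <= dilation_um + 1e-9
  }, logical(1))
  if (anyNA(contacted)) stop("an id has no pixels in nucleus_labels")
  mean(contacted)
}
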