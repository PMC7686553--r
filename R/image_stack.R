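#' Multi-channel image stack with physical voxel size
#'
#' The substrate of all imaging stages: a named list of 2D matrices or 3D
#' arrays (one per channel) plus the per-axis voxel size in micrometres.
#' Pixel indices are 0-based in the physical convention: the centre of pixel
#' `p` (0-based) lies at `(p + 0.5) * voxel_size` micrometres. In R's 1-based
#' indexing, matrix element `[i, j]` is centred at
#' `((i - 0.5) * vs_x, (j - 0.5) * vs_y)`.
#'
#' @param channels named list of numeric matrices (2D) or arrays (3D), all of
#'   identical dimension
#' @param voxel_size numeric length 2 (2D) or 3 (3D), micrometres per pixel
#'   along each axis; strictly positive
#' @return an object of class `image_stack`
#' @export
image_stack <- function(channels, voxel_size) {
  if (!is.list(channels) || length(channels) < 1L || is.null(names(channels)))
    stop("channels must be a non-empty named list")
  d <- dim(channels[[1L]])
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("channels must be 2D matrices or 3D arrays")
  for (ch in channels)
    if (!identical(dim(ch), d)) stop("all channels must share dimensions")
  if (any(d < 1L)) stop("all dimensions must be >= 1")
  if (length(voxel_size) != length(d))
    stop("voxel_size must have one entry per axis")
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive")
  structure(list(channels = channels, voxel_size = as.numeric(voxel_size)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("image_stack: %s, channels [%s], voxel size %s um\n",
              paste(d, collapse = " x "),
              paste(names(x$channels), collapse = ", "),
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' Number of z slices of a stack (1 for 2D)
#' @param stack an `image_stack`
#' @export
n_slices <- function(stack) {
  d <- dim(stack$channels[[1L]])
  if (length(d) == 3L) d[3L] else 1L
}

#' Project a 3D stack to 2D
#'
#' Maximal projection is the standard reduction for fluorescence stacks;
#' sum-of-slices is used for DAB brightfield material. Both reduce along z.
#'
#' @param stack a 3D `image_stack`
#' @param mode `"max"` or `"sum"`
#' @return a 2D `image_stack` with the same channels and in-plane voxel size
#' @export
project_stack <- function(stack, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  d <- dim(stack$channels[[1L]])
  if (length(d) != 3L)
    stop("project_stack requires a 3D stack; input is already 2D")
  f <- function(a) {
    slices <- lapply(seq_len(d[3L]), function(k) a[, , k])
    if (mode == "max") Reduce(pmax, slices) else Reduce(`+`, slices)
  }
  ch2 <- lapply(stack$channels, f)
  image_stack(ch2, stack$voxel_size[1:2])
}

#' Write an image stack as multi-page TIFF plus a sidecar metadata file
#'
#' Pages are ordered channel-major (all z slices of channel 1, then channel 2,
#' ...). Intensities are stored as 32-bit float after division by a recorded
#' scale so arbitrary dynamic ranges round-trip. Voxel size, channel names and
#' the scale go into `<path>.yaml`.
#'
#' @param stack an `image_stack`
#' @param path output TIFF path
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$channels[[1L]])
  nz <- if (length(d) == 3L) d[3L] else 1L
  mx <- max(1e-12, max(vapply(stack$channels, max, numeric(1))))
  pages <- list()
  for (ch in stack$channels) {
    a <- if (length(d) == 2L) array(ch, dim = c(d, 1L)) else ch
    for (k in seq_len(nz)) pages[[length(pages) + 1L]] <- a[, , k] / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(channel_names = names(stack$channels),
               voxel_size_um = as.numeric(stack$voxel_size),
               n_slices = nz, intensity_scale = mx)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path (expects the `<path>.yaml` sidecar next to it)
#' @return an `image_stack`
#' @export
read_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_slices
  nch <- length(meta$channel_names)
  if (length(pages) != nz * nch) stop("page count does not match metadata")
  chs <- list()
  for (c in seq_len(nch)) {
    sl <- pages[((c - 1L) * nz + 1L):(c * nz)]
    a <- array(0, dim = c(dim(sl[[1L]]), nz))
    for (k in seq_len(nz)) a[, , k] <- sl[[k]] * meta$intensity_scale
    chs[[meta$channel_names[c]]] <- if (nz == 1L) a[, , 1L] else a
  }
  image_stack(chs, meta$voxel_size_um)
}
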