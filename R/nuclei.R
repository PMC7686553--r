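## Nucleus detection, dual-threshold activation classification, cortical
## layer assignment and medial-distal intensity profiles.

#' Area/intensity threshold pair for strong-activation classification
#'
#' A nucleus is called strongly activated (`cfos_plusplus`) when its
#' projected area strictly exceeds `min_area` AND its mean gray value
#' strictly exceeds `min_intensity`. The conventional pair for c-Fos
#' immunofluorescence is 200 um^2 and 400 mean gray; an alternative pair of
#' 100 um^2 and 1100 mean gray is provided as
#' [thresholds_high_intensity()] for stainings with a hotter intensity scale.
#'
#' @param min_area minimum projected area, um^2 (strictly positive)
#' @param min_intensity minimum mean gray value (strictly positive)
#' @return list of class `threshold_pair`
#' @export
threshold_pair <- function(min_area = 200, min_intensity = 400) {
  if (min_area <= 0 || min_intensity <= 0)
    stop("thresholds must be strictly positive")
  structure(list(min_area = min_area, min_intensity = min_intensity),
            class = "threshold_pair")
}

#' Alternative threshold pair (100 um^2, 1100 mean gray)
#' @return a [threshold_pair()]
#' @export
thresholds_high_intensity <- function() threshold_pair(100, 1100)

## Otsu level on an arbitrary-range image; errors on flat input
auto_threshold_level <- function(img, method = "otsu") {
  if (method != "otsu") stop("unknown auto-threshold method: ", method)
  rng <- range(img)
  if (diff(rng) <= 0)
    stop("flat image: auto-thresholding undefined, supply a manual level")
  lv <- EBImage::otsu(EBImage::Image(img / rng[2L]), range = c(0, 1),
                      levels = 256L)
  lv * rng[2L]
}

#' Detect nuclear objects in a 2D projected image
#'
#' Auto-thresholds the channel (Otsu by default), labels 8-connected
#' foreground components, filters by minimum area, and measures each object's
#' centroid (um, pixel-centre convention), projected area (um^2) and mean
#' gray value on the *original* unthresholded image over the object mask.
#'
#' @param image2d numeric matrix (single channel) or a 2D [image_stack()]
#' @param voxel_size in-plane pixel size, um (length 1 or 2); taken from the
#'   stack when `image2d` is an `image_stack`
#' @param channel channel name when `image2d` is an `image_stack`
#' @param method auto-threshold method (currently `"otsu"`)
#' @param min_area minimum object area, um^2
#' @return data frame (one row per object) with columns `id`, `x_um`, `y_um`,
#'   `area_um2`, `mean_gray`, `activation_class` (NA until classified); the
#'   label matrix is attached as attribute `"labels"` and the threshold level
#'   as `"level"`
#' @export
detect_nuclei <- function(image2d, voxel_size = NULL, channel = NULL,
                          method = "otsu", min_area = 50) {
  if (inherits(image2d, "image_stack")) {
    if (is.null(channel)) channel <- names(image2d$channels)[1L]
    voxel_size <- image2d$voxel_size[1:2]
    image2d <- image2d$channels[[channel]]
  }
  if (is.null(voxel_size)) stop("in-plane voxel size must be known")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 2L)
  if (length(dim(image2d)) != 2L) stop("detect_nuclei expects a 2D image")
  px_area <- voxel_size[1L] * voxel_size[2L]
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_gray = numeric(0),
                      activation_class = character(0),
                      stringsAsFactors = FALSE)
  if (diff(range(image2d)) <= 0) {
    attr(empty, "labels") <- array(0L, dim = dim(image2d))
    attr(empty, "level") <- NA_real_
    return(empty)
  }
  level <- auto_threshold_level(image2d, method)
  lab <- label_components(image2d > level)
  k <- max(lab)
  if (k == 0L) {
    attr(empty, "labels") <- lab
    attr(empty, "level") <- level
    return(empty)
  }
  idx <- which(lab > 0L)
  pos <- arrayInd(idx, dim(lab))
  lv <- lab[idx]
  npx <- tabulate(lv, k)
  mx <- tapply(pos[, 1L], lv, mean)
  my <- tapply(pos[, 2L], lv, mean)
  mg <- tapply(image2d[idx], lv, mean)
  out <- data.frame(id = seq_len(k),
                    x_um = (as.numeric(mx) - 0.5) * voxel_size[1L],
                    y_um = (as.numeric(my) - 0.5) * voxel_size[2L],
                    area_um2 = npx * px_area,
                    mean_gray = as.numeric(mg),
                    activation_class = NA_character_,
                    stringsAsFactors = FALSE)
  keep <- out$area_um2 >= min_area
  ## relabel the matrix to the kept objects only
  lab2 <- array(0L, dim = dim(lab))
  if (any(keep)) {
    kept_ids <- out$id[keep]
    lab2[idx] <- match(lv, kept_ids, nomatch = 0L)
  }
  out <- out[keep, , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "labels") <- lab2
  attr(out, "level") <- level
  out
}

#' Classify nuclei as c-Fos+ or c-Fos++ by the dual threshold
#'
#' Strict comparisons: an object is `cfos_plusplus` iff `area_um2 >
#' min_area` AND `mean_gray > min_intensity`; every other detected object is
#' `cfos_plus`. Boundary values therefore fall to `cfos_plus`.
#'
#' @param nuclei data frame from [detect_nuclei()] (needs `area_um2`,
#'   `mean_gray`)
#' @param thresholds a [threshold_pair()]
#' @return the data frame with `activation_class` filled in
#' @export
classify_activation <- function(nuclei, thresholds = threshold_pair()) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  if (nrow(nuclei) == 0L) return(nuclei)
  if (any(is.na(nuclei$area_um2)) || any(is.na(nuclei$mean_gray)))
    stop("area and mean gray must be populated before classification")
  strong <- nuclei$area_um2 > thresholds$min_area &
    nuclei$mean_gray > thresholds$min_intensity
  nuclei$activation_class <- ifelse(strong, "cfos_plusplus", "cfos_plus")
  nuclei
}

#' Assign cortical layers to nuclei
#'
#' Each nucleus is assigned by its centroid's medial-distal position into
#' consecutive half-open bands `[start, start + width)` measured from the
#' midline edge of the layout. Positions beyond the last band get the
#' sentinel label `"beyond_VI"`; nothing is dropped.
#'
#' @param nuclei data frame with column `x_um`
#' @param layout a [cortex_layout()]
#' @return the data frame with a `layer` column
#' @export
assign_layers <- function(nuclei, layout) {
  stopifnot(inherits(layout, "cortex_layout"))
  nuclei$layer <- if (nrow(nuclei)) layer_of(nuclei$x_um, layout)
                  else character(0)
  nuclei
}

#' Per-layer counts and densities
#'
#' @param nuclei data frame with `layer` assigned (and `activation_class` if
#'   `class_filter` is used)
#' @param layout a [cortex_layout()]
#' @param class_filter optional activation classes to count (default: all)
#' @return data frame with columns `layer`, `count`, `density_mm2` (objects
#'   per mm^2 of the layer band within the field)
#' @export
layer_counts <- function(nuclei, layout, class_filter = NULL) {
  stopifnot(inherits(layout, "cortex_layout"))
  b <- layer_bands(layout)
  ## band area inside the field, mm^2
  width_x <- pmin(b$end, layout$field_size[1L]) - pmin(b$start,
                                                       layout$field_size[1L])
  band_area <- width_x * layout$field_size[2L] / 1e6
  if (any(band_area <= 0)) stop("zero-area layer band inside the field")
  sel <- nuclei
  if (!is.null(class_filter))
    sel <- sel[sel$activation_class %in% class_filter, , drop = FALSE]
  cnt <- table(factor(sel$layer, levels = c(b$layer, "beyond_VI")))
  out <- data.frame(layer = c(b$layer, "beyond_VI"),
                    count = as.integer(cnt),
                    density_mm2 = c(as.integer(cnt)[seq_len(nrow(b))] /
                                      band_area, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Longitudinal intensity profile along the medial-distal axis
#'
#' For every pixel column at distance x from the midline edge, the mean
#' intensity over the perpendicular (y) extent; per-layer grouped means are
#' attached for convenience.
#'
#' @param image2d numeric matrix or 2D [image_stack()] (first channel or
#'   `channel`)
#' @param layout a [cortex_layout()]
#' @param channel channel name when `image2d` is an `image_stack`
#' @return list of class `layer_profile` with `profile` (data frame
#'   `distance_um`, `mean_intensity`) and `by_layer` (data frame `layer`,
#'   `mean_intensity`)
#' @export
longitudinal_profile <- function(image2d, layout, channel = NULL) {
  vs <- layout$voxel_size[1:2]
  if (inherits(image2d, "image_stack")) {
    if (is.null(channel)) channel <- names(image2d$channels)[1L]
    vs <- image2d$voxel_size[1:2]
    image2d <- image2d$channels[[channel]]
  }
  if (length(dim(image2d)) != 2L)
    stop("longitudinal_profile expects a 2D image")
  extent_x <- nrow(image2d) * vs[1L]
  if (layout$midline_offset + sum(layout$layer_widths) > extent_x + 1e-9)
    stop("layout is wider than the image")
  dist <- (seq_len(nrow(image2d)) - 0.5) * vs[1L]
  prof <- rowMeans(image2d)
  lay <- layer_of(dist, layout)
  by_layer <- aggregate(list(mean_intensity = prof), list(layer = lay), mean)
  ord <- match(by_layer$layer, c(names(layout$layer_widths), "beyond_VI"))
  by_layer <- by_layer[order(ord), , drop = FALSE]
  rownames(by_layer) <- NULL
  structure(list(profile = data.frame(distance_um = dist,
                                      mean_intensity = prof),
                 by_layer = by_layer),
            class = "layer_profile")
}

#' Write a nuclei table as CSV with analysis provenance
#' @param nuclei nuclei data frame
#' @param path output path
#' @param thresholds the [threshold_pair()] used (recorded in the header)
#' @param method auto-threshold method used
#' @export
write_nuclei_table <- function(nuclei, path, thresholds = threshold_pair(),
                               method = "otsu") {
  write_table_with_provenance(
    nuclei, path,
    provenance = list(auto_threshold = method,
                      min_area_um2 = thresholds$min_area,
                      min_intensity = thresholds$min_intensity))
}
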