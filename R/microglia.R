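## Binarization, topology-preserving thinning and ramification metrics of
## the microglial channel.

#' Binarize a single-channel image
#'
#' @param image numeric matrix
#' @param method `"otsu"` or `"manual"`
#' @param manual_level threshold level for `method = "manual"`; foreground is
#'   `image > level`
#' @return list with `mask` (logical matrix) and `level` (threshold used)
#' @export
binarize <- function(image, method = c("otsu", "manual"),
                     manual_level = NULL) {
  method <- match.arg(method)
  if (length(dim(image)) != 2L) stop("binarize expects a single-channel 2D image")
  if (method == "manual") {
    if (is.null(manual_level)) stop("manual binarization needs manual_level")
    level <- manual_level
  } else {
    level <- auto_threshold_level(image, "otsu")
  }
  list(mask = image > level, level = level)
}

#' Skeletonize a binary mask to a 1-pixel-wide network
#'
#' Zhang-Suen iterative thinning: alternating sub-iterations delete simple
#' boundary pixels until stable. The result is idempotent (thinning a
#' skeleton changes nothing) and preserves the 8-connected component
#' structure of the input.
#'
#' @param mask logical or 0/1 matrix
#' @return logical matrix of class `skeleton` (attribute `voxel_size` is
#'   copied from the input when present)
#' @export
skeletonize <- function(mask) {
  if (length(dim(mask)) != 2L) stop("skeletonize expects a 2D mask")
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) {
    out <- m > 0
    class(out) <- c("skeleton", class(out))
    return(out)
  }
  ## pad so neighbour index arithmetic never leaves the matrix
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  nr <- nrow(p)
  ## linear-index offsets of the Zhang-Suen neighbourhood P2..P9 in cyclic
  ## order (a consistent orientation is all that matters)
  off <- c(nr, nr - 1L, -1L, -nr - 1L, -nr, -nr + 1L, 1L, nr + 1L)
  fg <- which(p == 1L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      if (!length(fg)) break
      nb <- matrix(0L, length(fg), 8L)
      for (k in 1:8) nb[, k] <- p[fg + off[k]]
      B <- rowSums(nb)
      nxt <- nb[, c(2:8, 1L)]
      A <- rowSums(nb == 0L & nxt == 1L)
      if (step == 1L) {
        cond <- B >= 2L & B <= 6L & A == 1L &
          (nb[, 1L] * nb[, 3L] * nb[, 5L] == 0L) &
          (nb[, 3L] * nb[, 5L] * nb[, 7L] == 0L)
      } else {
        cond <- B >= 2L & B <= 6L & A == 1L &
          (nb[, 1L] * nb[, 3L] * nb[, 7L] == 0L) &
          (nb[, 1L] * nb[, 5L] * nb[, 7L] == 0L)
      }
      if (any(cond)) {
        p[fg[cond]] <- 0L
        fg <- fg[!cond]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] > 0
  attr(out, "voxel_size") <- attr(mask, "voxel_size")
  class(out) <- c("skeleton", class(out))
  out
}

#' Ramification and staining metrics of a microglial field
#'
#' @param image original intensity image (matrix)
#' @param mask binary mask from [binarize()]
#' @param skeleton skeleton from [skeletonize()]
#' @return list with `skeleton_area_pct` (skeleton pixels / field pixels x
#'   100), `threshold_area_pct` (mask pixels / field pixels x 100) and
#'   `mean_gray` (whole-field mean of the original image)
#' @export
ramification_metrics <- function(image, mask, skeleton) {
  if (!identical(dim(image), dim(mask)) ||
      !identical(dim(image), dim(skeleton)))
    stop("image, mask and skeleton must share dimensions")
  n <- length(image)
  list(skeleton_area_pct = 100 * sum(skeleton > 0) / n,
       threshold_area_pct = 100 * sum(mask > 0) / n,
       mean_gray = mean(image))
}
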