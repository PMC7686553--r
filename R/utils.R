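## Internal numerics and component-labeling helpers shared by all modules.
## Connectivity matters for every count this package reports, so it is fixed
## here in one place: 8-connectivity in 2D, 26-connectivity in 3D.

#' Count connected groups among a set of elements given an edge list
#'
#' Union-find with path halving. `edges` is a 2-column integer matrix of
#' 1-based indices into `1:n`; elements not touched by any edge count as
#' singleton groups.
#'
#' @param n number of elements
#' @param edges integer matrix with 2 columns (may have 0 rows)
#' @return integer, the number of groups
#' @keywords internal
#' @noRd
uf_count <- function(n, edges) {
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L])
      b <- find(edges[k, 2L])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  length(unique(roots))
}

## Neighbor offsets: 8-connectivity in 2D (excluding self)
.offsets2d <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0), ])
}

## 26-connectivity in 3D (excluding self)
.offsets3d <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ])
}

#' Label connected components of a binary image
#'
#' 8-connectivity in 2D, 26-connectivity in 3D. Returns an integer array of
#' the same shape with background 0 and components labeled 1..k.
#'
#' @param mask logical or 0/1 numeric matrix (2D) or array (3D)
#' @return integer array of labels
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("mask must be a 2D matrix or 3D array")
  fg <- which(mask > 0)
  lab <- array(0L, dim = d)
  if (length(fg) == 0L) return(lab)
  pos <- arrayInd(fg, d)
  key <- fg                       # linear indices of foreground
  idx_of <- match                 # match neighbor linear index into key
  offs <- if (length(d) == 2L) .offsets2d() else .offsets3d()
  edges_a <- integer(0); edges_b <- integer(0)
  for (k in seq_len(nrow(offs))) {
    np <- sweep(pos, 2L, offs[k, ], "+")
    ok <- rep(TRUE, nrow(np))
    for (j in seq_along(d)) ok <- ok & np[, j] >= 1L & np[, j] <= d[j]
    if (!any(ok)) next
    if (length(d) == 2L) {
      nl <- np[ok, 1L] + (np[ok, 2L] - 1L) * d[1L]
    } else {
      nl <- np[ok, 1L] + (np[ok, 2L] - 1L) * d[1L] +
        (np[ok, 3L] - 1L) * d[1L] * d[2L]
    }
    m <- idx_of(nl, key)
    hit <- !is.na(m)
    if (any(hit)) {
      edges_a <- c(edges_a, which(ok)[hit])
      edges_b <- c(edges_b, m[hit])
    }
  }
  n <- length(fg)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges_a)) {
    for (k in seq_along(edges_a)) {
      a <- find(edges_a[k]); b <- find(edges_b[k])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab[fg] <- match(roots, unique(roots))
  lab
}

#' Count connected components among a subset of pixels/voxels
#'
#' Same connectivity conventions as [label_components()] but operates on an
#' explicit coordinate matrix (one row per element), which is what the Sholl
#' machinery needs.
#'
#' @param coords integer matrix of pixel (2 cols) or voxel (3 cols) positions
#' @return integer component count
#' @export
count_clusters <- function(coords) {
  n <- nrow(coords)
  if (is.null(n) || n == 0L) return(0L)
  nd <- ncol(coords)
  ## pack coordinates into a single integer key for matching
  span <- apply(coords, 2L, function(v) diff(range(v))) + 3L
  base <- coords
  for (j in seq_len(nd)) base[, j] <- coords[, j] - min(coords[, j]) + 1L
  pack <- function(m) {
    k <- m[, 1L]
    mult <- span[1L]
    if (nd >= 2L) { k <- k + m[, 2L] * mult; mult <- mult * span[2L] }
    if (nd >= 3L) k <- k + m[, 3L] * mult
    k
  }
  key <- pack(base)
  offs <- if (nd == 2L) .offsets2d() else .offsets3d()
  ea <- integer(0); eb <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(base, 2L, offs[k, ], "+")
    m <- match(pack(nb), key)
    hit <- !is.na(m)
    if (any(hit)) { ea <- c(ea, which(hit)); eb <- c(eb, m[hit]) }
  }
  uf_count(n, cbind(ea, eb))
}

#' Write a data frame as CSV with a provenance header
#'
#' Emits `# key: value` comment lines (software version, date, and any
#' caller-supplied parameters) followed by a standard CSV body, so that every
#' exported table carries the settings that produced it.
#'
#' @param df data frame
#' @param path output path
#' @param provenance named list of scalar settings to record
#' @export
write_table_with_provenance <- function(df, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  prov <- c(list(software = paste0("pfcquant ",
                                   as.character(utils::packageVersion("pfcquant")))),
            provenance)
  fmt1 <- function(v) {
    if (is.numeric(v)) format(v, digits = 17) else as.character(v)
  }
  for (nm in names(prov))
    writeLines(sprintf("# %s: %s", nm,
                       paste(fmt1(prov[[nm]]), collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_with_provenance()]
#'
#' @param path input path
#' @return data frame with attribute `"provenance"` (named character vector)
#' @export
read_table_with_provenance <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  prov <- character(0)
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    prov <- stats::setNames(vals, keys)
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"))
  attr(df, "provenance") <- prov
  df
}

## restore the RNG state on exit; gives every generator call its own stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
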