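# Image-filtering primitives of the segmentation workflow. All operate on
# plain numeric arrays; [z, y, x] for volumes, [y, x] for planes.

.disc_offsets_2d <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, ]
  cbind(dz = 0L, dy = as.integer(g$dy), dx = as.integer(g$dx))
}

.ball_offsets_3d <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, ]
  cbind(dz = as.integer(g$dz), dy = as.integer(g$dy), dx = as.integer(g$dx))
}

.as_vol <- function(x) {
  if (is.matrix(x)) array(x, dim = c(1, dim(x))) else x
}

.filter_nd <- function(x, offsets, stat) {
  vol <- .as_vol(x)
  out <- cpp_footprint_filter(as.numeric(vol), dim(vol),
                              offsets, as.integer(stat))
  dim(out) <- dim(vol)
  if (is.matrix(x)) out <- array(out, dim = dim(x))
  out
}

#' Sliding-paraboloid background subtraction
#'
#' Estimates the smooth background of a 2D plane as the grayscale opening
#' with a paraboloid structuring function of the given radius, then
#' subtracts it (clamping at zero). A flat plane is removed entirely;
#' isolated peaks narrower than the paraboloid are preserved.
#'
#' @param plane Numeric 2D matrix.
#' @param radius Paraboloid radius in pixels (default 50).
#' @return Background-subtracted plane, non-negative.
#' @export
subtract_background_paraboloid <- function(plane, radius = 50) {
  if (radius <= 0) stop("radius must be positive")
  stopifnot(is.matrix(plane))
  bg <- cpp_paraboloid_background(plane, radius)
  pmax(plane - bg, 0)
}

#' Saturated linear contrast enhancement
#'
#' Clips the stated percentage of extreme pixels (split equally between the
#' two tails) and linearly rescales the remainder to the full bit-depth
#' range.
#'
#' @param plane Numeric matrix or array.
#' @param saturation Total percentage of pixels allowed to saturate
#'   (default 0.2).
#' @param bit_depth Output range is `[0, 2^bit_depth - 1]`.
#' @return Rescaled data with attribute `flat = TRUE` when the input was
#'   degenerate (single-valued) and returned unchanged.
#' @export
enhance_contrast <- function(plane, saturation = 0.2, bit_depth = 8) {
  if (saturation < 0 || saturation >= 100) stop("saturation must be in [0, 100)")
  v <- sort(as.numeric(plane))
  n <- length(v)
  k <- floor(n * saturation / 200)
  lo <- v[k + 1]
  hi <- v[n - k]
  if (hi <= lo) {
    attr(plane, "flat") <- TRUE
    return(plane)
  }
  out <- (plane - lo) / (hi - lo) * (2^bit_depth - 1)
  out[out < 0] <- 0
  out[out > 2^bit_depth - 1] <- 2^bit_depth - 1
  out
}

#' Median filter with a circular 2D footprint
#'
#' The footprint contains every pixel whose centre lies within `radius`
#' pixels (a radius of 1.25 px gives the 5-pixel cross used by the
#' mitochondria pre-processing).
#'
#' @param plane Numeric 2D matrix.
#' @param radius Footprint radius in pixels.
#' @return Filtered plane.
#' @export
median_filter_2d <- function(plane, radius = 1.25) {
  .filter_nd(plane, .disc_offsets_2d(radius), 2L)
}

#' Median filter with a spherical 3D footprint
#'
#' @param vol Numeric 3D array `[z, y, x]`.
#' @param radius Footprint radius in voxels.
#' @return Filtered volume.
#' @export
median_filter_3d <- function(vol, radius = 2) {
  .filter_nd(vol, .ball_offsets_3d(radius), 2L)
}

#' Detect segmentation seeds as local intensity maxima
#'
#' A voxel is a candidate seed when it equals the maximum of its local box
#' window; plateaus of connected equal-valued maxima are collapsed to a
#' single seed each.
#'
#' @param vol Numeric 3D array `[z, y, x]`.
#' @param window Full window edge lengths `(x, y, z)` in voxels
#'   (default `c(8, 8, 4)`); the box half-width used is `floor(window/2)`.
#' @param exclude_zero Drop seeds at zero intensity (background plateaus).
#' @return Data frame of seed voxel coordinates `z, y, x` (1-based) and
#'   `value`.
#' @export
detect_seeds <- function(vol, window = c(8, 8, 4), exclude_zero = TRUE) {
  stopifnot(length(dim(vol)) == 3, length(window) == 3)
  hw <- as.integer(floor(window / 2))
  # window given as (x, y, z); volume is [z, y, x]
  mask <- cpp_local_max_mask(as.numeric(vol), dim(vol),
                             c(hw[3], hw[2], hw[1]))
  dim(mask) <- dim(vol)
  if (exclude_zero) mask <- mask & (vol > 0)
  lab <- cpp_label_components(as.logical(mask), dim(vol), 26L)
  dim(lab) <- dim(vol)
  ids <- unique(lab[lab > 0])
  if (length(ids) == 0) {
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      value = numeric(0)))
  }
  # one seed per plateau: the member voxel closest to the plateau centroid
  coords <- do.call(rbind, lapply(ids, function(i) {
    members <- arrayInd(which(lab == i), dim(vol))
    centre <- colMeans(members)
    d2 <- rowSums((members - rep(centre, each = nrow(members)))^2)
    members[which.min(d2), ]
  }))
  data.frame(z = coords[, 1], y = coords[, 2], x = coords[, 3],
             value = vol[coords])
}

#' Bernsen local threshold of a 2D plane
#'
#' Per pixel, the threshold is the mid-gray of the local minimum and
#' maximum within a circular radius; pixels above the threshold become
#' foreground. Where the local contrast (max - min) falls below
#' `contrast_limit`, the whole neighbourhood is deemed one class: the pixel
#' is foreground only when the local mid-gray exceeds half the intensity
#' range (128 on 8-bit data), so flat background stays background and flat
#' object interiors stay foreground.
#'
#' @param plane Numeric 2D matrix.
#' @param radius Neighbourhood radius in pixels (default 4).
#' @param contrast_limit Minimum local contrast (default 15).
#' @param low_ref Reference level for the low-contrast class
#'   (default `2^(bit_depth-1)` = 128).
#' @return Logical matrix (TRUE = foreground).
#' @export
bernsen_threshold_2d <- function(plane, radius = 4, contrast_limit = 15,
                                 low_ref = 128) {
  stopifnot(is.matrix(plane), radius >= 1)
  off <- .disc_offsets_2d(radius)
  lmin <- .filter_nd(plane, off, 0L)
  lmax <- .filter_nd(plane, off, 1L)
  mid <- (lmax + lmin) / 2
  low_contrast <- (lmax - lmin) < contrast_limit
  fg <- plane > mid
  fg[low_contrast] <- mid[low_contrast] > low_ref
  fg
}

.label_components_3d <- function(mask, connectivity = 26L) {
  lab <- cpp_label_components(as.logical(mask), dim(mask), as.integer(connectivity))
  dim(lab) <- dim(mask)
  lab
}

.seeded_watershed_3d <- function(intensity, seeds, mask, merge_radius = 5) {
  stopifnot(identical(dim(intensity), dim(mask)))
  if (nrow(seeds) == 0) return(array(0L, dim = dim(intensity)))
  keep <- mask[cbind(seeds$z, seeds$y, seeds$x)]
  seeds <- seeds[keep, , drop = FALSE]
  if (nrow(seeds) == 0) return(array(0L, dim = dim(intensity)))
  # Merge seeds closer than the watershed radius (union-find).
  n <- nrow(seeds)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    d <- as.matrix(dist(seeds[, c("x", "y", "z")]))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (d[i, j] <= merge_radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab_of <- match(roots, unique(roots))
  seed_vol <- array(0L, dim = dim(intensity))
  seed_vol[cbind(seeds$z, seeds$y, seeds$x)] <- lab_of
  out <- cpp_seeded_watershed(as.numeric(intensity), as.integer(seed_vol),
                              as.logical(mask), dim(intensity))
  dim(out) <- dim(intensity)
  out
}
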