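# Containers for 3D multi-channel image data and segmented 3D objects.

#' Construct a multi-channel 3D image stack
#'
#' @param data Numeric array `[z, y, x, channel]` (a 3D array is treated as
#'   single-channel). Intensities must lie in the declared bit-depth range.
#' @param voxel_size_nm `c(lateral, axial)` voxel size in nm. Conforming
#'   acquisitions use at most 180 nm laterally and 320 nm axially.
#' @param channels Channel names; defaults to `ch1..chN`.
#' @param bit_depth Intensity bit depth (8 by default; the printed
#'   segmentation thresholds assume 8-bit data).
#' @param normalized Whether the stack has been montage-normalized
#'   ([normalize_histograms_montage()]).
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, voxel_size_nm = c(lateral = 180, axial = 320),
                        channels = NULL, bit_depth = 8, normalized = FALSE) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1)
  stopifnot(length(dim(data)) == 4)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[4]))
  stopifnot(length(channels) == dim(data)[4])
  if (any(data < 0) || any(data > 2^bit_depth - 1)) {
    stop("intensities outside the declared bit-depth range")
  }
  dimnames(data) <- list(NULL, NULL, NULL, channels)
  structure(list(
    data = data,
    dim = dim(data)[1:3],
    voxel_size_nm = c(lateral = unname(voxel_size_nm[1]),
                      axial = unname(voxel_size_nm[2])),
    channels = channels,
    bit_depth = bit_depth,
    normalized = normalized
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x), channels: %s; voxel %g/%g nm\n",
              x$dim[1], x$dim[2], x$dim[3], paste(x$channels, collapse = ", "),
              x$voxel_size_nm["lateral"], x$voxel_size_nm["axial"]))
  invisible(x)
}

#' Volume of one voxel in cubic micrometres
#'
#' `lateral^2 * axial`, converted from nm to um.
#'
#' @param stack An `image_stack`.
#' @return Voxel volume (um^3).
#' @export
voxel_volume_um3 <- function(stack) {
  vs <- stack$voxel_size_nm / 1000
  unname(vs["lateral"]^2 * vs["axial"])
}

.stack_channel <- function(stack, channel) {
  if (!channel %in% stack$channels) {
    stop("channel '", channel, "' not present in stack")
  }
  out <- stack$data[, , , channel, drop = FALSE]
  dim(out) <- dim(stack$data)[1:3] # drop only the channel dimension
  out
}

#' Measure segmented 3D objects
#'
#' Builds a `roi_set` from a 3D label volume: per-ROI voxel count, volume in
#' um^3 (voxel count times voxel volume, from the stack metadata) and mean /
#' standard deviation of intensity in every channel of the original stack.
#'
#' @param labels Integer 3D array of object labels (0 = background).
#' @param stack The `image_stack` the labels were derived from (measurements
#'   are taken on its original intensities).
#' @return A `roi_set`: `labels` plus a measurement data frame `table` with
#'   columns `id`, `voxels`, `volume_um3`, `mean_<channel>`, `sd_<channel>`.
#' @export
measure_rois <- function(labels, stack) {
  if (is.null(stack$voxel_size_nm) || any(!is.finite(stack$voxel_size_nm))) {
    stop("voxel size metadata is required to compute volumes")
  }
  lab_vec <- as.integer(labels)
  fg <- lab_vec > 0L
  ids <- sort(unique(lab_vec[fg]))
  if (length(ids) == 0) {
    tab <- data.frame(id = integer(0), voxels = integer(0),
                      volume_um3 = numeric(0))
    for (ch in stack$channels) {
      tab[[paste0("mean_", ch)]] <- numeric(0)
      tab[[paste0("sd_", ch)]] <- numeric(0)
    }
  } else {
    f <- factor(lab_vec[fg], levels = ids)
    counts <- as.integer(table(f))
    tab <- data.frame(id = ids, voxels = counts,
                      volume_um3 = counts * voxel_volume_um3(stack))
    for (ch in stack$channels) {
      v <- as.numeric(stack$data[, , , ch])[fg]
      sums <- tapply(v, f, sum)
      sqs <- tapply(v^2, f, sum)
      mean_ <- as.numeric(sums) / counts
      var_ <- (as.numeric(sqs) - counts * mean_^2) / pmax(counts - 1, 1)
      tab[[paste0("mean_", ch)]] <- mean_
      tab[[paste0("sd_", ch)]] <- sqrt(pmax(var_, 0))
    }
  }
  structure(list(labels = labels, table = tab,
                 voxel_size_nm = stack$voxel_size_nm),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d objects, %d labelled voxels\n",
              nrow(x$table), sum(x$table$voxels)))
  invisible(x)
}

#' Number of objects in a ROI set
#' @param rois A `roi_set`.
#' @return Integer count.
#' @export
n_rois <- function(rois) nrow(rois$table)
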