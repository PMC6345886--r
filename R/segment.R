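# The automated 3D quantification workflow: mitochondria segmentation
# (local-threshold strategy), foci segmentation (global-threshold strategy
# with montage normalization), positivity classification, translocation and
# foci statistics, and receptor-intensity normalization.

#' Segmentation configuration with the workflow's standard constants
#'
#' Defaults are the constants of the published workflow: 50 px paraboloid
#' radius, 0.2% contrast saturation, 1.25 px 2D median kernel, (8, 8, 4) px
#' seed window, 2-voxel mitochondrial 3D median, 4 px Bernsen radius, 5 px
#' watershed radius, 1.5-voxel foci 3D median, global foci threshold 96,
#' 300-voxel foci maximum size, 0.01% montage histogram fraction,
#' 0.02072 um^3 (<= 2 voxel) mitochondrial exclusion, positivity mean
#' threshold 5 and the experiment-specific SD threshold table
#' (values 10 / 15 / 20 / 25 / 30).
#'
#' @param ... Named overrides for any field.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(...) {
  cfg <- list(
    paraboloid_radius = 50,
    contrast_saturation = 0.2,
    median2d_radius = 1.25,
    seed_window = c(8, 8, 4),
    mito_median3d_radius = 2,
    bernsen_radius = 4,
    bernsen_contrast_limit = 15,
    watershed_radius = 5,
    foci_median3d_radius = 1.5,
    foci_threshold = 96,
    foci_max_voxels = 300,
    montage_fraction = 0.01,
    mito_min_volume_um3 = 0.02072,
    mito_min_voxels = 2,
    positivity_mean_threshold = 5,
    positivity_sd_thresholds = c(
      # GFP-tagged receptors
      "GFP-OPTN|pentaKO" = 10,
      "GFP-OPTN(F178A)|pentaKO" = 10,
      "GFP-OPTN|pentaKO+mCh-NDP52mut" = 10,
      "GFP-NDP52|pentaKO+mCh-OPTNmut" = 10,
      "GFP-OPTN(F178A)|pentaKO+mCh-NDP52mut" = 15,
      "GFP-NDP52(V136S)|pentaKO+mCh-OPTNmut" = 15,
      "GFP-NDP52|pentaKO" = 25,
      "GFP-NDP52(V136S)|pentaKO" = 25,
      "GFP-NDP52|WT" = 25,
      "GFP-NDP52|hexaKO" = 25,
      "GFP-OPTN|WT" = 30,
      "GFP-OPTN|hexaKO" = 30,
      # mCherry-tagged receptors
      "mCh-OPTN(D474N)|pentaKO+GFP-NDP52" = 30,
      "mCh-OPTN(F178A/D474N)|pentaKO+GFP-NDP52" = 30,
      "mCh-NDP52(C443K)|pentaKO+GFP-OPTN" = 30,
      "mCh-NDP52(V136S/C443K)|pentaKO+GFP-OPTN" = 30,
      # HA-tagged Atg8s
      "HA-LC3B|pentaKO+GFP-OPTN" = 30,
      "HA-LC3C|pentaKO+GFP-NDP52" = 20
    ),
    bit_depth = 8
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "segmentation_config")
}

#' Segment mitochondria with the local-threshold strategy
#'
#' Pipeline per the workflow: per-plane sliding-paraboloid background
#' subtraction, contrast enhancement, per-plane 2D median; seed detection by
#' 3D local maxima; 3D median noise reduction; per-plane Bernsen local
#' thresholding; 3D seeded watershed; exclusion of objects of 2 voxels or
#' fewer (<= 0.02072 um^3). Measurements are taken on the original stack in
#' every channel.
#'
#' @param stack An `image_stack` with voxel-size metadata.
#' @param channel Mitochondria channel name.
#' @param cfg A [segmentation_config()].
#' @return A `roi_set` of retained mitochondrial objects.
#' @export
segment_mitochondria <- function(stack, channel = "mito",
                                 cfg = segmentation_config()) {
  vol <- .stack_channel(stack, channel)
  nz <- dim(vol)[1]
  pre <- vol
  for (z in seq_len(nz)) {
    pre[z, , ] <- subtract_background_paraboloid(pre[z, , ],
                                                 cfg$paraboloid_radius)
  }
  pre <- enhance_contrast(pre, cfg$contrast_saturation, cfg$bit_depth)
  attr(pre, "flat") <- NULL
  for (z in seq_len(nz)) {
    pre[z, , ] <- median_filter_2d(pre[z, , ], cfg$median2d_radius)
  }
  seeds <- detect_seeds(pre, cfg$seed_window)
  smooth <- median_filter_3d(pre, cfg$mito_median3d_radius)
  mask <- array(FALSE, dim = dim(smooth))
  for (z in seq_len(nz)) {
    mask[z, , ] <- bernsen_threshold_2d(smooth[z, , ], cfg$bernsen_radius,
                                        cfg$bernsen_contrast_limit,
                                        low_ref = 2^(cfg$bit_depth - 1))
  }
  labels <- .seeded_watershed_3d(smooth, seeds, mask, cfg$watershed_radius)
  rois <- measure_rois(labels, stack)
  drop_ids <- rois$table$id[rois$table$voxels <= cfg$mito_min_voxels |
                              rois$table$volume_um3 <= cfg$mito_min_volume_um3]
  if (length(drop_ids)) {
    rois$labels[rois$labels %in% drop_ids] <- 0L
    rois$table <- rois$table[!rois$table$id %in% drop_ids, , drop = FALSE]
    rownames(rois$table) <- NULL
  }
  rois
}

#' Linear histogram normalization across an experiment montage
#'
#' Assembles a montage of per-stack maximum-intensity projections, finds the
#' lowest and highest integer intensities whose pixel counts exceed the
#' given fraction of all montage pixels, and linearly rescales every stack's
#' channel between those two values.
#'
#' @param stacks Non-empty list of `image_stack` objects sharing `channel`.
#' @param channel Channel to normalize.
#' @param fraction Histogram fraction in percent (default 0.01).
#' @return List of stacks with the channel rescaled and `normalized = TRUE`.
#' @export
normalize_histograms_montage <- function(stacks, channel = "foci",
                                         fraction = 0.01) {
  if (length(stacks) == 0) stop("at least one image is required")
  mips <- lapply(stacks, function(s) apply(.stack_channel(s, channel), c(2, 3), max))
  montage <- round(unlist(mips))
  counts <- table(montage)
  thr <- length(montage) * fraction / 100
  cand <- as.numeric(names(counts))[counts > thr]
  if (length(cand) == 0) stop("no intensity exceeds the montage fraction")
  new_min <- min(cand)
  new_max <- max(cand)
  if (new_max <= new_min) stop("degenerate montage histogram")
  lapply(stacks, function(s) {
    bd <- s$bit_depth
    v <- .stack_channel(s, channel)
    v <- (v - new_min) / (new_max - new_min) * (2^bd - 1)
    v[v < 0] <- 0
    v[v > 2^bd - 1] <- 2^bd - 1
    s$data[, , , channel] <- v
    s$normalized <- TRUE
    s
  })
}

#' Segment foci with the global-threshold strategy
#'
#' 3D median noise reduction (1.5-voxel footprint), connected components of
#' voxels above the global threshold (96 by default on 8-bit data), and
#' removal of components larger than the 300-voxel maximum size. Stacks
#' should be montage-normalized first; a warning is emitted otherwise and
#' the segmentation proceeds.
#'
#' @param stack An `image_stack`.
#' @param channel Foci channel name.
#' @param cfg A [segmentation_config()].
#' @return A `roi_set` of retained foci.
#' @export
segment_foci <- function(stack, channel = "foci", cfg = segmentation_config()) {
  if (!isTRUE(stack$normalized)) {
    warning("stack is not montage-normalized; proceeding on raw intensities")
  }
  vol <- .stack_channel(stack, channel)
  smooth <- median_filter_3d(vol, cfg$foci_median3d_radius)
  mask <- smooth > cfg$foci_threshold
  labels <- .label_components_3d(mask, 26L)
  rois <- measure_rois(labels, stack)
  drop_ids <- rois$table$id[rois$table$voxels > cfg$foci_max_voxels]
  if (length(drop_ids)) {
    rois$labels[rois$labels %in% drop_ids] <- 0L
    rois$table <- rois$table[!rois$table$id %in% drop_ids, , drop = FALSE]
    rownames(rois$table) <- NULL
  }
  rois
}

#' Classify ROIs as positive for a marker channel
#'
#' An object is positive when its mean intensity in the channel exceeds the
#' mean threshold (5 by default) AND its intensity standard deviation
#' strictly exceeds the experiment-specific SD threshold.
#'
#' @param rois A `roi_set` with measurements for `channel`.
#' @param channel Marker channel name.
#' @param experiment_key Key into the configured SD-threshold table; ignored
#'   when `sd_threshold` is given explicitly.
#' @param sd_threshold Explicit SD threshold (overrides the table).
#' @param mean_threshold Mean-intensity threshold (default from config).
#' @param cfg A [segmentation_config()].
#' @return Logical vector of per-ROI positivity, aligned with `rois$table`.
#' @export
classify_positive <- function(rois, channel, experiment_key = NULL,
                              sd_threshold = NULL,
                              mean_threshold = NULL,
                              cfg = segmentation_config()) {
  if (is.null(mean_threshold)) mean_threshold <- cfg$positivity_mean_threshold
  if (is.null(sd_threshold)) {
    if (is.null(experiment_key) ||
        !experiment_key %in% names(cfg$positivity_sd_thresholds)) {
      stop("unknown experiment key; supply sd_threshold explicitly")
    }
    sd_threshold <- cfg$positivity_sd_thresholds[[experiment_key]]
  }
  mcol <- paste0("mean_", channel)
  scol <- paste0("sd_", channel)
  if (!all(c(mcol, scol) %in% names(rois$table))) {
    stop("no measurements for channel '", channel, "'")
  }
  rois$table[[mcol]] > mean_threshold & rois$table[[scol]] > sd_threshold
}

#' Fraction of mitochondrial volume positive for a marker
#'
#' `100 * sum(volume of positive ROIs) / sum(volume of all retained ROIs)`.
#'
#' @param mito_rois A `roi_set` from [segment_mitochondria()].
#' @param labels Logical per-ROI positivity (from [classify_positive()]).
#' @return Percentage of mitochondrial volume positive.
#' @export
translocation_fraction <- function(mito_rois, labels) {
  if (nrow(mito_rois$table) == 0) stop("empty ROI set: fraction undefined")
  stopifnot(length(labels) == nrow(mito_rois$table))
  100 * sum(mito_rois$table$volume_um3[labels]) / sum(mito_rois$table$volume_um3)
}

#' Per-image foci summary statistics
#'
#' Foci count per cell (cell counts are supplied externally, as in manual
#' counting), mean focus volume and mean intensity in a marker channel.
#'
#' @param foci_rois A `roi_set` from [segment_foci()].
#' @param cells_in_image Number of cells in the image (>= 1).
#' @param channel Optional channel for the mean-intensity summary.
#' @return List with `foci_per_cell`, `mean_volume_um3`,
#'   `mean_intensity` (NA when no foci or no channel given) and `n_foci`.
#' @export
foci_statistics <- function(foci_rois, cells_in_image, channel = NULL) {
  if (cells_in_image < 1) stop("cells_in_image must be >= 1")
  n <- nrow(foci_rois$table)
  list(
    n_foci = n,
    foci_per_cell = n / cells_in_image,
    mean_volume_um3 = if (n > 0) mean(foci_rois$table$volume_um3) else NA_real_,
    mean_intensity = if (n > 0 && !is.null(channel))
      mean(foci_rois$table[[paste0("mean_", channel)]]) else NA_real_
  )
}

#' Receptor-intensity normalization anchors
#'
#' The raw intensities mapped to 0 and 1 for each receptor:
#' OPTN (4.88, 64.28) and NDP52 (15.05, 193.21).
#'
#' @param receptor `"OPTN"` or `"NDP52"`, or `NULL` for the full table.
#' @return Numeric `c(zero, one)` anchors, or the named table.
#' @export
normalization_anchors <- function(receptor = NULL) {
  tab <- list(OPTN = c(zero = 4.88, one = 64.28),
              NDP52 = c(zero = 15.05, one = 193.21))
  if (is.null(receptor)) return(tab)
  if (!receptor %in% names(tab)) stop("unknown receptor: ", receptor)
  tab[[receptor]]
}

#' Normalize a raw receptor intensity to [0, 1]
#'
#' `(raw - anchor0) / (anchor1 - anchor0)`, clipped to `[0, 1]`.
#'
#' @param raw Raw mean intensity (vectorized).
#' @param anchors `c(zero, one)` anchor intensities, e.g. from
#'   [normalization_anchors()].
#' @return Normalized intensity in `[0, 1]`.
#' @export
normalize_receptor_intensity <- function(raw, anchors) {
  a0 <- anchors[[1]]
  a1 <- anchors[[2]]
  if (a1 <= a0) stop("anchor for 1 must exceed anchor for 0")
  pmin(pmax((raw - a0) / (a1 - a0), 0), 1)
}
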