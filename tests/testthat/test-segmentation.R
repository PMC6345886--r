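test_that("segmentation defaults equal the workflow's standard constants", {
  cfg <- segmentation_config()
  expect_identical(cfg$paraboloid_radius, 50)
  expect_identical(cfg$contrast_saturation, 0.2)
  expect_identical(cfg$median2d_radius, 1.25)
  expect_identical(cfg$seed_window, c(8, 8, 4))
  expect_identical(cfg$mito_median3d_radius, 2)
  expect_identical(cfg$bernsen_radius, 4)
  expect_identical(cfg$watershed_radius, 5)
  expect_identical(cfg$foci_median3d_radius, 1.5)
  expect_identical(cfg$foci_threshold, 96)
  expect_identical(cfg$foci_max_voxels, 300)
  expect_identical(cfg$montage_fraction, 0.01)
  expect_identical(cfg$mito_min_volume_um3, 0.02072)
  expect_identical(cfg$mito_min_voxels, 2)
  expect_identical(cfg$positivity_mean_threshold, 5)
  expect_setequal(unique(cfg$positivity_sd_thresholds), c(10, 15, 20, 25, 30))
  expect_identical(segmentation_config(foci_threshold = 120)$foci_threshold, 120)
  expect_error(segmentation_config(not_a_field = 1), "unknown config fields")
})

test_that("mitochondria segmentation recovers separated tubules", {
  gen <- fx_image()
  rois <- segment_mitochondria(gen$stack, "mito")
  n_true <- nrow(gen$truth$objects)
  expect_gte(n_rois(rois), n_true - 1)
  expect_lte(n_rois(rois), n_true + 1)
  # volume bookkeeping: table counts match the label volume
  expect_identical(sum(rois$table$voxels), sum(rois$labels > 0))
  # exclusion filter: nothing at or below 2 voxels survives
  expect_true(all(rois$table$voxels > 2))
  # total segmented volume close to ground truth
  expect_lt(abs(sum(rois$table$voxels) - sum(gen$truth$objects$voxels)) /
              sum(gen$truth$objects$voxels), 0.25)
})

test_that("tiny specks are excluded and empty stacks give empty ROI sets", {
  vol <- array(0, dim = c(10, 64, 64))
  # one genuine tubule-like bar and one 2-voxel speck
  vol[3:7, 28:34, 10:30] <- 180
  vol[5, 50, 50:51] <- 220
  stack <- image_stack(vol, channels = "mito")
  rois <- segment_mitochondria(stack, "mito")
  expect_true(all(rois$table$voxels > 2))
  expect_true(all(rois$labels[5, 50, 50:51] == 0))
  expect_gte(n_rois(rois), 1)

  empty <- image_stack(array(0, dim = c(6, 32, 32)), channels = "mito")
  expect_identical(n_rois(segment_mitochondria(empty, "mito")), 0L)
})

test_that("montage normalization bounds come from the histogram fraction rule", {
  # two flat single-plane stacks with hand-countable histograms
  a <- array(0, dim = c(1, 50, 40))   # 2000 px montage contribution
  a[1, 1:25, ] <- 40                  # 1000 px at 40
  a[1, 26:50, ] <- 10                 # 1000 px at 10
  b <- array(200, dim = c(1, 50, 40)) # 2000 px at 200
  b[1, 1, 1] <- 250                   # a single pixel at 250
  sa <- image_stack(a, channels = "foci")
  sb <- image_stack(b, channels = "foci")
  out <- normalize_histograms_montage(list(sa, sb), "foci", fraction = 0.01)
  # montage = 4000 px; threshold = 0.4 px; 250 occurs once (> 0.4) -> max;
  # 10 occurs 1000 times -> min
  va <- out[[1]]$data[, , , 1]
  expect_equal(min(va), 0)                       # 10 -> 0 (clipped)
  expect_equal(max(va), (40 - 10) / (250 - 10) * 255, tolerance = 1e-10)
  expect_true(out[[1]]$normalized)
  # identical stacks map identically
  out2 <- normalize_histograms_montage(list(sa, sa), "foci")
  expect_identical(out2[[1]]$data, out2[[2]]$data)
  expect_error(normalize_histograms_montage(list(), "foci"), "at least one")
})

test_that("foci below the global threshold or above the size cap are dropped", {
  vol <- array(0, dim = c(10, 48, 48))
  g <- expand.grid(z = 1:10, y = 1:48, x = 1:48)
  spot <- function(cz, cy, cx, amp, sig) {
    amp * exp(-(((g$z - cz) / (sig * 0.5625))^2 + ((g$y - cy) / sig)^2 +
                  ((g$x - cx) / sig)^2) / 2)
  }
  dim_spot <- array(spot(5, 12, 12, 80, 1.5), dim = dim(vol))   # peak < 96
  bright <- array(spot(5, 34, 34, 220, 1.5), dim = dim(vol))    # detectable
  stack <- image_stack(round(dim_spot + bright), channels = "foci",
                       normalized = TRUE)
  rois <- segment_foci(stack, "foci")
  expect_identical(n_rois(rois), 1L)
  # the retained focus sits at the bright location
  expect_gt(rois$labels[5, 34, 34], 0)

  # a 400-voxel supra-threshold blob is discarded, a 250-voxel one kept
  vol2 <- array(0, dim = c(12, 40, 40))
  vol2[1:4, 1:10, 1:10] <- 150    # 400 voxels above threshold
  vol2[7:11, 25:34, 30:34] <- 150 # 250 voxels above threshold
  stack2 <- image_stack(vol2, channels = "foci", normalized = TRUE)
  cfg <- segmentation_config(foci_median3d_radius = 0) # preserve exact counts
  rois2 <- segment_foci(stack2, "foci", cfg)
  expect_identical(n_rois(rois2), 1L)
  expect_identical(rois2$table$voxels, 250L)
})

test_that("raising the foci threshold never increases the detected count", {
  gen <- fx_image()
  norm <- normalize_histograms_montage(list(gen$stack), "foci")[[1]]
  counts <- vapply(c(60, 96, 140, 200), function(thr) {
    n_rois(segment_foci(norm, "foci", segmentation_config(foci_threshold = thr)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("positivity classification follows the strict mean/SD rule", {
  tab <- data.frame(id = 1:3, voxels = c(10, 10, 10), volume_um3 = rep(0.1, 3),
                    mean_gfp = c(6, 4, 6), sd_gfp = c(12, 100, 10))
  rois <- structure(list(labels = NULL, table = tab), class = "roi_set")
  lab <- classify_positive(rois, "gfp", sd_threshold = 10)
  expect_identical(lab, c(TRUE, FALSE, FALSE)) # mean>5 & sd>10, both strict
  # table lookup by experiment key
  lab2 <- classify_positive(rois, "gfp", experiment_key = "GFP-OPTN|pentaKO")
  expect_identical(lab2, lab)
  expect_error(classify_positive(rois, "gfp", experiment_key = "nonsense"),
               "unknown experiment key")
})

test_that("translocation fraction is a volume-weighted percentage", {
  tab <- data.frame(id = 1:2, voxels = c(5, 5), volume_um3 = c(1, 1))
  rois <- structure(list(labels = NULL, table = tab), class = "roi_set")
  expect_equal(translocation_fraction(rois, c(TRUE, TRUE)), 100)
  expect_equal(translocation_fraction(rois, c(TRUE, FALSE)), 50)
  empty <- structure(list(labels = NULL, table = tab[0, ]), class = "roi_set")
  expect_error(translocation_fraction(empty, logical(0)), "empty")
})

test_that("receptor positivity and translocation recover the ground truth", {
  gen <- fx_image()
  rois <- segment_mitochondria(gen$stack, "mito")
  lab <- classify_positive(rois, "receptor", sd_threshold = 10)
  # match segmented objects to ground-truth objects via the label volumes
  truth_pos <- vapply(seq_len(n_rois(rois)), function(i) {
    ids <- gen$truth$labels[rois$labels == rois$table$id[i]]
    ids <- ids[ids > 0]
    if (length(ids) == 0) return(NA)
    gen$truth$objects$positive[as.integer(names(which.max(table(ids))))]
  }, logical(1))
  keep <- !is.na(truth_pos)
  tp <- sum(lab[keep] & truth_pos[keep])
  f1 <- 2 * tp / (2 * tp + sum(lab[keep] & !truth_pos[keep]) +
                    sum(!lab[keep] & truth_pos[keep]))
  expect_gte(f1, 0.95)
  frac <- translocation_fraction(rois, lab)
  expect_lt(abs(frac - gen$truth$positive_volume_fraction), 2)
})

test_that("foci statistics recover counts per cell within tolerance", {
  gen <- fx_image()
  norm <- normalize_histograms_montage(list(gen$stack), "foci")[[1]]
  rois <- segment_foci(norm, "foci")
  truth_n <- sum(gen$truth$foci$supra_voxels > 0)
  expect_lt(abs(n_rois(rois) - truth_n) / truth_n, 0.10 + 1e-9)
  st <- foci_statistics(rois, cells_in_image = gen$truth$n_cells)
  expect_equal(st$foci_per_cell, n_rois(rois) / gen$truth$n_cells)
  expect_error(foci_statistics(rois, 0), ">= 1")
  # trivial arithmetic cases
  tab <- data.frame(id = 1:30, voxels = rep(8L, 30), volume_um3 = rep(0.08, 30))
  r30 <- structure(list(labels = NULL, table = tab), class = "roi_set")
  expect_equal(foci_statistics(r30, 10)$foci_per_cell, 3)
  r0 <- structure(list(labels = NULL, table = tab[0, ]), class = "roi_set")
  s0 <- foci_statistics(r0, 10)
  expect_equal(s0$foci_per_cell, 0)
  expect_true(is.na(s0$mean_volume_um3))
})

test_that("receptor intensity normalization maps the anchors to 0 and 1", {
  nd <- normalization_anchors("NDP52")
  expect_equal(normalize_receptor_intensity(15.05, nd), 0)
  expect_equal(normalize_receptor_intensity(193.21, nd), 1)
  expect_equal(normalize_receptor_intensity((15.05 + 193.21) / 2, nd), 0.5)
  op <- normalization_anchors("OPTN")
  expect_equal(normalize_receptor_intensity(4.88, op), 0)
  expect_equal(normalize_receptor_intensity(64.28, op), 1)
  # clipping
  expect_equal(normalize_receptor_intensity(0, nd), 0)
  expect_equal(normalize_receptor_intensity(1e4, nd), 1)
  expect_error(normalize_receptor_intensity(5, c(10, 10)), "exceed")
})
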