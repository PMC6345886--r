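test_that("paraboloid background subtraction removes flat background", {
  flat <- matrix(37, 64, 64)
  out <- subtract_background_paraboloid(flat, 50)
  expect_true(all(abs(out) <= 1))
})

test_that("paraboloid background subtraction preserves narrow peaks", {
  img <- matrix(20, 101, 101)
  img[51, 51] <- 20 + 180 # delta spike of height 180
  out <- subtract_background_paraboloid(img, 50)
  expect_gt(out[51, 51], 0.95 * 180)
  expect_lt(out[51, 51], 1.05 * 180)
  expect_error(subtract_background_paraboloid(img, 0), "positive")
})

test_that("smooth gradients are treated as background, compact objects are not", {
  # a linear intensity ramp is reproduced by the parabolic opening away from
  # the image border (within the border the opening cannot see the full slope)
  ramp <- matrix(rep(seq(0, 50, length.out = 101), each = 101), 101, 101)
  out <- subtract_background_paraboloid(ramp, 50)
  expect_lt(max(abs(out[, 30:72])), 1e-9)
  # a compact 3 px object is not absorbed into the background
  img2 <- matrix(0, 101, 101)
  img2[50:52, 50:52] <- 100
  bg2 <- mitoamp:::cpp_paraboloid_background(img2, 50)
  expect_lt(max(bg2), 1)
})

test_that("contrast enhancement clips the stated pixel fraction per tail", {
  ramp <- matrix(seq_len(1000), 40, 25) # 1000 distinct intensities
  out <- enhance_contrast(ramp, saturation = 0.2)
  # bounds at the 2nd and 999th ranked pixels (0.1% clipped per tail)
  expect_identical(sum(out == 0), 2L)
  expect_identical(sum(out == 255), 2L)
  rescaled <- (ramp - 2) / (999 - 2) * 255
  expect_equal(out[ramp >= 2 & ramp <= 999], rescaled[ramp >= 2 & ramp <= 999])
})

test_that("zero saturation gives an exact min-max stretch", {
  img <- matrix(c(10, 10, 90, 90), 2, 2)
  out <- enhance_contrast(img, saturation = 0)
  expect_identical(sort(unique(as.numeric(out))), c(0, 255))
})

test_that("degenerate single-valued images are returned unchanged and flagged", {
  img <- matrix(7, 5, 5)
  out <- enhance_contrast(img)
  expect_true(attr(out, "flat"))
  expect_equal(as.numeric(out), rep(7, 25))
})

test_that("seed detection finds one seed per isolated spot", {
  vol <- array(0, dim = c(8, 40, 40))
  g <- expand.grid(z = 1:8, y = 1:40, x = 1:40)
  spot <- function(cz, cy, cx) {
    100 * exp(-(((g$z - cz) / 1)^2 + ((g$y - cy) / 2)^2 + ((g$x - cx) / 2)^2) / 2)
  }
  one <- array(spot(4, 20, 20), dim = dim(vol))
  seeds <- detect_seeds(one, c(8, 8, 4))
  expect_identical(nrow(seeds), 1L)
  expect_identical(unlist(seeds[1, c("z", "y", "x")], use.names = FALSE),
                   c(4L, 20L, 20L))

  two <- array(spot(4, 10, 10) + spot(4, 30, 30), dim = dim(vol))
  seeds2 <- detect_seeds(two, c(8, 8, 4))
  expect_identical(nrow(seeds2), 2L)
})

test_that("Bernsen thresholding separates a bright disc from the field", {
  img <- matrix(10, 64, 64)
  g <- expand.grid(y = 1:64, x = 1:64)
  disc <- (g$y - 32)^2 + (g$x - 32)^2 <= 10^2
  img[cbind(g$y[disc], g$x[disc])] <- 200
  fg <- bernsen_threshold_2d(img, radius = 4, contrast_limit = 15)
  # disc interior foreground, far field background
  inner <- (g$y - 32)^2 + (g$x - 32)^2 <= 7^2
  outer <- (g$y - 32)^2 + (g$x - 32)^2 >= 20^2
  expect_true(all(fg[cbind(g$y[inner], g$x[inner])]))
  expect_false(any(fg[cbind(g$y[outer], g$x[outer])]))
})

test_that("a uniform plane is assigned entirely to one class", {
  img <- matrix(50, 32, 32)
  fg <- bernsen_threshold_2d(img, radius = 4, contrast_limit = 15)
  expect_false(any(fg)) # low contrast, mid-gray not above global mean
})

test_that("median filter footprints have the expected size", {
  # radius 1.25 px -> 5-pixel cross
  expect_identical(nrow(mitoamp:::.disc_offsets_2d(1.25)), 5L)
  # radius 1.5 voxels in 3D -> 19-voxel footprint
  expect_identical(nrow(mitoamp:::.ball_offsets_3d(1.5)), 19L)
  img <- matrix(0, 9, 9)
  img[5, 5] <- 100 # isolated single-pixel impulse is removed
  expect_true(all(median_filter_2d(img, 1.25) == 0))
})
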