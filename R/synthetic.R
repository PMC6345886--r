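# Seed-deterministic synthetic-data generators with ground truth: 3D image
# stacks (tubular mitochondria + punctate foci over uneven background with
# Poisson-Gaussian noise), model time courses, and bivariate log-normal
# cytometry samples.

#' Scene description for synthetic 3D stacks
#'
#' Defaults emulate a conforming confocal field: 180/320 nm voxels, 8-bit,
#' a dozen separated tubular mitochondria, two dozen punctate foci, a smooth
#' uneven background and Poisson shot noise plus Gaussian read noise.
#'
#' @param nz,ny,nx Stack dimensions (z-extent 12 planes = 3.84 um at 320 nm,
#'   above the 2.8 um minimum).
#' @param n_mito Number of tubular mitochondria.
#' @param mito_radius Tube radius (lateral px).
#' @param mito_length Random-walk step count (approximate tube length, px).
#' @param mito_intensity,mito_intensity_sd Tube intensity mean and voxel
#'   jitter (8-bit units).
#' @param positive_fraction Target fraction of mitochondrial volume painted
#'   receptor-positive (0-1).
#' @param receptor_pos_mean,receptor_pos_sd Receptor-channel intensity of
#'   positive objects (high mean, high variance: punctate receptor signal).
#' @param receptor_neg_mean,receptor_neg_sd Receptor intensity of negative
#'   objects.
#' @param n_foci Number of Gaussian foci.
#' @param foci_peak Range of focus peak amplitudes.
#' @param foci_sigma Focus lateral standard deviation (px).
#' @param n_cells Cells in the field (foci are assigned to cells for
#'   per-cell ground-truth counts).
#' @param background_amplitude Amplitude of the smooth polynomial
#'   background.
#' @param read_noise_sd Gaussian read-noise SD.
#' @param poisson Apply Poisson shot noise to the signal.
#' @return An `image_scene` list.
#' @export
image_scene <- function(nz = 12, ny = 96, nx = 96,
                        n_mito = 12, mito_radius = 4, mito_length = 14,
                        mito_intensity = 180, mito_intensity_sd = 4,
                        positive_fraction = 0.3,
                        receptor_pos_mean = 35, receptor_pos_sd = 20,
                        receptor_neg_mean = 2, receptor_neg_sd = 1,
                        n_foci = 24, foci_peak = c(170, 240),
                        foci_sigma = 1.8, n_cells = 8,
                        background_amplitude = 15,
                        read_noise_sd = 2, poisson = TRUE) {
  structure(as.list(environment()), class = "image_scene")
}

.paint_ball_offsets <- function(r_lat, aspect) {
  rz <- max(1, round(r_lat / aspect))
  g <- expand.grid(dz = -rz:rz, dy = -ceiling(r_lat):ceiling(r_lat),
                   dx = -ceiling(r_lat):ceiling(r_lat))
  keep <- (g$dz * aspect)^2 + g$dy^2 + g$dx^2 <= r_lat^2 + 1e-9
  as.matrix(g[keep, ])
}

.paint_cyl_offsets <- function(r_lat, aspect) {
  # disc swept over the axial extent: flat axial faces survive median
  # filtering the way optically-sectioned tubes do
  rz <- max(1, round(r_lat / aspect))
  g <- expand.grid(dz = -rz:rz, dy = -ceiling(r_lat):ceiling(r_lat),
                   dx = -ceiling(r_lat):ceiling(r_lat))
  keep <- g$dy^2 + g$dx^2 <= r_lat^2 + 1e-9
  as.matrix(g[keep, ])
}

.random_walk_tube <- function(scene, occupied, margin) {
  aspect <- 320 / 180
  off <- .paint_cyl_offsets(scene$mito_radius, aspect)
  zmargin <- max(1, round(scene$mito_radius / aspect)) + 1
  for (try in 1:60) {
    pos <- c(
      z = runif(1, 1 + zmargin, scene$nz - zmargin),
      y = runif(1, 1 + margin, scene$ny - margin),
      x = runif(1, 1 + margin, scene$nx - margin)
    )
    dir <- rnorm(3)
    dir[1] <- dir[1] * 0.2 # mostly in-plane tubes
    dir <- dir / sqrt(sum(dir^2))
    path <- matrix(0, nrow = scene$mito_length, ncol = 3)
    ok <- TRUE
    for (i in seq_len(scene$mito_length)) {
      path[i, ] <- pos
      dir <- dir + c(0.05, 0.3, 0.3) * rnorm(3)
      dir[1] <- dir[1] * 0.5 # keep tubes roughly in-plane
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir
      if (pos[1] < 1 + 1 || pos[1] > scene$nz - 1 ||
          pos[2] < 1 + margin / 2 || pos[2] > scene$ny - margin / 2 ||
          pos[3] < 1 + margin / 2 || pos[3] > scene$nx - margin / 2) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    # paint with an axial (centre-bright) and radial falloff, each voxel
    # taking its brightest contribution, so every object has one intensity
    # peak and no flat plateaus
    centre_i <- (scene$mito_length + 1) / 2
    radial <- 1 - 0.25 * (off[, "dy"]^2 + off[, "dx"]^2) / scene$mito_radius^2
    rel <- numeric(0)
    zi <- yi <- xi <- integer(0)
    for (i in seq_len(nrow(path))) {
      centre <- round(path[i, ])
      axial <- 1 - 0.4 * ((i - centre_i) / centre_i)^2
      zi <- c(zi, centre[1] + off[, "dz"])
      yi <- c(yi, centre[2] + off[, "dy"])
      xi <- c(xi, centre[3] + off[, "dx"])
      rel <- c(rel, axial * radial)
    }
    keep <- zi >= 1 & zi <= scene$nz & yi >= 1 & yi <= scene$ny &
      xi >= 1 & xi <= scene$nx
    zi <- zi[keep]; yi <- yi[keep]; xi <- xi[keep]; rel <- rel[keep]
    ord <- order(rel, decreasing = TRUE)
    first <- !duplicated(cbind(zi, yi, xi)[ord, , drop = FALSE])
    sel <- ord[first]
    vox <- cbind(zi[sel], yi[sel], xi[sel], rel[sel])
    # separation check: no painted voxel within 2 px of another object
    sep <- .paint_ball_offsets(2, aspect)
    clash <- FALSE
    for (k in seq_len(nrow(sep))) {
      zz <- pmin(pmax(vox[, 1] + sep[k, "dz"], 1), scene$nz)
      yy <- pmin(pmax(vox[, 2] + sep[k, "dy"], 1), scene$ny)
      xx <- pmin(pmax(vox[, 3] + sep[k, "dx"], 1), scene$nx)
      if (any(occupied[cbind(zz, yy, xx)])) {
        clash <- TRUE
        break
      }
    }
    if (!clash) return(vox)
  }
  NULL
}

#' Generate a synthetic multi-channel 3D stack with ground truth
#'
#' Channels: `mito` (dilated random-walk tubules with a centre-weighted
#' intensity profile), `receptor` (painted per ground-truth positivity) and
#' `foci` (Gaussian spots). A smooth polynomial background and
#' Poisson-Gaussian noise are added to every channel, and intensities are
#' quantized to 8-bit. Regeneration with the same seed is identical.
#'
#' @param scene An [image_scene()].
#' @param seed Integer seed.
#' @return List with `stack` (an `image_stack`) and `truth` (label volume,
#'   per-object table with positivity, per-cell foci assignments,
#'   supra-threshold focus volumes, the scene and the seed).
#' @export
generate_image_stack <- function(scene = image_scene(), seed = 1) {
  max_extent <- scene$mito_length + 2 * scene$mito_radius
  if (max_extent > min(scene$ny, scene$nx) - 4 || scene$mito_radius * 2 + 2 > scene$nz) {
    stop("requested objects are larger than the stack volume")
  }
  .with_seed(seed, {
    dims <- c(scene$nz, scene$ny, scene$nx)
    labels <- array(0L, dim = dims)
    occupied <- array(FALSE, dim = dims)
    mito <- array(0, dim = dims)
    margin <- ceiling(max_extent / 2) + 2
    margin <- min(margin, floor(min(scene$ny, scene$nx) / 3))
    objects <- list()
    for (id in seq_len(scene$n_mito)) {
      vox <- .random_walk_tube(scene, occupied, margin)
      if (is.null(vox)) {
        stop("could not place all mitochondria; scene too crowded")
      }
      idx <- vox[, 1:3, drop = FALSE]
      labels[idx] <- id
      occupied[idx] <- TRUE
      mito[idx] <- scene$mito_intensity * vox[, 4] +
        rnorm(nrow(idx), 0, scene$mito_intensity_sd)
      objects[[id]] <- idx
    }
    voxels <- vapply(objects, nrow, integer(1))
    # mark objects positive until the target volume fraction is reached
    ord <- sample(seq_along(objects))
    target <- scene$positive_fraction * sum(voxels)
    cum <- cumsum(voxels[ord])
    n_pos <- if (target <= 0) 0 else which.min(abs(cum - target))
    positive <- seq_along(objects) %in% ord[seq_len(n_pos)]

    receptor <- array(0, dim = dims)
    for (id in seq_along(objects)) {
      idx <- objects[[id]]
      receptor[idx] <- if (positive[id]) {
        pmax(rnorm(nrow(idx), scene$receptor_pos_mean, scene$receptor_pos_sd), 0)
      } else {
        pmax(rnorm(nrow(idx), scene$receptor_neg_mean, scene$receptor_neg_sd), 0)
      }
    }

    foci <- array(0, dim = dims)
    aspect <- 320 / 180
    sig <- scene$foci_sigma
    sigz <- sig / aspect
    centres <- matrix(numeric(0), ncol = 3)
    foci_tab <- NULL
    for (id in seq_len(scene$n_foci)) {
      placed <- FALSE
      for (try in 1:100) {
        cz <- sample(2:(scene$nz - 1), 1)
        cy <- runif(1, 6, scene$ny - 5)
        cx <- runif(1, 6, scene$nx - 5)
        if (nrow(centres) == 0 ||
            min(sqrt(colSums((t(centres) - c(cz * aspect, cy, cx))^2))) > 8) {
          centres <- rbind(centres, c(cz * aspect, cy, cx))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place all foci; scene too crowded")
      amp <- runif(1, scene$foci_peak[1], scene$foci_peak[2])
      r <- ceiling(4 * sig)
      rz <- ceiling(4 * sigz)
      zr <- max(1, round(cz) - rz):min(scene$nz, round(cz) + rz)
      yr <- max(1, round(cy) - r):min(scene$ny, round(cy) + r)
      xr <- max(1, round(cx) - r):min(scene$nx, round(cx) + r)
      g <- expand.grid(z = zr, y = yr, x = xr)
      val <- amp * exp(-(((g$z - cz) / sigz)^2 + ((g$y - cy) / sig)^2 +
                           ((g$x - cx) / sig)^2) / 2)
      idx <- cbind(g$z, g$y, g$x)
      foci[idx] <- foci[idx] + val
      foci_tab <- rbind(foci_tab, data.frame(
        id = id, z = cz, y = cy, x = cx, amplitude = amp,
        cell = sample.int(scene$n_cells, 1)
      ))
    }

    # smooth uneven background, shared gradient across channels
    yy <- matrix(seq_len(scene$ny) / scene$ny, scene$ny, scene$nx)
    xx <- matrix(rep(seq_len(scene$nx) / scene$nx, each = scene$ny),
                 scene$ny, scene$nx)
    cf <- runif(3)
    bg_plane <- scene$background_amplitude *
      (0.3 + cf[1] * xx + cf[2] * yy + cf[3] * xx * yy) / 2.3
    bg <- aperm(array(rep(bg_plane, scene$nz), c(scene$ny, scene$nx, scene$nz)),
                c(3, 1, 2))

    quantize <- function(signal) {
      v <- signal + bg
      if (scene$poisson) v <- array(rpois(length(v), pmax(v, 0)), dim = dims)
      v <- v + rnorm(length(v), 0, scene$read_noise_sd)
      array(pmin(pmax(round(v), 0), 255), dim = dims)
    }
    data <- array(0, dim = c(dims, 3))
    data[, , , 1] <- quantize(mito)
    data[, , , 2] <- quantize(receptor)
    data[, , , 3] <- quantize(foci)
    stack <- image_stack(data, channels = c("mito", "receptor", "foci"))

    # ground-truth supra-threshold focus volumes: the objects the
    # global-threshold workflow defines, evaluated on the noiseless signal
    # after the configured 3D median
    cfg <- segmentation_config()
    if (!is.null(foci_tab) && nrow(foci_tab) > 0) {
      supra <- median_filter_3d(foci + bg, cfg$foci_median3d_radius) >
        cfg$foci_threshold
      supra_lab <- .label_components_3d(supra, 26L)
      foci_tab$supra_voxels <- vapply(seq_len(nrow(foci_tab)), function(i) {
        lz <- pmin(pmax(round(foci_tab$z[i]), 1), scene$nz)
        ly <- pmin(pmax(round(foci_tab$y[i]), 1), scene$ny)
        lx <- pmin(pmax(round(foci_tab$x[i]), 1), scene$nx)
        l <- supra_lab[lz, ly, lx]
        if (l == 0) 0L else sum(supra_lab == l)
      }, integer(1))
    } else {
      foci_tab <- data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                             x = numeric(0), amplitude = numeric(0),
                             cell = integer(0), supra_voxels = integer(0))
    }

    object_table <- data.frame(
      id = seq_along(objects),
      voxels = voxels,
      volume_um3 = voxels * voxel_volume_um3(stack),
      positive = positive
    )
    truth <- list(
      labels = labels,
      objects = object_table,
      positive_volume_fraction =
        100 * sum(voxels[positive]) / sum(voxels),
      foci = foci_tab,
      per_cell_counts = tabulate(foci_tab$cell, nbins = scene$n_cells),
      n_cells = scene$n_cells,
      scene = scene,
      seed = seed
    )
    list(stack = stack, truth = truth)
  })
}

#' Generate a synthetic model time course with ground truth
#'
#' Simulates the stimulated wild-type protocol, samples the PINK1 dimer,
#' total pS65-Ub and total lipidated Atg8 readouts at the requested times
#' and adds multiplicative Gaussian noise.
#'
#' @param net A `mito_network` (the generating parameters are the ground
#'   truth).
#' @param times Sampling grid (s).
#' @param noise_sd Multiplicative noise fraction (0 = noiseless).
#' @param seed Integer seed.
#' @return List with `observations` (data frame: time, pink1d, ps65ub,
#'   atg8pe) and `truth` (generating parameters and the noiseless table).
#' @export
generate_timecourse <- function(net = build_default_network(),
                                times = seq(0, 7200, by = 600),
                                noise_sd = 0, seed = 1) {
  dt <- min(diff(times))
  sim <- simulate_mitophagy(net, t_end = max(times), dt = dt)
  idx <- match(times, sim$times)
  if (any(is.na(idx))) stop("times must be multiples of the smallest interval")
  clean <- data.frame(
    time = times,
    pink1d = sim$trajectory[idx, "PINK1d"],
    ps65ub = ps65ub_readout(sim$trajectory)[idx],
    atg8pe = sim$atg8pe[idx]
  )
  obs <- clean
  if (noise_sd > 0) {
    obs[-1] <- .with_seed(seed, {
      lapply(clean[-1], function(v) v * (1 + rnorm(length(v), 0, noise_sd)))
    })
  }
  list(observations = obs,
       truth = list(params = net$params, noiseless = clean, seed = seed))
}

#' Generate a synthetic mtKeima cytometry sample with ground truth
#'
#' Mixes two bivariate log-normal populations in the 488-excited x
#' 561-excited plane: a neutral-pH (untreated-like) population and an
#' acidified, 561-shifted population, with GFP and iRFP670 reporter
#' columns.
#'
#' @param n Number of events (default 20000, a standard acquisition).
#' @param positive_fraction Percentage of events drawn from the acidified
#'   population (0-100).
#' @param seed Integer seed.
#' @param neutral_mean,acidic_mean log10 intensity means `c(488, 561)` of
#'   the two populations.
#' @param log_sd log10 intensity SD (both axes).
#' @param correlation Within-population log-intensity correlation.
#' @return List with `sample` (a `facs_sample`) and `truth` (logical
#'   per-event acidified membership, the requested fraction and the seed).
#' @export
generate_facs_sample <- function(n = 20000, positive_fraction = 0,
                                 seed = 1,
                                 neutral_mean = c(3.0, 2.0),
                                 acidic_mean = c(2.4, 3.0),
                                 log_sd = 0.15, correlation = 0.6) {
  if (n < 1) stop("n must be >= 1")
  if (positive_fraction < 0 || positive_fraction > 100) {
    stop("positive_fraction must lie in [0, 100]")
  }
  .with_seed(seed, {
    n_pos <- round(n * positive_fraction / 100)
    sigma <- log_sd^2 * matrix(c(1, correlation, correlation, 1), 2)
    draw <- function(m, k) {
      if (k == 0) return(matrix(numeric(0), ncol = 2))
      MASS::mvrnorm(k, mu = m, Sigma = sigma)
    }
    pts <- rbind(draw(neutral_mean, n - n_pos), draw(acidic_mean, n_pos))
    membership <- rep(c(FALSE, TRUE), c(n - n_pos, n_pos))
    ord <- sample.int(n)
    pts <- pts[ord, , drop = FALSE]
    membership <- membership[ord]
    tab <- data.frame(
      ex488_em695 = 10^pts[, 1],
      ex561_em670 = 10^pts[, 2],
      gfp = rlnorm(n, log(1000), 0.3),
      irfp670 = rlnorm(n, log(800), 0.3)
    )
    list(sample = facs_sample(tab),
         truth = list(acidified = membership,
                      positive_fraction = positive_fraction,
                      seed = seed))
  })
}
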