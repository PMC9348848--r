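#' Simulation configuration for 3D smFISH image stacks
#'
#' Parameters of a synthetic spinning-disk acquisition: a Z-stack with a
#' spot (mRNA) channel, a GFP cell-marker channel and an optional DAPI
#' channel. Cells are rendered as filled ellipses in the GFP channel;
#' diffraction-limited transcripts are isotropic 3D Gaussians placed
#' inside cells over a noisy background.
#'
#' @param seed Integer seed.
#' @param shape_zyx Integer triple (z, y, x) of voxel dimensions.
#' @param n_cells Number of cells (two sister PGCs by default).
#' @param spots_per_cell Spots per cell; a single integer or a length-2
#'   range sampled uniformly.
#' @param spot_sigma_px Spot Gaussian sigma in pixels (> 0).
#' @param spot_amplitude Peak intensity added by one spot.
#' @param background_mean Constant background level.
#' @param noise_sd Gaussian read-noise standard deviation; the ratio
#'   `spot_amplitude / noise_sd` is the SNR.
#' @param cell_radius_px In-plane cell radius in pixels.
#' @param min_spot_sep_px Minimum pairwise distance between spot centres;
#'   default `6 * spot_sigma_px` so spots are individually resolvable.
#' @param dapi Logical; add a DAPI channel (nuclear blob per cell).
#'
#' @return An object of class `image_sim_config`.
#' @export
image_sim_config <- function(seed = 1L,
                             shape_zyx = c(24L, 160L, 160L),
                             n_cells = 2L,
                             spots_per_cell = 15L,
                             spot_sigma_px = 1.5,
                             spot_amplitude = 500,
                             background_mean = 100,
                             noise_sd = 50,
                             cell_radius_px = 30,
                             min_spot_sep_px = 6 * spot_sigma_px,
                             dapi = FALSE) {
  .check(.is_count(seed), "seed must be a single integer")
  .check(length(shape_zyx) == 3 && all(shape_zyx >= 4),
         "shape_zyx must be three dimensions >= 4")
  .check(.is_count(n_cells) && n_cells >= 1, "n_cells must be >= 1")
  .check(length(spots_per_cell) %in% 1:2 && all(spots_per_cell >= 0),
         "spots_per_cell must be an integer or range")
  .check(is.numeric(spot_sigma_px) && spot_sigma_px > 0,
         "spot_sigma_px must be > 0")
  .check(noise_sd > 0 && spot_amplitude / noise_sd > 0,
         "amplitude / noise_sd must define a positive SNR")
  structure(list(seed = as.integer(seed),
                 shape_zyx = as.integer(shape_zyx),
                 n_cells = as.integer(n_cells),
                 spots_per_cell = as.integer(spots_per_cell),
                 spot_sigma_px = spot_sigma_px,
                 spot_amplitude = spot_amplitude,
                 background_mean = background_mean,
                 noise_sd = noise_sd,
                 cell_radius_px = cell_radius_px,
                 min_spot_sep_px = min_spot_sep_px,
                 dapi = isTRUE(dapi)),
            class = "image_sim_config")
}

#' Generate a synthetic multi-channel 3D smFISH stack with ground truth
#'
#' The GFP channel contains `n_cells` bright filled ellipses (constant in
#' Z over the central slices); the spot channel contains isotropic
#' Gaussian spots at the truth coordinates, all inside cell regions, plus
#' constant background and Gaussian noise. Voxels are 16-bit unsigned:
#' values are clipped to \[0, 65535\], never wrapped. Same seed gives a
#' voxel-identical stack.
#'
#' @param config An [image_sim_config()].
#' @return A list with
#'   \describe{
#'     \item{channels}{named list of 3D arrays (z, y, x): `spot`, `gfp`,
#'       and optionally `dapi`.}
#'     \item{truth}{list with `spots` (data.frame `z`, `y`, `x`, `cell`,
#'       1-based voxel coordinates) and `cells` (data.frame `cell`, `cy`,
#'       `cx`, `ry`, `rx`).}
#'   }
#' @export
gen_image <- function(config) {
  .check(inherits(config, "image_sim_config"), "config must be an image_sim_config")
  cfg <- config
  dz <- cfg$shape_zyx[1]; dy <- cfg$shape_zyx[2]; dx <- cfg$shape_zyx[3]
  .with_seed(cfg$seed, {
    cells <- .place_cells(cfg$n_cells, dy, dx, cfg$cell_radius_px)

    # GFP channel: filled ellipses, bright over central z-slices
    yy <- matrix(seq_len(dy), dy, dx)
    xx <- matrix(seq_len(dx), dy, dx, byrow = TRUE)
    gfp2d <- matrix(0, dy, dx)
    for (i in seq_len(nrow(cells))) {
      inside <- ((yy - cells$cy[i]) / cells$ry[i])^2 +
        ((xx - cells$cx[i]) / cells$rx[i])^2 <= 1
      gfp2d[inside] <- 1
    }
    gfp <- array(0, c(dz, dy, dx))
    zc <- max(2L, ceiling(dz * 0.2)):min(dz - 1L, floor(dz * 0.8))
    for (z in zc) gfp[z, , ] <- gfp2d * 3000
    gfp <- gfp + cfg$background_mean +
      array(rnorm(dz * dy * dx, 0, cfg$noise_sd), c(dz, dy, dx))

    # spot centres: rejection-sampled inside cells, min pairwise separation
    n_spots <- if (length(cfg$spots_per_cell) == 2) {
      sample(cfg$spots_per_cell[1]:cfg$spots_per_cell[2], cfg$n_cells,
             replace = TRUE)
    } else rep(cfg$spots_per_cell, cfg$n_cells)
    spots <- .place_spots(cells, n_spots, dz, zc, cfg$min_spot_sep_px)

    spot_ch <- array(cfg$background_mean, c(dz, dy, dx))
    if (nrow(spots) > 0) {
      spot_ch <- spot_ch +
        .render_spots(spots, c(dz, dy, dx), cfg$spot_sigma_px,
                      cfg$spot_amplitude)
    }
    spot_ch <- spot_ch + array(rnorm(dz * dy * dx, 0, cfg$noise_sd),
                               c(dz, dy, dx))

    channels <- list(spot = .clip16(spot_ch), gfp = .clip16(gfp))
    if (cfg$dapi) {
      dapi <- array(cfg$background_mean, c(dz, dy, dx))
      for (i in seq_len(nrow(cells))) {
        nuc <- ((yy - cells$cy[i])^2 + (xx - cells$cx[i])^2) <=
          (cfg$cell_radius_px / 2)^2
        for (z in zc) dapi[z, , ][nuc] <- dapi[z, , ][nuc] + 2000
      }
      channels$dapi <- .clip16(dapi + array(rnorm(dz * dy * dx, 0, cfg$noise_sd),
                                            c(dz, dy, dx)))
    }
    list(channels = channels,
         truth = list(spots = spots, cells = cells))
  })
}

# 16-bit unsigned: round to integer grey levels, clip (never wrap)
.clip16 <- function(a) { a <- round(a); a[a < 0] <- 0; a[a > 65535] <- 65535; a }

# non-overlapping ellipse centres on the (y, x) plane; cells are kept a
# few blur-sigmas apart so the segmentation mask can resolve them
.place_cells <- function(n_cells, dy, dx, r, gap = 24) {
  .check(2.5 * r < min(dy, dx),
         "cell_radius_px too large for the field of view")
  for (restart in 1:500) {
    cy <- cx <- numeric(n_cells)
    placed <- 0L
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (try in 1:200) {
        y <- runif(1, r + 2, dy - r - 2)
        x <- runif(1, r + 2, dx - r - 2)
        if (i == 1 || all(sqrt((cy[seq_len(i - 1)] - y)^2 +
                                 (cx[seq_len(i - 1)] - x)^2) > 2 * r + gap)) {
          cy[i] <- y; cx[i] <- x; ok <- TRUE; break
        }
      }
      if (!ok) break
      placed <- i
    }
    if (placed == n_cells) {
      return(data.frame(cell = seq_len(n_cells), cy = cy, cx = cx,
                        ry = r * runif(n_cells, 0.85, 1),
                        rx = r * runif(n_cells, 0.85, 1)))
    }
  }
  stop("cells cannot be placed without overlap at requested size",
       call. = FALSE)
}

# spot centres inside cell ellipses (with margin), global min separation
.place_spots <- function(cells, n_spots, dz, z_range, min_sep) {
  all_y <- all_x <- all_z <- numeric(0)
  all_cell <- integer(0)
  for (i in seq_len(nrow(cells))) {
    placed <- 0L
    tries <- 0L
    max_tries <- 20000L
    while (placed < n_spots[i]) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(
          "spots cannot be placed at requested density (cell %d: %d of %d placed)",
          i, placed, n_spots[i]), call. = FALSE)
      }
      y <- cells$cy[i] + runif(1, -1, 1) * (cells$ry[i] - 3)
      x <- cells$cx[i] + runif(1, -1, 1) * (cells$rx[i] - 3)
      if (((y - cells$cy[i]) / (cells$ry[i] - 3))^2 +
            ((x - cells$cx[i]) / (cells$rx[i] - 3))^2 > 1) next
      z <- runif(1, min(z_range) + 1, max(z_range) - 1)
      if (length(all_y) > 0 &&
            any((all_y - y)^2 + (all_x - x)^2 + (all_z - z)^2 < min_sep^2)) next
      all_y <- c(all_y, y); all_x <- c(all_x, x); all_z <- c(all_z, z)
      all_cell <- c(all_cell, i)
      placed <- placed + 1L
    }
  }
  data.frame(z = round(all_z), y = round(all_y), x = round(all_x),
             cell = all_cell)
}

# sum of isotropic 3D Gaussians, rendered on a local support of 4 sigma
.render_spots <- function(spots, dim_zyx, sigma, amplitude) {
  out <- array(0, dim_zyx)
  w <- ceiling(4 * sigma)
  for (i in seq_len(nrow(spots))) {
    zr <- max(1, spots$z[i] - w):min(dim_zyx[1], spots$z[i] + w)
    yr <- max(1, spots$y[i] - w):min(dim_zyx[2], spots$y[i] + w)
    xr <- max(1, spots$x[i] - w):min(dim_zyx[3], spots$x[i] + w)
    gz <- exp(-((zr - spots$z[i])^2) / (2 * sigma^2))
    gy <- exp(-((yr - spots$y[i])^2) / (2 * sigma^2))
    gx <- exp(-((xr - spots$x[i])^2) / (2 * sigma^2))
    out[zr, yr, xr] <- out[zr, yr, xr] + amplitude * outer(gz, outer(gy, gx))
  }
  out
}
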