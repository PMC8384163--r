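#' @title Digital phantom generation
#' @description Forward models that emulate the calibration objects and
#'   volunteer studies the pipeline is validated against: gadolinium-doped
#'   T1 vials, an ice-water diffusion vial, a macromolecular (MT) vial, an
#'   oil (fat) vial, an agar-embedded pancreas-shaped object, smooth B1
#'   transmit inhomogeneity, Rician magnitude noise, and measure-level
#'   multisite volunteer studies with known random-effect structure.
#' @name digital-phantom
NULL

# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# stream afterwards.  All phantom randomness flows through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.finite(seed), seed == round(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic substream seed derived from a master seed, kept within the
# 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude MRI noise: each voxel value v becomes
#' `sqrt((v + g1 * sigma)^2 + (g2 * sigma)^2)` with independent standard
#' normal g1, g2 — the magnitude of a complex Gaussian perturbation.  At high
#' signal-to-noise this approaches additive Gaussian noise; at low signal it
#' produces the characteristic positive (Rayleigh) floor, which is why
#' diffusion signals at strong weighting are simulated this way rather than
#' with Gaussian noise.  Invalid (`NA`) voxels stay invalid.
#'
#' @param volume an `image_volume`.
#' @param sigma noise scale in signal units, `>= 0`.
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return an `image_volume` with the same grid.
#' @export
add_rician_noise <- function(volume, sigma, seed = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  if (sigma == 0) return(volume)
  d <- volume$data
  ok <- !is.na(d)
  n <- sum(ok)
  with_seed(seed, {
    g1 <- stats::rnorm(n)
    g2 <- stats::rnorm(n)
    d[ok] <- sqrt((d[ok] + g1 * sigma)^2 + (g2 * sigma)^2)
  })
  volume$data <- d
  volume
}

#' Simulate a smooth B1 transmit-inhomogeneity field
#'
#' Produces the flip-angle correction factor f: a smooth, slowly varying
#' field near 1 built from a handful of low-frequency cosine components with
#' seed-determined directions, wavelengths and phases.  The component
#' coefficients depend only on the seed, never on the grid, so the same seed
#' evaluated on two grids yields samples of the same underlying analytic
#' field — coarse-grid simulation followed by regridding therefore agrees
#' with direct fine-grid evaluation up to interpolation error.  Deviation
#' from 1 is bounded by `amplitude` by construction.
#'
#' @param grid a `grid_spec`.
#' @param amplitude maximal fractional deviation from 1, in `[0, 0.5]`.
#'   Default 0.1, a typical abdominal transmit-field deviation at 3 T.
#' @param length_scale characteristic wavelength scale in mm (default 300,
#'   i.e. variation on the scale of the field of view).
#' @param seed integer seed.
#' @param n_components number of cosine components.
#' @return an `image_volume` of f on `grid`.
#' @export
simulate_b1_field <- function(grid, amplitude = 0.1, length_scale = 300,
                              seed = 1L, n_components = 6L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(amplitude) || amplitude < 0 || amplitude > 0.5)
    stop("`amplitude` must lie in [0, 0.5]")
  check_spacing(length_scale, "length_scale", 1L)
  if (amplitude == 0)
    return(image_volume(array(1, dim = grid$shape), grid$in_plane_spacing,
                        grid$slice_spacing, grid$origin, "b1 field",
                        space = grid$space))
  co <- with_seed(seed, {
    u <- matrix(stats::rnorm(3L * n_components), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    list(amp = stats::runif(n_components, 0.3, 1),
         dir = u,
         wavelength = stats::runif(n_components, 1, 2.5) * length_scale,
         phase = stats::runif(n_components, 0, 2 * pi))
  })
  ax <- grid_axes(grid)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  raw <- array(0, dim = grid$shape)
  X <- rep(ax$x, times = ny)                      # in-plane coordinate planes
  Y <- rep(ax$y, each = nx)
  for (m in seq_len(n_components)) {
    ph_xy <- 2 * pi * (co$dir[m, 1] * X + co$dir[m, 2] * Y) / co$wavelength[m]
    for (k in seq_len(nz)) {
      ph <- ph_xy + 2 * pi * co$dir[m, 3] * ax$z[k] / co$wavelength[m] +
        co$phase[m]
      raw[, , k] <- raw[, , k] + co$amp[m] * cos(ph)
    }
  }
  field <- 1 + amplitude * raw / sum(co$amp)   # |raw| <= sum(amp) pointwise
  image_volume(field, grid$in_plane_spacing, grid$slice_spacing, grid$origin,
               "b1 field", space = grid$space)
}

#' Default phantom grid
#'
#' The acquisition geometry used for parametric mapping in the harmonized
#' protocol: 128 x 104 matrix at 3 x 3 mm in plane, 24 slices of 4 mm.
#' @export
default_phantom_grid <- function() grid_spec(c(128L, 104L, 24L), c(3, 3), 4)

#' Digital vial phantom with calibrated truths
#'
#' Builds the digital analogue of the shipped calibration object: four
#' gadolinium-doped gelatin vials with prescribed T1 values of 500, 1000,
#' 1250 and 1500 ms; an ice-water vial with a diffusion coefficient of
#' 0.0011 mm^2/s; a crosslinked-protein vial with a configurable
#' magnetization transfer ratio; and an oil vial with a configurable fat
#' fraction, all cylinders embedded in a water background.  Ground-truth
#' parameter maps, the region labels, and the acquisition/noise parameters
#' are returned together as a `phantom_spec` ready for
#' [simulate_acquisition()].
#'
#' @param grid a `grid_spec`; must be large enough for seven vial
#'   cross-sections (default [default_phantom_grid()]).
#' @param mtr_truth true MTR of the protein vial (dimensionless, default
#'   0.35).
#' @param fat_fraction_truth true fat fraction of the oil vial (default
#'   0.95).
#' @param vial_radius_mm cylinder radius in mm (default 14, a 50 ml tube).
#' @param s0 proton-density/gain scale of the simulated scanner (signal
#'   units, default 1000).
#' @param noise_sigma Rician noise scale in signal units (default 0,
#'   noiseless).
#' @param b1_amplitude fractional B1 deviation passed to
#'   [simulate_b1_field()]; 0 gives a homogeneous transmit field.
#' @param seed master seed for the phantom's stochastic components.
#' @return a `phantom_spec`: list with `grid`, `truth` (named
#'   `parametric_map`s: `t1_ms`, `adc_mm2_s`, `mtr`, `fat_fraction`),
#'   `s0_map`, `b1_field`, `labels` (integer region volume), `vials`
#'   (data.frame of label, name, parameter, truth), `noise_sigma`, `seed`.
#' @export
make_vial_phantom_truth <- function(grid = default_phantom_grid(),
                                    mtr_truth = 0.35,
                                    fat_fraction_truth = 0.95,
                                    vial_radius_mm = 14,
                                    s0 = 1000, noise_sigma = 0,
                                    b1_amplitude = 0, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  stopifnot(mtr_truth >= 0, mtr_truth <= 1,
            fat_fraction_truth >= 0, fat_fraction_truth <= 1)
  ax <- grid_axes(grid)
  fov <- c(diff(range(ax$x)), diff(range(ax$y)))
  # vial centers: 4 T1 vials in one row, ice/MT/fat in a second row
  r <- vial_radius_mm
  gapx <- fov[1] / 5; gapy <- fov[2] / 3
  if (gapx < 2.2 * r || gapy < 2.2 * r)
    stop("grid too small to fit seven vials of radius ", r, " mm")
  cx1 <- min(ax$x) + gapx * (1:4); cy1 <- min(ax$y) + gapy
  cx2 <- min(ax$x) + gapx * c(1.5, 2.5, 3.5); cy2 <- min(ax$y) + 2 * gapy
  centers <- rbind(cbind(cx1, cy1), cbind(cx2, cy2))
  vials <- data.frame(
    label = 1:7,
    name = c("t1_vial_1", "t1_vial_2", "t1_vial_3", "t1_vial_4",
             "ice_water", "mt_vial", "fat_vial"),
    parameter = c(rep("t1_ms", 4), "adc_mm2_s", "mtr", "fat_fraction"),
    truth = c(500, 1000, 1250, 1500, 0.0011, mtr_truth, fat_fraction_truth),
    stringsAsFactors = FALSE)

  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  X <- rep(ax$x, times = ny); Y <- rep(ax$y, each = nx)
  plane <- integer(nx * ny)
  for (v in 1:7) {
    in_vial <- (X - centers[v, 1])^2 + (Y - centers[v, 2])^2 <= r^2
    if (any(plane[in_vial] != 0L))
      stop("vial geometry overlap; reduce `vial_radius_mm`")
    plane[in_vial] <- v
  }
  k_in <- seq(2L, max(2L, nz - 1L))    # vials span all but the end slices
  labels <- array(0L, dim = grid$shape)
  for (k in k_in) labels[, , k] <- plane

  # background: room-temperature water (long T1, free diffusion, no MT, no fat)
  t1 <- array(2500, dim = grid$shape)
  adc <- array(2.0e-3, dim = grid$shape)
  mtr <- array(0, dim = grid$shape)
  ff <- array(0, dim = grid$shape)
  for (v in 1:7) {
    reg <- labels == v
    switch(vials$parameter[v],
           t1_ms = { t1[reg] <- vials$truth[v] },
           adc_mm2_s = { adc[reg] <- vials$truth[v]; t1[reg] <- 1800 },
           mtr = { mtr[reg] <- vials$truth[v]; t1[reg] <- 900 },
           fat_fraction = { ff[reg] <- vials$truth[v]; t1[reg] <- 350 })
  }
  mk <- function(a, kind, units) parametric_map(
    image_volume(a, grid$in_plane_spacing, grid$slice_spacing, grid$origin,
                 paste("truth", kind), space = grid$space),
    kind = kind, units = units)
  b1 <- simulate_b1_field(grid, amplitude = b1_amplitude,
                          seed = derive_seed(seed, 1L))
  structure(list(
    grid = grid,
    truth = list(t1_ms = mk(t1, "T1", "ms"),
                 adc_mm2_s = mk(adc, "ADC", "mm^2/s"),
                 mtr = mk(mtr, "MTR", ""),
                 fat_fraction = mk(ff, "fat_fraction", "")),
    s0_map = image_volume(array(s0, dim = grid$shape), grid$in_plane_spacing,
                          grid$slice_spacing, grid$origin, "S0",
                          space = grid$space),
    b1_field = b1,
    labels = labels,
    vials = vials,
    noise_sigma = noise_sigma,
    seed = seed), class = "phantom_spec")
}

#' Synthetic pancreas-shaped object with matched contours
#'
#' Generates a stylized pancreas: a connected, curved, tapered tube swept
#' along a smooth in-plane C-curve across at least 10 axial slices, with
#' elliptical cross-sections that shrink linearly from head to tail.  The
#' per-slice ellipse boundaries are returned as a `contour_stack` (the
#' digital stand-in for radiologist tracings) and rasterized onto `grid` to
#' give the mask.  In-plane semi-axes are iteratively rescaled so that the
#' voxelized mask volume lands within 2% of `volume_ml`.
#'
#' @param grid a `grid_spec` (default [default_phantom_grid()]).
#' @param volume_ml requested organ volume in ml, within `[30, 150]`
#'   (default 89, the reference volume of the study's printed organ
#'   phantom).
#' @param n_slices number of contoured slices (>= 10, default 14 — about
#'   5.6 cm of cranio-caudal extent at 4 mm spacing).
#' @param seed integer seed jittering the curvature and orientation.
#' @return list with `mask` (binary `image_volume`), `contours`
#'   (`contour_stack`), and `volume_ml` (voxel-count volume actually
#'   achieved).
#' @export
make_pancreas_truth <- function(grid = default_phantom_grid(), volume_ml = 89,
                                n_slices = 14L, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (volume_ml < 30 || volume_ml > 150)
    stop("`volume_ml` must lie in [30, 150] ml")
  if (n_slices < 10L) stop("a pancreas spans at least 10 slices")
  if (grid$shape[3] < n_slices + 2L)
    stop("grid has too few slices for the requested organ extent")
  ax <- grid_axes(grid)
  cx0 <- mean(range(ax$x)); cy0 <- mean(range(ax$y))
  jit <- with_seed(seed, stats::runif(3, -1, 1))
  k0 <- max(2L, (grid$shape[3] - n_slices) %/% 2L)
  t <- seq(0, 1, length.out = n_slices)
  # C-shaped in-plane centerline, gently drifting with slice
  theta <- (-0.5 + 1.55 * t + 0.12 * jit[1]) * pi
  R <- 42 + 4 * jit[2]
  cx <- cx0 + R * cos(theta) * 0.8
  cy <- cy0 + R * sin(theta) * 0.55
  taper <- seq(1.25, 0.55, length.out = n_slices)       # head large, tail small
  a0 <- 16; b0 <- 11                                    # mm semi-axes, pre-scale
  psi <- theta + pi / 2 + 0.2 * jit[3]                  # ellipse follows curve
  phi <- seq(0, 2 * pi, length.out = 65L)[-65L]         # 64-gon boundary

  build <- function(s) {
    cts <- lapply(seq_len(n_slices), function(i) {
      aa <- s * a0 * taper[i]; bb <- s * b0 * taper[i]
      vx <- cx[i] + aa * cos(phi) * cos(psi[i]) - bb * sin(phi) * sin(psi[i])
      vy <- cy[i] + aa * cos(phi) * sin(psi[i]) + bb * sin(phi) * cos(psi[i])
      list(slice = k0 + i - 1L, vertices = cbind(vx, vy))
    })
    contour_stack(cts, grid$slice_spacing)
  }
  # analytic initial scale, then fixed-point correction on the voxel count
  area_poly <- sum(pi * a0 * b0 * taper^2)
  s <- sqrt(volume_ml * 1000 / (area_poly * grid$slice_spacing))
  mask <- NULL; vol <- NA_real_; cts <- NULL
  for (it in 1:8) {
    cts <- build(s)
    mask <- rasterize_contours(cts, grid)
    vol <- sum(mask$data) * voxel_volume_mm3(grid) / 1000
    if (abs(vol - volume_ml) / volume_ml < 0.015) break
    s <- s * sqrt(volume_ml / vol)
  }
  if (abs(vol - volume_ml) / volume_ml > 0.02)
    stop("could not voxelize requested volume within 2% on this grid; ",
         "achieved ", signif(vol, 4), " ml")
  rng <- range(ax$x[apply(mask$data > 0, 1, any)])
  if (rng[1] <= min(ax$x) || rng[2] >= max(ax$x))
    stop("organ shape does not fit inside the grid")
  list(mask = mask, contours = cts, volume_ml = vol)
}

#' Simulate an acquisition series from a phantom
#'
#' Forward-models the three quantitative acquisitions on a digital phantom:
#' \describe{
#'   \item{`vfa`}{spoiled-gradient-echo signals
#'     `S = S0 * sin(f*a) * (1 - E) / (1 - E * cos(f*a))`, `E = exp(-TR/T1)`,
#'     at each prescribed flip angle `a`, with the true flip-angle
#'     correction factor f taken from the phantom's B1 field.}
#'   \item{`dwi`}{monoexponential diffusion decay
#'     `SI(b) = S0 * exp(-ADC * b)` at each b-value.}
#'   \item{`mt`}{a saturation pair `SI_on = SI_off * (1 - MTR)`.}
#' }
#' Echo-time decay is neglected throughout (TE assumed much shorter than
#' T2*).  Rician noise of scale `noise_sigma` is applied to every frame with
#' frame-specific substreams derived from `seed`.
#'
#' @param spec a `phantom_spec`.
#' @param protocol `"vfa"`, `"dwi"` or `"mt"`.
#' @param flip_angles_deg prescribed flip angles for `vfa` (default
#'   `c(4, 8, 12, 16, 20)` degrees).
#' @param tr_ms repetition time for `vfa` (default 4.6 ms).
#' @param b_values diffusion weightings for `dwi` (default
#'   `c(0, 50, 200, 800)` s/mm^2).
#' @param noise_sigma Rician scale; defaults to `spec$noise_sigma`.
#' @param seed master seed for the noise; defaults to `spec$seed`.
#' @return a `vfa_series`, `dwi_series` or `mt_pair`.
#' @export
simulate_acquisition <- function(spec, protocol = c("vfa", "dwi", "mt"),
                                 flip_angles_deg = c(4, 8, 12, 16, 20),
                                 tr_ms = 4.6,
                                 b_values = c(0, 50, 200, 800),
                                 noise_sigma = spec$noise_sigma,
                                 seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  protocol <- match.arg(protocol)
  g <- spec$grid
  vol <- function(a, lab) image_volume(a, g$in_plane_spacing, g$slice_spacing,
                                       g$origin, lab, space = g$space)
  noisy <- function(v, k) add_rician_noise(v, noise_sigma, derive_seed(seed, k))
  s0 <- spec$s0_map$data
  if (protocol == "vfa") {
    t1 <- spec$truth$t1_ms$volume$data
    f <- spec$b1_field$data
    E <- exp(-tr_ms / t1)
    frames <- lapply(seq_along(flip_angles_deg), function(i) {
      a <- flip_angles_deg[i] * pi / 180
      s <- s0 * sin(f * a) * (1 - E) / (1 - E * cos(f * a))
      noisy(vol(s, sprintf("vfa %g deg", flip_angles_deg[i])), 100L + i)
    })
    vfa_series(flip_angles_deg, frames, tr_ms)
  } else if (protocol == "dwi") {
    adc <- spec$truth$adc_mm2_s$volume$data
    frames <- lapply(seq_along(b_values), function(i) {
      s <- s0 * exp(-adc * b_values[i])
      noisy(vol(s, sprintf("dwi b=%g", b_values[i])), 200L + i)
    })
    dwi_series(b_values, frames)
  } else {
    m <- spec$truth$mtr$volume$data
    off <- noisy(vol(s0, "mt off"), 301L)
    on <- noisy(vol(s0 * (1 - m), "mt on"), 302L)
    mt_pair(off, on)
  }
}

#' Site effect for simulated multisite studies
#'
#' Emulates residual hardware/software differences between scanners: a
#' multiplicative signal gain, a multiplicative perturbation of the
#' flip-angle correction factor, and per-measure additive biases applied at
#' the measure level in volunteer simulations.
#'
#' @param gain_factor multiplicative signal scale (> 0).
#' @param b1_scale multiplicative perturbation of the transmit field (> 0).
#' @param additive_bias named numeric vector of per-measure offsets.
#' @export
site_effect <- function(gain_factor = 1, b1_scale = 1,
                        additive_bias = numeric(0)) {
  stopifnot(gain_factor > 0, b1_scale > 0, is.numeric(additive_bias))
  structure(list(gain_factor = gain_factor, b1_scale = b1_scale,
                 additive_bias = additive_bias), class = "site_effect")
}

#' Multisite volunteer study design
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_sites number of scanning sites (>= 2).
#' @param measure_means named numeric vector of per-measure population means.
#' @param subject_sd named per-measure between-subject SD (same names).
#' @param site_sd named per-measure within-subject between-site SD.
#' @param seed integer seed.
#' @export
study_design <- function(n_subjects, n_sites, measure_means,
                         subject_sd, site_sd, seed = 1L) {
  stopifnot(n_subjects >= 2, n_sites >= 2,
            is.numeric(measure_means), length(names(measure_means)) > 0)
  subject_sd <- subject_sd[names(measure_means)]
  site_sd <- site_sd[names(measure_means)]
  if (any(is.na(subject_sd)) || any(is.na(site_sd)))
    stop("`subject_sd` and `site_sd` must be named for every measure")
  if (any(subject_sd < 0) || any(site_sd < 0))
    stop("standard deviations must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sites = as.integer(n_sites),
                 measure_means = measure_means,
                 subject_sd = subject_sd, site_sd = site_sd,
                 seed = as.integer(seed)), class = "study_design")
}

#' Simulate a multisite volunteer study at the measure level
#'
#' Draws, for each measure m, subject i and site j,
#' `value = mu_m + a_i + e_ij + bias_jm` with
#' `a_i ~ N(0, subject_sd_m^2)` (a stable subject trait) and
#' `e_ij ~ N(0, site_sd_m^2)` (scan-to-scan/between-site error) — the random
#' -effects structure in which between-subject variation exceeds
#' between-site variation whenever `subject_sd > site_sd`.  Operating at the
#' measure level (rather than synthesizing abdominal images per scan)
#' matches what the reproducibility statistics consume.
#'
#' @param design a `study_design`.
#' @param site_effects optional list of `n_sites` [site_effect()] objects
#'   supplying additive per-measure biases.
#' @return list with `table` (a [measure_table()] data.frame) and `truth`
#'   (the generating means, SDs, and per-subject random effects), for
#'   parameter-recovery checks.
#' @export
simulate_multisite_study <- function(design, site_effects = NULL) {
  stopifnot(inherits(design, "study_design"))
  ns <- design$n_subjects; nk <- design$n_sites
  if (!is.null(site_effects) && length(site_effects) != nk)
    stop("`site_effects` must have one entry per site (", nk, ")")
  measures <- names(design$measure_means)
  rows <- vector("list", length(measures))
  effects <- list()
  with_seed(design$seed, {
    for (mi in seq_along(measures)) {
      m <- measures[mi]
      a <- stats::rnorm(ns, 0, design$subject_sd[[m]])
      e <- matrix(stats::rnorm(ns * nk, 0, design$site_sd[[m]]), ns, nk)
      bias <- vapply(seq_len(nk), function(j) {
        if (is.null(site_effects)) 0
        else {
          b <- site_effects[[j]]$additive_bias
          if (m %in% names(b)) b[[m]] else 0
        }
      }, numeric(1))
      val <- design$measure_means[[m]] + outer(a, rep(1, nk)) + e +
        matrix(bias, ns, nk, byrow = TRUE)
      rows[[mi]] <- data.frame(
        subject = rep(sprintf("S%03d", seq_len(ns)), nk),
        site = rep(sprintf("site%02d", seq_len(nk)), each = ns),
        measure = m,
        value = as.vector(val),
        stringsAsFactors = FALSE)
      effects[[m]] <- list(subject_effects = a, residuals = e)
    }
  })
  list(table = measure_table(do.call(rbind, rows)),
       truth = list(measure_means = design$measure_means,
                    subject_sd = design$subject_sd,
                    site_sd = design$site_sd,
                    effects = effects))
}
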