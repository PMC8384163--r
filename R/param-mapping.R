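#' Parametric map
#'
#' An [image_volume()] carrying the estimate of one quantitative parameter
#' per voxel, its kind and units, an optional companion field (the S0 gain
#' map of a T1 fit), and fit diagnostics (censoring counts, reason codes).
#'
#' @param volume an `image_volume` of parameter values; invalid voxels `NA`.
#' @param kind one of `"ADC"`, `"T1"`, `"MTR"`, `"fat_fraction"`.
#' @param units unit string (`"mm^2/s"`, `"ms"`, `""`).
#' @param aux optional companion `image_volume` (e.g. S0).
#' @param diagnostics named list of fit diagnostics.
#' @export
parametric_map <- function(volume, kind, units = "", aux = NULL,
                           diagnostics = list()) {
  stopifnot(inherits(volume, "image_volume"))
  kind <- match.arg(kind, c("ADC", "T1", "MTR", "fat_fraction"))
  structure(list(volume = volume, kind = kind, units = units, aux = aux,
                 diagnostics = diagnostics), class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s [%s]\n", x$kind, x$units))
  print(x$volume)
  if (length(x$diagnostics))
    cat("  diagnostics:", paste(names(x$diagnostics), unlist(x$diagnostics),
                                sep = "=", collapse = ", "), "\n")
  invisible(x)
}

check_shared_grid <- function(vols, what) {
  g <- grid_of(vols[[1]])
  for (v in vols[-1])
    if (!same_grid(g, v)) stop(what, " frames must share one grid")
  invisible(g)
}

#' Diffusion-weighted series
#'
#' @param b_values numeric vector of unique, non-negative diffusion
#'   weightings (s/mm^2); frames are stored sorted by ascending b.
#' @param volumes list of `image_volume`s, one per b-value, on one grid.
#' @export
dwi_series <- function(b_values, volumes) {
  stopifnot(is.numeric(b_values), length(b_values) >= 2,
            all(b_values >= 0), !anyDuplicated(b_values),
            length(volumes) == length(b_values))
  check_shared_grid(volumes, "DWI")
  o <- order(b_values)
  structure(list(b_values = b_values[o], volumes = volumes[o]),
            class = "dwi_series")
}

#' Variable-flip-angle spoiled-gradient-echo series
#'
#' @param flip_angles_deg prescribed flip angles in degrees, at least 2
#'   distinct values in (0, 90).
#' @param volumes list of `image_volume`s, one per angle, on one grid.
#' @param tr_ms repetition time in ms (> 0).
#' @export
vfa_series <- function(flip_angles_deg, volumes, tr_ms) {
  stopifnot(is.numeric(flip_angles_deg),
            length(unique(flip_angles_deg)) >= 2,
            all(flip_angles_deg > 0), all(flip_angles_deg < 90),
            length(volumes) == length(flip_angles_deg),
            is.numeric(tr_ms), tr_ms > 0)
  check_shared_grid(volumes, "VFA")
  o <- order(flip_angles_deg)
  structure(list(flip_angles_deg = flip_angles_deg[o], volumes = volumes[o],
                 tr_ms = tr_ms), class = "vfa_series")
}

#' Flip-angle correction factor map
#'
#' @param volume `image_volume` of the dimensionless correction factor f
#'   (actual over prescribed flip angle); non-positive values are flagged
#'   invalid.
#' @export
b1_map <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  bad <- !is.na(volume$data) & volume$data <= 0
  if (any(bad)) volume$data[bad] <- NA_real_
  structure(list(volume = volume), class = "b1_map")
}

#' Magnetization-transfer image pair
#'
#' @param mt_off,mt_on `image_volume`s acquired without/with the MT
#'   saturation pre-pulse, on the same grid.
#' @export
mt_pair <- function(mt_off, mt_on) {
  check_shared_grid(list(mt_off, mt_on), "MT")
  structure(list(mt_off = mt_off, mt_on = mt_on), class = "mt_pair")
}

#' Two-point ADC map
#'
#' Computes the apparent diffusion coefficient per voxel from two frames of
#' a diffusion series via the exact two-point solution of the
#' monoexponential decay model
#' `SI(b_high) = SI(b_low) * exp(-ADC * (b_high - b_low))`:
#' `ADC = log(SI(b_low) / SI(b_high)) / (b_high - b_low)`.
#' The harmonized protocol uses b 200 and 800 s/mm^2; the perfusion-
#' sensitive non-standardized variant is obtained with `b_low = 0`.
#' Voxels with non-positive or invalid signal at either b-value are flagged
#' invalid, as are voxels with a negative estimate (counted in the
#' diagnostics, not clamped into the map).
#'
#' @param series a [dwi_series()].
#' @param b_low,b_high the two b-values to use (defaults 200 and 800); both
#'   must be present in the series.
#' @return a `parametric_map` of kind `"ADC"` in mm^2/s, with diagnostics
#'   `n_nonpositive_signal` and `n_negative_adc`.
#' @export
fit_adc <- function(series, b_low = 200, b_high = 800) {
  stopifnot(inherits(series, "dwi_series"))
  if (b_high <= b_low) stop("`b_high` must exceed `b_low`")
  pick <- function(b) {
    i <- which(abs(series$b_values - b) < 1e-9)
    if (length(i) != 1L)
      stop("b-value ", b, " not in series (available: ",
           paste(series$b_values, collapse = ", "), ")")
    series$volumes[[i]]
  }
  lo <- pick(b_low); hi <- pick(b_high)
  s_lo <- lo$data; s_hi <- hi$data
  nonpos <- (!is.na(s_lo) & s_lo <= 0) | (!is.na(s_hi) & s_hi <= 0)
  adc <- log(s_lo / s_hi) / (b_high - b_low)
  adc[nonpos] <- NA_real_
  neg <- !is.na(adc) & adc < 0
  adc[neg] <- NA_real_
  vol <- image_volume(adc, lo$in_plane_spacing, lo$slice_spacing, lo$origin,
                      sprintf("ADC map (b %g/%g)", b_low, b_high),
                      space = lo$space)
  parametric_map(vol, "ADC", "mm^2/s",
                 diagnostics = list(b_low = b_low, b_high = b_high,
                                    n_nonpositive_signal = sum(nonpos),
                                    n_negative_adc = sum(neg)))
}

# Spoiled-gradient-echo steady-state signal.
spgr_signal <- function(s0, t1_ms, alpha_rad, tr_ms, f = 1) {
  E <- exp(-tr_ms / t1_ms)
  s0 * sin(f * alpha_rad) * (1 - E) / (1 - E * cos(f * alpha_rad))
}

#' B1-corrected variable-flip-angle T1 map
#'
#' Estimates T1 and the gain/proton-density constant S0 at every voxel by
#' nonlinear least squares on the spoiled-gradient-echo signal model
#' `S(a) = S0 * sin(f*a) * (1 - E) / (1 - E * cos(f*a))`, `E = exp(-TR/T1)`,
#' where a is the prescribed flip angle and f the voxel's flip-angle
#' correction factor from the B1 map (`f = 1` everywhere when `b1` is
#' `NULL`, the non-standardized variant in which transmit-field correction
#' is omitted).  The fit is initialized from the linearized form (the
#' regression of `S/sin(f*a)` on `S/tan(f*a)`, whose slope is E) and
#' refined by a damped, vectorized Gauss-Newton iteration in (S0, E); the
#' linear estimate is exact on noiseless data, so refinement matters only
#' under noise.  T1 is constrained to (0, 10000] ms; voxels with fewer than
#' two valid frames, a non-physical linearized slope, a boundary-pinned
#' estimate, or no convergence are flagged invalid with a reason count in
#' the diagnostics.
#'
#' If the B1 map lives on a coarser grid (transmit-field maps typically use
#' 8 mm slices) regrid it first with [regrid_volume()].
#'
#' @param series a [vfa_series()].
#' @param b1 a [b1_map()] on the series grid, or `NULL` for no correction.
#' @param t1_max_ms upper T1 bound in ms (default 10000).
#' @param tol relative parameter tolerance for convergence (default 1e-8).
#' @param max_iter maximum Gauss-Newton iterations (default 200).
#' @return a `parametric_map` of kind `"T1"` in ms with the fitted S0 as
#'   `aux` and censoring diagnostics.
#' @export
fit_t1_vfa <- function(series, b1 = NULL, t1_max_ms = 10000,
                       tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(series, "vfa_series"))
  g <- grid_of(series$volumes[[1]])
  nvox <- prod(g$shape)
  nfr <- length(series$flip_angles_deg)
  alpha <- series$flip_angles_deg * pi / 180
  tr <- series$tr_ms

  if (is.null(b1)) {
    f <- rep(1, nvox)
  } else {
    stopifnot(inherits(b1, "b1_map"))
    if (!same_grid(g, b1$volume))
      stop("B1 map grid differs from the series grid; regrid it first")
    f <- as.vector(b1$volume$data)
  }

  S <- matrix(NA_real_, nvox, nfr)
  for (i in seq_len(nfr)) S[, i] <- as.vector(series$volumes[[i]]$data)
  sinfa <- sin(outer(f, alpha))      # nvox x nfr
  cosfa <- cos(outer(f, alpha))
  valid <- is.finite(S) & is.finite(sinfa) & sinfa > 0
  nvalid <- rowSums(valid)
  usable <- nvalid >= 2L & is.finite(f)

  # --- linearized (DESPOT1-style) initialization: y = S/sin, x = S/tan
  Sv <- ifelse(valid, S, 0)
  y <- ifelse(valid, Sv / sinfa, 0)
  x <- ifelse(valid, Sv * cosfa / sinfa, 0)
  n <- pmax(nvalid, 1L)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  den <- sxx - sx * sx / n
  slope <- ifelse(den > 0, (sxy - sx * sy / n) / den, NA_real_)
  intercept <- (sy - slope * sx) / n

  E_hi <- exp(-tr / t1_max_ms)
  E <- pmin(pmax(slope, 1e-8), E_hi)
  s0 <- intercept / (1 - E)
  bad_init <- !usable | !is.finite(E) | !is.finite(s0) | s0 <= 0
  E[bad_init] <- NA_real_; s0[bad_init] <- NA_real_

  # --- damped Gauss-Newton refinement in (s0, E), vectorized over voxels
  live <- which(!bad_init)
  if (length(live)) {
    sse_of <- function(s0v, Ev, rows) {
      m <- (s0v * (1 - Ev)) * sinfa[rows, , drop = FALSE] /
        (1 - Ev * cosfa[rows, , drop = FALSE])
      r <- (S[rows, , drop = FALSE] - m)
      r[!valid[rows, , drop = FALSE]] <- 0
      rowSums(r * r)
    }
    sse <- sse_of(s0[live], E[live], live)
    active <- rep(TRUE, length(live))
    for (it in seq_len(max_iter)) {
      rows <- live[active]
      if (!length(rows)) break
      s0a <- s0[rows]; Ea <- E[rows]
      sf <- sinfa[rows, , drop = FALSE]; cf <- cosfa[rows, , drop = FALSE]
      vd <- valid[rows, , drop = FALSE]
      denom <- 1 - Ea * cf
      m <- (s0a * (1 - Ea)) * sf / denom
      r <- S[rows, , drop = FALSE] - m
      r[!vd] <- 0
      j1 <- m / s0a                              # dm/dS0
      j2 <- s0a * sf * (cf - 1) / (denom * denom)  # dm/dE
      j1[!vd] <- 0; j2[!vd] <- 0
      a11 <- rowSums(j1 * j1); a12 <- rowSums(j1 * j2); a22 <- rowSums(j2 * j2)
      g1 <- rowSums(j1 * r); g2 <- rowSums(j2 * r)
      det <- a11 * a22 - a12 * a12
      det[det <= 0 | !is.finite(det)] <- NA_real_
      d1 <- (a22 * g1 - a12 * g2) / det
      d2 <- (a11 * g2 - a12 * g1) / det
      d1[is.na(d1)] <- 0; d2[is.na(d2)] <- 0
      # backtracking: halve until SSE does not increase
      step <- rep(1, length(rows))
      sse_old <- sse[active]
      for (bt in 1:12) {
        s0n <- s0a + step * d1
        En <- pmin(pmax(Ea + step * d2, 1e-8), E_hi)
        s0n <- pmax(s0n, 1e-12)
        sse_new <- sse_of(s0n, En, rows)
        worse <- sse_new > sse_old * (1 + 1e-12)
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      moved <- abs(s0n - s0a) > tol * pmax(abs(s0a), 1e-12) |
               abs(En - Ea) > tol * pmax(Ea, 1e-12)
      s0[rows] <- s0n; E[rows] <- En
      sse[active] <- sse_new
      active[active] <- moved
      if (!any(active)) break
    }
  }

  t1 <- -tr / log(E)
  pinned <- !is.na(E) & (E >= E_hi - 1e-12 | E <= 1e-8 + 1e-12)
  t1[pinned] <- NA_real_
  out_of_range <- !is.na(t1) & (t1 <= 0 | t1 > t1_max_ms)
  t1[out_of_range] <- NA_real_
  s0[is.na(t1)] <- NA_real_
  if (all(is.na(t1))) stop("T1 fit produced no valid voxel (empty result)")

  vol <- image_volume(array(t1, g$shape), g$in_plane_spacing, g$slice_spacing,
                      g$origin,
                      if (is.null(b1)) "T1 map (no B1 correction)"
                      else "T1 map (B1 corrected)",
                      space = g$space)
  aux <- image_volume(array(s0, g$shape), g$in_plane_spacing, g$slice_spacing,
                      g$origin, "S0 map", space = g$space)
  parametric_map(vol, "T1", "ms", aux = aux,
                 diagnostics = list(
                   b1_corrected = !is.null(b1),
                   n_too_few_frames = sum(!usable),
                   n_bad_initialization = sum(bad_init & usable),
                   n_boundary_pinned = sum(pinned),
                   n_out_of_range = sum(out_of_range)))
}

#' Magnetization transfer ratio map
#'
#' `MTR = (SI_off - SI_on) / SI_off` per voxel.  Voxels with non-positive or
#' invalid `SI_off` are flagged invalid; noisy estimates outside `[0, 1]`
#' are kept in the map but counted in the diagnostics.
#'
#' @param pair an [mt_pair()].
#' @return a `parametric_map` of kind `"MTR"` (dimensionless).
#' @export
compute_mtr <- function(pair) {
  stopifnot(inherits(pair, "mt_pair"))
  off <- pair$mt_off$data; on <- pair$mt_on$data
  bad <- is.na(off) | off <= 0 | is.na(on)
  mtr <- (off - on) / off
  mtr[bad] <- NA_real_
  out <- !is.na(mtr) & (mtr < 0 | mtr > 1)
  g <- pair$mt_off
  vol <- image_volume(mtr, g$in_plane_spacing, g$slice_spacing, g$origin,
                      "MTR map", space = g$space)
  parametric_map(vol, "MTR", "",
                 diagnostics = list(n_invalid_off = sum(bad),
                                    n_outside_unit_interval = sum(out)))
}
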