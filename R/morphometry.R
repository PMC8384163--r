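#' Area and perimeter of a closed planar polygon
#'
#' Area by the shoelace formula (absolute value, so vertex orientation is
#' irrelevant) and perimeter as the closed polyline length.  Degenerate
#' (collinear / zero-area) polygons are not an error: they return area 0
#' with `degenerate = TRUE` and a still-meaningful perimeter.
#'
#' @param vertices n x 2 numeric matrix of vertices in mm, first vertex not
#'   repeated; at least 3 rows.
#' @return list with `area_mm2`, `perimeter_mm`, `degenerate`.
#' @export
polygon_geometry <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 3)
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perim <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  list(area_mm2 = area, perimeter_mm = perim, degenerate = area == 0)
}

#' Pancreas volume from slice contours
#'
#' Volume = (sum of per-slice contour areas) x slice distance, converted
#' from mm^3 to ml — the slice-summation rule used for manual organ
#' tracings.
#'
#' @param stack a non-empty [contour_stack()].
#' @return volume in ml.
#' @export
pancreas_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  if (length(stack$contours) == 0) stop("empty contour stack")
  areas <- vapply(stack$contours,
                  function(ct) polygon_geometry(ct$vertices)$area_mm2,
                  numeric(1))
  sum(areas) * stack$frame_spacing / 1000
}

#' Pancreas volume index
#'
#' Organ volume normalized by body weight, ml/kg — removes the correlation
#' between body size and pancreas size when comparing individuals.
#'
#' @param volume_ml pancreas volume in ml.
#' @param weight_kg body weight in kg (> 0).
#' @return PVI in ml/kg.
#' @export
pancreas_volume_index <- function(volume_ml, weight_kg) {
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop("`weight_kg` must be positive")
  volume_ml / weight_kg
}

#' Surface-area-to-volume ratio from slice contours
#'
#' Surface area is approximated as (sum of per-slice perimeters) x slice
#' distance — the open-tube construction, with no end caps — and divided by
#' the slice-summation volume.  Returned in 1/mm with the unit recorded in
#' an attribute; multiply by 10 for 1/cm.
#'
#' @param stack a non-empty [contour_stack()].
#' @return ratio in 1/mm (attribute `units`).
#' @export
surface_area_to_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  if (length(stack$contours) == 0) stop("empty contour stack")
  geo <- lapply(stack$contours, function(ct) polygon_geometry(ct$vertices))
  vol_mm3 <- sum(vapply(geo, `[[`, numeric(1), "area_mm2")) * stack$frame_spacing
  if (vol_mm3 <= 0) stop("degenerate structure: zero volume")
  surf_mm2 <- sum(vapply(geo, `[[`, numeric(1), "perimeter_mm")) *
    stack$frame_spacing
  structure(surf_mm2 / vol_mm3, units = "1/mm")
}

#' Whole-structure ROI mean on a parametric map
#'
#' Rasterizes the contours at the map's own grid (the re-gridding of traced
#' outlines to each map's resolution) and averages the map over valid
#' in-mask voxels.  Invalid (censored) voxels are excluded from the mean and
#' counted.
#'
#' @param map a [parametric_map()].
#' @param stack a [contour_stack()].
#' @return list with `mean`, `n_voxels` (in mask), `n_censored` (in mask but
#'   invalid).
#' @export
roi_mean_on_map <- function(map, stack) {
  stopifnot(inherits(map, "parametric_map"))
  mask <- rasterize_contours(stack, grid_of(map$volume))
  inroi <- mask$data > 0
  n <- sum(inroi)
  if (n == 0) stop("empty ROI: no voxel center falls inside the contours")
  vals <- map$volume$data[inroi]
  ncens <- sum(is.na(vals))
  if (ncens == n) stop("empty ROI: all in-mask voxels are invalid")
  list(mean = mean(vals, na.rm = TRUE), n_voxels = n, n_censored = ncens)
}

#' Circular single-slice ROI mean
#'
#' Places a circle of the given area at `center` on one slice (the hepatic
#' fat-fraction convention: a 4 cm^2 circle on the right hepatic lobe,
#' placed by the analyst to avoid vessels) and averages the map over voxels
#' whose centers fall inside it.
#'
#' @param map a [parametric_map()].
#' @param center length-3: x mm, y mm, slice index (1-based).
#' @param area_cm2 circle area in cm^2 (default 4).
#' @return list with `mean`, `n_voxels`, `n_censored`, `radius_mm`.
#' @export
circular_roi_mean <- function(map, center, area_cm2 = 4) {
  stopifnot(inherits(map, "parametric_map"), length(center) == 3)
  g <- grid_of(map$volume)
  slice <- as.integer(center[3])
  if (slice < 1 || slice > g$shape[3]) stop("slice index out of range")
  radius <- sqrt(area_cm2 * 100 / pi)
  ax <- grid_axes(g)
  if (center[1] - radius < min(ax$x) || center[1] + radius > max(ax$x) ||
      center[2] - radius < min(ax$y) || center[2] + radius > max(ax$y))
    stop("circular ROI extends beyond the image")
  px <- rep(ax$x, times = g$shape[2])
  py <- rep(ax$y, each = g$shape[1])
  inroi <- (px - center[1])^2 + (py - center[2])^2 <= radius^2
  vals <- map$volume$data[, , slice][inroi]
  n <- sum(inroi)
  ncens <- sum(is.na(vals))
  if (n == 0 || ncens == n) stop("empty circular ROI")
  list(mean = mean(vals, na.rm = TRUE), n_voxels = n, n_censored = ncens,
       radius_mm = radius)
}

#' All pancreas measures for one scan
#'
#' Convenience wrapper computing the per-scan measure set from one set of
#' contours, the available parametric maps, the subject's weight, and an
#' optional hepatic ROI placement: volume, PVI, surface-to-volume ratio (in
#' 1/cm, the conventional reporting unit), and the ROI means of every map
#' supplied.
#'
#' @param contours a [contour_stack()].
#' @param maps named list of `parametric_map`s; recognised names `adc`,
#'   `t1`, `mtr`, `fat_fraction`.
#' @param weight_kg body weight (for PVI); `NA` to skip.
#' @param hepatic list(`map =` parametric_map, `center =` c(x, y, slice)) or
#'   `NULL`.
#' @return named numeric vector of measures (missing ones absent).
#' @export
compute_scan_measures <- function(contours, maps = list(), weight_kg = NA,
                                  hepatic = NULL) {
  vol <- pancreas_volume(contours)
  out <- c(volume = vol,
           surface_to_volume = 10 * as.numeric(surface_area_to_volume(contours)))
  if (is.finite(weight_kg))
    out["pvi"] <- pancreas_volume_index(vol, weight_kg)
  roi_names <- c(adc = "adc", t1 = "t1", mtr = "mtr",
                 fat_fraction = "panc_fat_fraction")
  for (nm in names(maps)) {
    key <- if (nm %in% names(roi_names)) roi_names[[nm]] else nm
    out[key] <- roi_mean_on_map(maps[[nm]], contours)$mean
  }
  if (!is.null(hepatic))
    out["hep_fat_fraction"] <- circular_roi_mean(hepatic$map, hepatic$center)$mean
  out
}
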