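test_that("polygon geometry: shoelace area and closed perimeter", {
  sq <- square_contour(10)$vertices
  g <- polygon_geometry(sq)
  expect_equal(g$area_mm2, 100)
  expect_equal(g$perimeter_mm, 40)
  expect_false(g$degenerate)
  # orientation invariance
  g_cw <- polygon_geometry(sq[4:1, ])
  expect_equal(g_cw$area_mm2, 100)
  expect_equal(g_cw$perimeter_mm, 40)
  # regular 64-gon approximates its circumscribing circle
  phi <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- polygon_geometry(cbind(10 * cos(phi), 10 * sin(phi)))
  expect_equal(circ$area_mm2, pi * 100, tolerance = 0.005)
  expect_equal(circ$perimeter_mm, 2 * pi * 10, tolerance = 0.005)
  # collinear polygon: degenerate but not an error
  line <- polygon_geometry(cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_true(line$degenerate)
  expect_equal(line$area_mm2, 0)
  expect_gt(line$perimeter_mm, 0)
})

test_that("slice-summation volume and its linearity in spacing", {
  st <- square_stack(10, slices = 1:5, frame_spacing = 4)
  expect_equal(pancreas_volume(st), 5 * 100 * 4 / 1000)   # 2.0 ml
  st8 <- square_stack(10, slices = 1:5, frame_spacing = 8)
  expect_equal(pancreas_volume(st8), 2 * pancreas_volume(st))
  expect_error(pancreas_volume(contour_stack(list(), 4)), "empty")
})

test_that("contour volume of the synthetic pancreas matches voxel counting", {
  p <- make_pancreas_truth(default_phantom_grid(), volume_ml = 89, seed = 2)
  vox_ml <- sum(p$mask$data) * voxel_volume_mm3(p$mask) / 1000
  expect_equal(pancreas_volume(p$contours), vox_ml, tolerance = 0.02)
})

test_that("PVI is volume over weight", {
  # weight back-solved from a published volume/PVI pair
  expect_equal(pancreas_volume_index(81.297, 74.845), 1.0862,
               tolerance = 1e-4)
  expect_equal(pancreas_volume_index(0, 70), 0)
  expect_equal(pancreas_volume_index(80, 100),
               pancreas_volume_index(80, 50) / 2)
  expect_error(pancreas_volume_index(80, 0), "positive")
})

test_that("surface-to-volume uses the open-tube construction and scales as 1/s", {
  st <- square_stack(10, slices = 1:5, frame_spacing = 4)
  expect_equal(as.numeric(surface_area_to_volume(st)), 0.4)   # 40/100 per mm
  st2 <- square_stack(20, slices = 1:5, frame_spacing = 4)    # scaled by 2
  expect_equal(as.numeric(surface_area_to_volume(st2)), 0.2)
  # equal volume, thinner tube: higher ratio
  thin <- square_stack(5, slices = 1:20, frame_spacing = 4)
  fat <- square_stack(10, slices = 1:5, frame_spacing = 4)
  expect_equal(pancreas_volume(thin), pancreas_volume(fat))
  expect_gt(as.numeric(surface_area_to_volume(thin)),
            as.numeric(surface_area_to_volume(fat)))
})

test_that("ROI mean averages valid in-mask voxels and reports censoring", {
  g <- grid_spec(c(20, 20, 3), c(3, 3), 4)
  arr <- array(5, dim = g$shape)
  map <- parametric_map(image_volume(arr, c(3, 3), 4), "T1", "ms")
  st <- square_stack(30, 28.5, 28.5, slices = 2L)
  r <- roi_mean_on_map(map, st)
  expect_equal(r$mean, 5)
  expect_equal(r$n_voxels, 100)
  expect_equal(r$n_censored, 0)
  # half the ROI at 1, half at 3 -> 2; censored voxels excluded
  arr2 <- array(1, dim = g$shape); arr2[11:20, , ] <- 3
  arr2[10, 10, 2] <- NA
  map2 <- parametric_map(image_volume(arr2, c(3, 3), 4), "T1", "ms")
  r2 <- roi_mean_on_map(map2, st)
  expect_equal(r2$n_censored, 1)
  expect_equal(r2$mean, (50 * 3 + 49 * 1) / 99)
  far <- square_stack(3, 100, 100, slices = 3L)
  expect_error(roi_mean_on_map(map, far), "empty ROI")
})

test_that("measures are invariant under joint in-plane translation", {
  p <- make_pancreas_truth(default_phantom_grid(), volume_ml = 60, seed = 8)
  shift <- c(7.5, -4.5)
  moved <- contour_stack(lapply(p$contours$contours, function(ct)
    list(slice = ct$slice,
         vertices = sweep(ct$vertices, 2, shift, `+`))),
    p$contours$frame_spacing)
  expect_equal(pancreas_volume(moved), pancreas_volume(p$contours))
  expect_equal(as.numeric(surface_area_to_volume(moved)),
               as.numeric(surface_area_to_volume(p$contours)))
  g <- default_phantom_grid()
  gm <- grid_spec(g$shape, g$in_plane_spacing, g$slice_spacing,
                  origin = g$origin + c(shift, 0))
  arr <- array(rep(seq_len(g$shape[3]), each = prod(g$shape[1:2])), g$shape)
  map0 <- parametric_map(image_volume(arr, g$in_plane_spacing,
                                      g$slice_spacing, g$origin), "T1", "ms")
  map1 <- parametric_map(image_volume(arr, g$in_plane_spacing,
                                      g$slice_spacing, gm$origin), "T1", "ms")
  expect_equal(roi_mean_on_map(map1, moved), roi_mean_on_map(map0, p$contours))
})

test_that("4 cm^2 circular ROI has radius 11.28 mm and near-nominal coverage", {
  g <- grid_spec(c(100, 100, 3), c(1.4, 1.4), 4)
  arr <- array(2.5, dim = g$shape)
  map <- parametric_map(image_volume(arr, c(1.4, 1.4), 4), "fat_fraction")
  r <- circular_roi_mean(map, c(70.7, 70.7, 2), area_cm2 = 4)
  expect_equal(r$radius_mm, sqrt(400 / pi), tolerance = 1e-6)
  expect_equal(r$radius_mm, 11.28, tolerance = 1e-3)
  expect_equal(r$mean, 2.5)
  expect_lt(abs(r$n_voxels * 1.4^2 - 400) / 400, 0.03)
  expect_error(circular_roi_mean(map, c(3, 3, 2)), "beyond")
})

test_that("per-scan measure set assembles volume, PVI, s/v and ROI means", {
  g <- grid_spec(c(20, 20, 6), c(3, 3), 4)
  st <- square_stack(30, 28.5, 28.5, slices = 2:4)
  mk <- function(v, kind) parametric_map(
    image_volume(array(v, g$shape), c(3, 3), 4), kind)
  out <- compute_scan_measures(
    st, maps = list(adc = mk(1.2e-3, "ADC"), t1 = mk(950, "T1")),
    weight_kg = 75,
    hepatic = list(map = mk(0.04, "fat_fraction"), center = c(28.5, 28.5, 5)))
  expect_equal(unname(out["volume"]), 3 * 900 * 4 / 1000)
  expect_equal(unname(out["pvi"]), out[["volume"]] / 75)
  expect_equal(unname(out["surface_to_volume"]), 10 * 120 / 900)
  expect_equal(unname(out["adc"]), 1.2e-3)
  expect_equal(unname(out["t1"]), 950)
  expect_equal(unname(out["hep_fat_fraction"]), 0.04)
})
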