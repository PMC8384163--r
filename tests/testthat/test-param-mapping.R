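make_dwi <- function(values_by_b, shape = c(3, 3, 2)) {
  b <- as.numeric(names(values_by_b))
  dwi_series(b, lapply(values_by_b, function(v)
    image_volume(array(v, shape), c(3, 3), 4)))
}

test_that("two-point ADC solves the monoexponential exactly", {
  s <- make_dwi(list(`200` = 500, `800` = 500))
  expect_equal(unique(as.vector(fit_adc(s)$volume$data)), 0)
  s2 <- make_dwi(list(`200` = 1000, `800` = 1000 * exp(-0.6)))
  expect_equal(unique(as.vector(fit_adc(s2)$volume$data)), 1e-3)
  expect_error(fit_adc(s2, b_low = 0), "not in series")
  expect_error(fit_adc(s2, 800, 200), "exceed")
})

test_that("ADC is invariant to signal gain and censors bad voxels without clamping", {
  g <- small_grid()
  spec <- make_vial_phantom_truth(g)
  spec$truth$adc_mm2_s$volume$data[] <- 1.4e-3
  dwi <- simulate_acquisition(spec, "dwi")
  m1 <- fit_adc(dwi)
  expect_equal(unique(as.vector(m1$volume$data)), 1.4e-3, tolerance = 1e-12)
  for (k in c(0.5, 10)) {
    scaled <- dwi_series(dwi$b_values, lapply(dwi$volumes, function(v) {
      v$data <- v$data * k; v
    }))
    expect_equal(fit_adc(scaled)$volume$data, m1$volume$data,
                 tolerance = 1e-12)
  }
  # negative estimates (signal grows with b) are censored and counted
  bad <- make_dwi(list(`200` = 100, `800` = 150))
  mb <- fit_adc(bad)
  expect_true(all(is.na(mb$volume$data)))
  expect_equal(mb$diagnostics$n_negative_adc, 18)
  z <- make_dwi(list(`200` = 0, `800` = 10))
  expect_equal(fit_adc(z)$diagnostics$n_nonpositive_signal, 18)
})

test_that("noiseless VFA fit recovers T1 and S0 essentially exactly", {
  angles <- c(4, 8, 12, 16, 20); tr <- 4.6
  sig <- spgr_oracle(1000, 1000, angles, tr)
  series <- vfa_series(angles, lapply(sig, function(s)
    image_volume(array(s, c(3, 3, 2)), c(3, 3), 4)), tr)
  fit <- fit_t1_vfa(series)
  expect_equal(unique(as.vector(fit$volume$data)), 1000, tolerance = 1e-4)
  expect_equal(unique(as.vector(fit$aux$data)), 1000, tolerance = 1e-4)
})

test_that("all four calibration vial T1 values are recovered through the forward model", {
  spec <- make_vial_phantom_truth(small_grid())
  fit <- fit_t1_vfa(simulate_acquisition(spec, "vfa"),
                    b1 = b1_map(spec$b1_field))
  for (v in 1:4) {
    truth <- spec$vials$truth[v]
    est <- fit$volume$data[spec$labels == v]
    expect_equal(max(abs(est - truth) / truth), 0, tolerance = 1e-6)
  }
})

test_that("T1 estimates are gain invariant (S0 absorbs the scanner scale)", {
  spec <- make_vial_phantom_truth(small_grid())
  vfa <- simulate_acquisition(spec, "vfa")
  ref <- fit_t1_vfa(vfa)
  for (k in c(0.5, 2, 10)) {
    scaled <- vfa_series(vfa$flip_angles_deg, lapply(vfa$volumes, function(v) {
      v$data <- v$data * k; v
    }), vfa$tr_ms)
    fk <- fit_t1_vfa(scaled)
    expect_equal(fk$volume$data, ref$volume$data, tolerance = 1e-8)
    expect_equal(fk$aux$data, ref$aux$data * k, tolerance = 1e-6)
  }
})

test_that("nonlinear fit agrees with a dense brute-force grid oracle", {
  set.seed(31)
  angles <- c(4, 8, 12, 16, 20); tr <- 4.6
  n <- 100
  t1_true <- runif(n, 300, 3000)
  s0_true <- runif(n, 500, 2000)
  f_true <- runif(n, 0.9, 1.1)
  S <- sapply(angles, function(a) spgr_oracle(s0_true, t1_true, a, tr, f_true))
  vols <- lapply(seq_along(angles), function(i)
    image_volume(array(S[, i], c(n, 1, 1)), c(3, 3), 4))
  fmap <- b1_map(image_volume(array(f_true, c(n, 1, 1)), c(3, 3), 4))
  fit <- fit_t1_vfa(vfa_series(angles, vols, tr), b1 = fmap)
  est <- as.vector(fit$volume$data)
  oracle <- vapply(seq_len(n), function(i)
    t1_grid_oracle(S[i, ], angles, tr, f_true[i]), numeric(1))
  expect_true(all(abs(est - oracle) <= 1))      # within the 1 ms grid step
  expect_true(all(abs(est - t1_true) <= 1))
})

test_that("ignoring a 10% flip-angle miscalibration biases T1 by more than 5%", {
  angles <- c(4, 8, 12, 16, 20); tr <- 4.6
  sig <- spgr_oracle(1000, 1000, angles, tr, f = 1.1)
  series <- vfa_series(angles, lapply(sig, function(s)
    image_volume(array(s, c(4, 4, 2)), c(3, 3), 4)), tr)
  uncorrected <- fit_t1_vfa(series, b1 = NULL)
  expect_gt(abs(unique(as.vector(uncorrected$volume$data)) - 1000) / 1000,
            0.05)
  f <- b1_map(image_volume(array(1.1, c(4, 4, 2)), c(3, 3), 4))
  corrected <- fit_t1_vfa(series, b1 = f)
  expect_equal(unique(as.vector(corrected$volume$data)), 1000,
               tolerance = 1e-6)
})

test_that("degenerate VFA voxels are censored with reasons, mismatched B1 grids refused", {
  angles <- c(4, 8, 12, 16, 20); tr <- 4.6
  sig <- spgr_oracle(1000, 1000, angles, tr)
  arrs <- lapply(sig, function(s) array(s, c(3, 3, 2)))
  arrs[[1]][1, 1, 1] <- NA; arrs[[2]][1, 1, 1] <- NA
  arrs[[3]][1, 1, 1] <- NA; arrs[[4]][1, 1, 1] <- NA  # one valid frame left
  vols <- lapply(arrs, function(a) image_volume(a, c(3, 3), 4))
  fit <- fit_t1_vfa(vfa_series(angles, vols, tr))
  expect_true(is.na(fit$volume$data[1, 1, 1]))
  expect_equal(fit$diagnostics$n_too_few_frames, 1)
  wrong <- b1_map(image_volume(array(1, c(5, 5, 2)), c(3, 3), 4))
  expect_error(fit_t1_vfa(vfa_series(angles, vols, tr), b1 = wrong), "grid")
  # a series with no usable voxel at all is an empty-result error
  blank <- lapply(1:5, function(i) image_volume(array(NA_real_, c(2, 2, 1)),
                                                c(3, 3), 4))
  expect_error(fit_t1_vfa(vfa_series(angles, blank, tr)), "no valid voxel")
})

test_that("MTR map implements the saturation ratio with censoring", {
  off <- image_volume(array(100, c(3, 3, 2)), c(3, 3), 4)
  on60 <- image_volume(array(60, c(3, 3, 2)), c(3, 3), 4)
  expect_equal(unique(as.vector(compute_mtr(mt_pair(off, on60))$volume$data)),
               0.4)
  expect_equal(unique(as.vector(compute_mtr(mt_pair(off, off))$volume$data)),
               0)
  on0 <- image_volume(array(0, c(3, 3, 2)), c(3, 3), 4)
  expect_equal(unique(as.vector(compute_mtr(mt_pair(off, on0))$volume$data)),
               1)
  z <- image_volume(array(0, c(3, 3, 2)), c(3, 3), 4)
  m <- compute_mtr(mt_pair(z, on60))
  expect_true(all(is.na(m$volume$data)))
  expect_equal(m$diagnostics$n_invalid_off, 18)
  other <- image_volume(array(1, c(4, 4, 2)), c(3, 3), 4)
  expect_error(mt_pair(off, other), "grid")
})

test_that("series constructors enforce their invariants", {
  v <- uniform_volume(1)
  expect_error(dwi_series(c(800), list(v)))
  expect_error(dwi_series(c(200, 200), list(v, v)))
  expect_error(dwi_series(c(-5, 800), list(v, v)))
  expect_error(vfa_series(c(4, 95), list(v, v), 4.6))
  expect_error(vfa_series(c(4, 20), list(v, v), 0))
  # frames stored sorted ascending
  s <- dwi_series(c(800, 0), list(uniform_volume(1), uniform_volume(2)))
  expect_equal(s$b_values, c(0, 800))
  expect_equal(s$volumes[[1]]$data[1], 2)
})
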