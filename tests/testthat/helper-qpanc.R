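# Shared fixtures and independent oracles used across the suite.

# axis-aligned square contour (side mm) centered at (cx, cy) on one slice
square_contour <- function(side, cx = 0, cy = 0, slice = 1L) {
  h <- side / 2
  list(slice = slice,
       vertices = cbind(c(cx - h, cx + h, cx + h, cx - h),
                        c(cy - h, cy - h, cy + h, cy + h)))
}

square_stack <- function(side, cx = 0, cy = 0, slices = 1L,
                         frame_spacing = 4) {
  contour_stack(lapply(slices, function(s) square_contour(side, cx, cy, s)),
                frame_spacing)
}

# textbook Friedman chi-square on a complete subjects x sites matrix,
# average ranks for ties (independent of stats::friedman.test)
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2)
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  all_sums <- combn(length(pooled), na, function(i) sum(r[i]))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-12)
}

# SPGR forward signal for oracle computations, independent of the package's
# internal model function
spgr_oracle <- function(s0, t1, alpha_deg, tr, f = 1) {
  a <- f * alpha_deg * pi / 180
  E <- exp(-tr / t1)
  s0 * sin(a) * (1 - E) / (1 - E * cos(a))
}

# brute-force T1 oracle: dense grid over T1 with the profiled closed-form S0
t1_grid_oracle <- function(signals, alpha_deg, tr, f = 1,
                           t1_grid = seq(100, 4000, by = 1)) {
  best <- c(Inf, NA)
  for (t1 in t1_grid) {
    m1 <- spgr_oracle(1, t1, alpha_deg, tr, f)
    s0 <- sum(m1 * signals) / sum(m1 * m1)
    sse <- sum((signals - s0 * m1)^2)
    if (sse < best[1]) best <- c(sse, t1)
  }
  best[2]
}

# tiny uniform image volume
uniform_volume <- function(value, shape = c(6, 6, 4), spacing = c(3, 3),
                           slice = 4, origin = c(0, 0, 0)) {
  image_volume(array(value, dim = shape), spacing, slice, origin)
}

# small vial phantom grid used throughout the fitting tests
small_grid <- function() grid_spec(c(40, 34, 8), c(9, 9), 8)

# acquisition SNR convention: sigma = mean noiseless in-object signal / snr
sigma_for_snr <- function(volumes, snr) {
  mean(vapply(volumes, function(v) mean(v$data, na.rm = TRUE), numeric(1))) / snr
}
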