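test_that("a dense ring yields the analytic radius", {
  co <- ring_coords(100, 5.0, 0)
  fr <- mk_frame(co)              # carbon, Bondi 1.70
  p <- pore_radius_profile(fr, z_range = c(0, 0))
  expect_equal(p$radius[1], 3.30, tolerance = 0.05)
  expect_false(p$capped[1])
  # against the brute-force grid oracle
  oracle <- pore_slice_oracle(co, rep(1.7, 100), 0)
  expect_lt(abs(p$radius[1] - oracle), 0.05)
})

test_that("stacked rings give the minimum at the narrow ring", {
  co <- rbind(ring_coords(60, 5.0, -2), ring_coords(60, 4.0, 2))
  fr <- mk_frame(co)
  p <- pore_radius_profile(fr, z_range = c(-3, 3))
  expect_equal(min(p$radius), 2.30, tolerance = 0.05)
  expect_equal(p$z[which.min(p$radius)], 2, tolerance = 0.3)
})

test_that("slices far from any atom are capped and flagged", {
  fr <- mk_frame(ring_coords(30, 4, 0))
  p <- pore_radius_profile(fr, z_range = c(40, 40), max_radius = 10)
  expect_equal(p$radius[1], 10)
  expect_true(p$capped[1])
})

test_that("profile agrees with the grid oracle on constructed pores", {
  pores <- list(
    ring_coords(100, 5.0, 0),
    ring_coords(60, 3.0, 0),
    ring_coords(40, 4.5, 0),
    rbind(ring_coords(60, 5.0, -2), ring_coords(60, 4.0, 2)),
    rbind(ring_coords(50, 5, -3), ring_coords(50, 3, 0), ring_coords(50, 4, 3)),
    do.call(rbind, lapply(0:6, function(k) ring_coords(40, 5 - 0.4 * k, k - 3))),
    ring_coords(80, 2.3, 0),
    rbind(ring_coords(40, 4, -1), ring_coords(40, 4, 1)),
    ring_coords(60, 5, 0, center = c(1, 0.5)),
    rbind(ring_coords(30, 3.5, -2), ring_coords(90, 5.5, 2)))
  for (k in seq_along(pores)) {
    co <- pores[[k]]
    fr <- mk_frame(co)
    p <- pore_radius_profile(fr, z_range = c(-3, 3), z_step = 0.5,
                             lateral_bound = 3)
    for (j in seq_along(p$z)) {
      oracle <- pore_slice_oracle(co, rep(1.7, nrow(co)), p$z[j], bound = 3)
      expect_lt(abs(p$radius[j] - oracle), 0.05,
                label = sprintf("pore %d, z = %.1f: |%.4f - %.4f|",
                                k, p$z[j], p$radius[j], oracle))
    }
  }
})

test_that("radius is invariant under rotation about z and z translation", {
  co <- rbind(ring_coords(60, 5.0, -1), ring_coords(60, 3.7, 1))
  p1 <- pore_radius_profile(mk_frame(co), z_range = c(-2, 2))
  p2 <- pore_radius_profile(mk_frame(rotate_z(co, 33)), z_range = c(-2, 2))
  expect_lt(max(abs(p1$radius - p2$radius)), 0.05)
  co3 <- co; co3[, 3] <- co3[, 3] + 7
  p3 <- pore_radius_profile(mk_frame(co3), z_range = c(5, 9))
  expect_lt(max(abs(p1$radius - p3$radius)), 1e-9)
})

test_that("enlarging all vdW radii by delta shifts every radius by exactly delta", {
  co <- rbind(ring_coords(60, 5.0, -1), ring_coords(60, 4.0, 1))
  fr <- mk_frame(co)
  delta <- 0.2
  p1 <- pore_radius_profile(fr, radii = rep(1.7, nrow(co)), z_range = c(-2, 2))
  p2 <- pore_radius_profile(fr, radii = rep(1.7 + delta, nrow(co)),
                            z_range = c(-2, 2))
  expect_equal(p1$radius - p2$radius, rep(delta, length(p1$radius)),
               tolerance = 1e-12)
})

test_that("minimal-radius series recovers the planted aperture", {
  for (ap in c(0.59, 2.3)) {
    sp <- channel_spec(n_frames = 5, per_residue_sigma = 0, gate_aperture = ap,
                       seed = 2)
    s <- min_radius_series(simulate_trajectory(sp), z_range = c(-3, 3))
    expect_equal(s$min_radius, rep(ap, 5), tolerance = 0.05)
    expect_equal(s$min_radius_z, rep(0, 5), tolerance = 0.5)
  }
})

test_that("permeable fraction counts strictly above the threshold", {
  expect_equal(permeable_fraction(rep(2, 10))$permeable_fraction, 1)
  expect_equal(permeable_fraction(rep(c(0.9, 1.3), 5))$permeable_fraction, 0.5)
  series <- c(rep(1.2, 6), rep(1.1, 4))
  expect_equal(permeable_fraction(series, 1.15)$permeable_fraction, 0.6)
  # boundary value is NOT permeable (strict inequality)
  expect_equal(permeable_fraction(c(1.15, 1.15))$permeable_fraction, 0)
})

test_that("permeation events count only complete in-bound traversals", {
  top <- mk_top(1, elety = "OW", resid = "HOH", chain = "W", elem = "O")
  path_z <- function(z) lapply(z, function(zz) matrix(c(0.2, 0, zz), 1))
  up <- mk_traj(path_z(seq(-8, 8, length.out = 9)), top = top)
  fx <- count_permeations(up, upper_gate_z = 5, lower_gate_z = -5)
  expect_equal(fx$n_permeation_events, 1L)
  expect_equal(fx$events$direction, "up")
  # oscillation across only the lower plane
  osc <- mk_traj(path_z(c(-8, -3, -8, -3, -8)), top = top)
  expect_equal(count_permeations(osc, upper_gate_z = 5,
                                 lower_gate_z = -5)$n_permeation_events, 0L)
  # traversal that strays laterally is discarded
  stray <- mk_traj(list(matrix(c(0, 0, -8), 1), matrix(c(12, 0, 0), 1),
                        matrix(c(0, 0, 8), 1)), top = top)
  expect_equal(count_permeations(stray, upper_gate_z = 5, lower_gate_z = -5,
                                 lateral_bound = 8)$n_permeation_events, 0L)
  # gate plane ordering enforced
  expect_error(count_permeations(up, upper_gate_z = -5, lower_gate_z = 5),
               "upper_gate_z > lower_gate_z")
})

test_that("planted traversing waters are all counted, blocked ones never", {
  sp <- channel_spec(n_frames = 120, seed = 21, n_waters_traversing = 5L,
                     n_waters_blocked = 4L)
  tr <- simulate_trajectory(sp)
  m <- truth_manifest(tr)
  fx <- count_permeations(tr, upper_gate_z = m$upper_gate_z,
                          lower_gate_z = m$lower_gate_z)
  expect_equal(fx$n_permeation_events, 5L)
  expect_true(all(fx$events$direction == "up"))
})
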