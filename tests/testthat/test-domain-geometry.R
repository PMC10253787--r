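test_that("radius of gyration matches closed forms", {
  sq <- matrix(c(1, 1, 0, 1, -1, 0, -1, 1, 0, -1, -1, 0), 4, 3, byrow = TRUE)
  tr <- mk_traj(list(sq))
  expect_equal(rg_series(tr, sel = 1:4)$rg, sqrt(2))
  # coincident atoms
  tr0 <- mk_traj(list(matrix(5, 4, 3)))
  expect_equal(rg_series(tr0, sel = 1:4)$rg, 0)
  # homogeneity: dilation by 2 doubles Rg
  tr2 <- mk_traj(list(2 * sq))
  expect_equal(rg_series(tr2, sel = 1:4)$rg, 2 * sqrt(2))
})

test_that("twist angle equals the tangential tilt and ignores radial tilt", {
  for (tt in c(0, 10, 30, 60)) {
    ref <- build_reference(channel_spec(helix_tilt_tangential_deg = tt,
                                        helix_tilt_radial_deg = 0))
    tw <- twist_angle(ref, chain = "A")
    expect_lt(abs(tw$twist_angle - tt), 0.5)
  }
  for (rt in c(10, 30)) {
    ref <- build_reference(channel_spec(helix_tilt_tangential_deg = 0,
                                        helix_tilt_radial_deg = rt))
    expect_lt(abs(twist_angle(ref, chain = "A")$twist_angle), 0.5)
  }
  # radial tilt barely perturbs the recovered tangential tilt
  ref <- build_reference(channel_spec(helix_tilt_tangential_deg = 30,
                                      helix_tilt_radial_deg = 10))
  expect_lt(abs(twist_angle(ref, chain = "A")$twist_angle - 30), 0.5)
})

test_that("twist angle is invariant under frame rotation about z and atom order", {
  ref <- build_reference(channel_spec(helix_tilt_tangential_deg = 25))
  a0 <- twist_angle(ref, chain = "A")$twist_angle
  co <- frame_coords(ref)
  rot <- structure_frame(ref$top, flat(rotate_z(co, 57)))
  expect_equal(twist_angle(rot, chain = "A")$twist_angle, a0, tolerance = 1e-9)
  # reverse the helix atom order
  idx <- resolve_selection(ref, "chain A, calpha")$indices
  perm <- seq_len(nrow(ref$top))
  perm[idx] <- rev(idx)
  rev_fr <- structure_frame(ref$top[perm, ], flat(co[perm, ]))
  expect_equal(twist_angle(rev_fr, chain = "A")$twist_angle, a0,
               tolerance = 1e-9)
})

test_that("per-frame twist series carries the chain mean", {
  sp <- channel_spec(n_frames = 4, per_residue_sigma = 0,
                     helix_tilt_tangential_deg = 20)
  tw <- twist_series(simulate_trajectory(sp))
  expect_setequal(unique(tw$chain), c("A", "B", "C", "D", "mean"))
  expect_equal(tw$angle[tw$chain == "mean"], rep(20, 4), tolerance = 0.5)
})

test_that("twist angle needs enough Calpha atoms", {
  fr <- mk_frame(matrix(rnorm(6), 2), resno = 1:2)
  expect_error(twist_angle(fr, helix = 1:2), "at least 3")
})

test_that("distance matrix averages per-frame Calpha distances", {
  top <- mk_top(3, resno = 1:3)
  line <- function(d) matrix(c(0, 0, 0, d, 0, 0, 2 * d, 0, 0), 3, 3, byrow = TRUE)
  tr <- mk_traj(list(line(2)), top = top)
  dm <- distance_matrix(tr, chain = "A")
  expect_equal(dm$D[1, 3], 4.0)
  expect_equal(dm$D, t(dm$D))
  expect_equal(diag(dm$D), rep(0, 3))
  # two-frame averaging: distances 3 and 5 -> 4
  tr2 <- mk_traj(list(line(1.5), line(2.5)), top = top)
  expect_equal(distance_matrix(tr2, chain = "A")$D[1, 2], 2.0)
  expect_equal(distance_matrix(tr2, chain = "A")$D[1, 3], 4.0)
})

test_that("state comparison yields delta, correlations and antisymmetry", {
  mk_dm <- function(D, lab) structure(list(D = D, resno = seq_len(nrow(D)),
                                           chain = "A", state_label = lab),
                                      class = "distance_matrix")
  set.seed(4)
  base <- as.matrix(dist(matrix(rnorm(15), 5)))
  D1 <- mk_dm(base, "oxi")
  # equal states: zero delta, undefined correlations flagged
  cmpn <- compare_states(D1, D1)
  expect_true(all(cmpn$delta == 0))
  expect_true(all(is.na(cmpn$corr)))
  expect_length(cmpn$zero_variance_rows, 5)
  # perfectly (anti)correlated constructed rows: row 2 = 2 x row 1,
  # row 3 = -row 1
  delta <- rbind(c(0, 1, 2, 3),
                 c(0, 2, 4, 6),
                 c(0, -1, -2, -3),
                 c(4, 0, 5, 1))
  D2 <- mk_dm(delta, "oxi")
  D3 <- mk_dm(matrix(0, 4, 4), "red")
  cmp2 <- compare_states(D2, D3)
  expect_equal(cmp2$delta, delta)
  expect_equal(cmp2$corr[1, 2], 1.0)
  expect_equal(cmp2$corr[1, 3], -1.0)
  # exact antisymmetry under state swap
  expect_equal(compare_states(D3, D2)$delta, -cmp2$delta)
  # cross-state mode correlates D1 rows against D2 rows
  cs <- compare_states(D2, D2, corr_on = "states")
  expect_equal(diag(cs$corr), rep(1, 4))
  # misaligned residue sets
  D4 <- mk_dm(base, "oxi"); D4$resno <- 11:15
  expect_error(compare_states(D4, D1), "not aligned")
})
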