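test_that("untilted helices have principal axes parallel to z", {
  ref <- build_reference(channel_spec(helix_tilt_tangential_deg = 0,
                                      helix_tilt_radial_deg = 0))
  for (ch in c("A", "B", "C", "D")) {
    idx <- resolve_selection(ref, paste("chain", ch, ", calpha"))$indices
    ca <- frame_coords(ref)[idx, ]
    ax <- eigen(cov(ca), symmetric = TRUE)$vectors[, 1]
    # angle to z below 1e-6 rad
    expect_lt(acos(min(1, abs(ax[3]))), 1e-6)
  }
})

test_that("the tetramer is invariant under 90 degree rotation about z", {
  ref <- build_reference(channel_spec(seed = 2))
  co <- frame_coords(ref)
  idxA <- resolve_selection(ref, "chain A")$indices
  idxB <- resolve_selection(ref, "chain B")$indices
  expect_lt(max(abs(rotate_z(co[idxA, ], 90) - co[idxB, ])), 1e-6)
  # gate ring maps onto itself (ring atom count is a multiple of 4)
  idxG <- resolve_selection(ref, "chain G")$indices
  rot <- rotate_z(co[idxG, ], 90)
  shift <- length(idxG) / 4
  perm <- c((shift + 1):length(idxG), 1:shift)  # atom k maps onto atom k + n/4
  expect_lt(max(abs(rot - co[idxG, ][perm, ])), 1e-6)
})

test_that("gate ring clearance equals the aperture analytically", {
  # ring of 100 atoms at ring radius 5.0 with carbon vdW 1.7 -> clearance 3.3
  sp <- channel_spec(gate_aperture = 3.3, gate_ring_atoms = 100L)
  ref <- build_reference(sp)
  idx <- resolve_selection(ref, "resname GAT")$indices
  ring <- frame_coords(ref)[idx, ]
  expect_equal(unname(sqrt(ring[, 1]^2 + ring[, 2]^2)), rep(5.0, 100))
  expect_equal(min(sqrt(ring[, 1]^2 + ring[, 2]^2)) - 1.70, 3.3)
})

test_that("zero noise reproduces the reference in every frame", {
  sp <- channel_spec(n_frames = 4, per_residue_sigma = 0, seed = 8)
  tr <- simulate_trajectory(sp)
  ref <- build_reference(sp)
  for (f in 1:4) expect_equal(tr$xyz[f, ], ref$xyz, tolerance = 1e-12)
})

test_that("a fixed seed gives bit-identical trajectories", {
  sp <- channel_spec(n_frames = 6, seed = 123, n_waters_traversing = 1,
                     gate_open_fraction = 0.5,
                     planted_hbonds = list(list(occupancy = 0.5)))
  t1 <- simulate_trajectory(sp)
  t2 <- simulate_trajectory(sp)
  expect_identical(t1$xyz, t2$xyz)
  expect_identical(truth_manifest(t1), truth_manifest(t2))
})

test_that("invalid specifications are rejected", {
  expect_error(channel_spec(gate_aperture = -1), "positive")
  expect_error(channel_spec(gate_open_fraction = 1.5), "\\[0, 1\\]")
  expect_error(channel_spec(planted_hbonds = list(list(occupancy = 2))),
               "occupancy")
  expect_error(channel_spec(per_residue_sigma = rep(0.5, 7)),
               "per helix residue")
})

test_that("morph_states records ground-truth differences and checks topology", {
  sp1 <- channel_spec(n_frames = 20, seed = 1, helix_tilt_tangential_deg = 25,
                      label = "closed")
  sp2 <- channel_spec(n_frames = 20, seed = 2, helix_tilt_tangential_deg = 30.7,
                      gate_open_fraction = 1, label = "open")
  pair <- morph_states(sp1, sp2)
  expect_equal(pair$truth$twist_difference_deg, 5.7)
  expect_equal(pair$truth$labels, c("closed", "open"))
  # downstream permeable fraction differs in the known direction
  expect_lt(pair$truth$permeable_fraction[1], pair$truth$permeable_fraction[2])
  bad <- channel_spec(n_frames = 20, seed = 2, helix_residues = 20L)
  expect_error(morph_states(sp1, bad), "topology mismatch")
})

test_that("recovered twist-angle difference matches the planted 5.7 degrees", {
  sp1 <- channel_spec(n_frames = 8, seed = 4, helix_tilt_tangential_deg = 25,
                      per_residue_sigma = 0.1, label = "closed")
  sp2 <- channel_spec(n_frames = 8, seed = 5, helix_tilt_tangential_deg = 30.7,
                      per_residue_sigma = 0.1, label = "open")
  pair <- morph_states(sp1, sp2)
  tw <- function(tr) {
    s <- twist_series(tr, helix = "residues 658-692")
    mean(s$angle[s$chain == "mean"])
  }
  d <- tw(pair$open) - tw(pair$closed)
  expect_lt(abs(d - 5.7), 0.5)
})

test_that("identical specs give vanishing state-difference statistics", {
  sp <- channel_spec(n_frames = 15, seed = 77, per_residue_sigma = 0.3,
                     label = "same")
  pair <- morph_states(sp, sp)
  expect_equal(pair$truth$twist_difference_deg, 0)
  expect_identical(pair[[1]]$xyz, pair[[2]]$xyz)
})

test_that("the manifest is written as JSON alongside the dataset", {
  sp <- channel_spec(n_frames = 3, seed = 6,
                     planted_hbonds = list(list(occupancy = 1)))
  paths <- write_dataset(simulate_trajectory(sp), tempfile(), "x")
  m <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  expect_equal(m$n_frames, 3)
  expect_equal(m$hbonds$occupancy, 1)
})
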