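test_that("a minimal handwritten PDB reads back verbatim", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), tmp)
  fr <- read_structure(tmp)
  expect_equal(n_atoms(fr), 1L)
  expect_equal(as.numeric(fr$xyz), c(1, 2, 3))
  expect_equal(fr$top$elety, "CA")
  expect_equal(fr$top$chain, "A")
  expect_equal(fr$top$resno, 1L)
})

test_that("write/read round trip preserves coordinates and atom order", {
  sp <- channel_spec(n_frames = 1, seed = 5, n_waters_traversing = 1,
                     planted_hbonds = list(list(occupancy = 1)))
  ref <- build_reference(sp)
  tmp <- tempfile(fileext = ".pdb")
  write_structure(ref, tmp)
  back <- read_structure(tmp)
  # PDB fixed-width gives 1e-3 A precision
  expect_lt(max(abs(back$xyz - ref$xyz)), 1e-3)
  expect_identical(back$top$elety, ref$top$elety)
  expect_identical(back$top$resno, ref$top$resno)
  expect_identical(back$top$chain, ref$top$chain)
})

test_that("multi-model PDB honours the requested model", {
  sp <- channel_spec(n_frames = 4, seed = 9)
  tr <- simulate_trajectory(sp)
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = tr$xyz, resno = tr$top$resno,
                   resid = tr$top$resid, eleno = tr$top$eleno,
                   elety = tr$top$elety, chain = tr$top$chain,
                   elesy = tr$top$elem)
  m3 <- read_structure(tmp, model = 3)
  expect_lt(max(abs(m3$xyz - tr$xyz[3, ])), 1e-3)
  expect_error(read_structure(tmp, model = 9), "model")
})

test_that("unparsable and empty structure files raise format errors", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), tmp)
  expect_error(read_structure(tmp))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("DCD trajectory round trip preserves frames and order", {
  sp <- channel_spec(n_frames = 10, seed = 3, n_waters_traversing = 2)
  tr <- simulate_trajectory(sp)
  dir <- tempfile(); paths <- write_dataset(tr, dir, "rt")
  back <- read_trajectory(paths$topology, paths$trajectory, stride_ps = 250)
  expect_equal(n_frames(back), 10L)
  expect_lt(max(abs(back$xyz - tr$xyz)), 1e-5)  # single-precision storage
  expect_identical(back$top$elety, tr$top$elety)
})

test_that("atom-count mismatch and truncation are reported", {
  sp <- channel_spec(n_frames = 10, seed = 3)
  tr <- simulate_trajectory(sp)
  dir <- tempfile(); paths <- write_dataset(tr, dir, "tt")
  small <- get_frame(tr, 1)
  small <- structure_frame(small$top[1:10, ], small$xyz[1:30])
  expect_error(read_trajectory(small, paths$trajectory), "mismatch")
  sz <- file.size(paths$trajectory)
  raw <- readBin(paths$trajectory, "raw", sz)
  trunc <- tempfile(fileext = ".dcd")
  writeBin(raw[1:floor(sz * 0.62)], trunc)
  expect_error(read_trajectory(paths$topology, trunc), "recoverable")
})

test_that("selection grammar resolves counts deterministically", {
  co <- matrix(rnorm(9), 3)
  fr <- mk_frame(co)  # 3 CA atoms, chain A, resno 1:3
  s <- resolve_selection(fr, "chain A, residues 1-3, atoms CA")
  expect_length(s$indices, 3L)
  # the full tetramer: 4 chains x 282 residues x 4 backbone atoms
  big <- build_reference(channel_spec(helix_residues = 282L, first_resno = 432L,
                                      helix_tilt_tangential_deg = 0))
  sel <- resolve_selection(big, "residues 432-713, backbone")
  expect_length(sel$indices, 4L * 282L * 4L)
  sel2 <- resolve_selection(big, "residues 432-713, backbone")
  expect_identical(sel, sel2)
  # en dash works like a hyphen
  expect_identical(resolve_selection(big, "residues 432–713, backbone")$indices,
                   sel$indices)
})

test_that("selection errors and warnings follow the contract", {
  fr <- mk_frame(matrix(rnorm(9), 3))
  expect_error(resolve_selection(fr, "chain Z"), "empty selection")
  expect_warning(resolve_selection(fr, "atoms CA CB"), "not in topology")
  expect_error(resolve_selection(fr, "bogus clause"), "unknown selection keyword")
})

test_that("van der Waals assignment uses the table with a logged fallback", {
  fr <- mk_frame(matrix(0, 3, 3), elem = c("C", "H", "XX"))
  expect_message(r <- assign_vdw(fr), "default radius")
  expect_equal(r, c(1.70, 1.20, 1.70))
  all_h <- mk_frame(matrix(0, 4, 3), elem = "H")
  expect_equal(assign_vdw(all_h), rep(1.20, 4))
  hole <- assign_vdw(mk_frame(matrix(0, 1, 3), elem = "C"),
                     vdw_table("hole_simple"))
  expect_equal(hole, 1.85)
})
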