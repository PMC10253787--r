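test_that("ideal helix geometry yields canonical phi/psi", {
  sp <- channel_spec(n_frames = 2, per_residue_sigma = 0)
  dh <- extract_dihedrals(simulate_trajectory(sp), sel = "chain A")
  expect_lt(max(abs(dh$angles[1, dh$type == "phi"] + 57)), 1)
  expect_lt(max(abs(dh$angles[1, dh$type == "psi"] + 47)), 1)
  # terminal residues: no phi for the first, no psi for the last
  expect_false(any(dh$type == "phi" & dh$resno == min(dh$resno)))
  expect_false(any(dh$type == "psi" & dh$resno == max(dh$resno)))
})

test_that("an all-trans backbone gives +/-180 degree dihedrals", {
  zig <- gatescan:::build_helix_backbone(6, phi = 180, psi = 180)
  n <- nrow(zig)
  top <- data.frame(elety = rep(c("N", "CA", "C", "O"), 6), resid = "ALA",
                    chain = "A", resno = rep(1:6, each = 4),
                    elem = rep(c("N", "C", "C", "O"), 6),
                    stringsAsFactors = FALSE)
  tr <- trajectory(top, matrix(as.numeric(t(zig)), 1))
  dh <- extract_dihedrals(tr)
  expect_true(all(abs(abs(dh$angles)) > 179.9))
})

test_that("a 2-residue chain has one phi and one psi", {
  bb <- gatescan:::build_helix_backbone(2)
  top <- data.frame(elety = rep(c("N", "CA", "C", "O"), 2), resid = "ALA",
                    chain = "A", resno = rep(1:2, each = 4),
                    elem = rep(c("N", "C", "C", "O"), 2),
                    stringsAsFactors = FALSE)
  dh <- extract_dihedrals(trajectory(top, matrix(as.numeric(t(bb)), 1)))
  expect_equal(sort(dh$type), c("phi", "psi"))
  expect_equal(dh$resno[dh$type == "phi"], 2L)
  expect_equal(dh$resno[dh$type == "psi"], 1L)
})

test_that("chain breaks skip the spanning dihedrals with a warning", {
  bb <- gatescan:::build_helix_backbone(4)
  bb[13:16, 1] <- bb[13:16, 1] + 50  # displace residue 4
  top <- data.frame(elety = rep(c("N", "CA", "C", "O"), 4), resid = "ALA",
                    chain = "A", resno = rep(1:4, each = 4),
                    elem = rep(c("N", "C", "C", "O"), 4),
                    stringsAsFactors = FALSE)
  expect_warning(
    dh <- extract_dihedrals(trajectory(top, matrix(as.numeric(t(bb)), 1))),
    "chain break")
  expect_false(any(dh$resno == 4))
})

test_that("a frozen trajectory has all-zero eigenvalues and projections", {
  ang <- matrix(c(-57, -47, 120), 5, 3, byrow = TRUE)
  pc <- dpca(ang)
  expect_equal(pc$eigenvalues, rep(0, 6))
  expect_equal(unname(pc$projections), matrix(0, 5, 2))
})

test_that("one oscillating dihedral is fully captured by its sin/cos pair", {
  set.seed(6)
  nf <- 200
  ang <- matrix(rep(c(-57, -47, 63, 120), each = nf), nf, 4)
  ang[, 2] <- 180 * sin(seq(0, 6 * pi, length.out = nf))  # the planted mode
  pc <- dpca(ang, n_components = 2)
  X <- cbind(sin(pi / 180 * ang), cos(pi / 180 * ang))
  total <- sum(diag(cov(X)))
  expect_equal(sum(pc$eigenvalues[1:2]), total, tolerance = 1e-10)
  expect_lt(sum(pc$eigenvalues[-(1:2)]), 1e-20)
})

test_that("eigendecomposition matches a brute-force covariance oracle", {
  set.seed(7)
  ang <- matrix(runif(5 * 3, -180, 180), 5, 3)
  pc <- dpca(ang, n_components = 6)
  # independent small-matrix oracle: covariance assembled element by element
  X <- cbind(sin(pi / 180 * ang), cos(pi / 180 * ang))
  n <- nrow(X); k <- ncol(X)
  C <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    C[i, j] <- sum((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))) / (n - 1)
  }
  rebuilt <- pc$eigenvectors %*% diag(pc$eigenvalues) %*% t(pc$eigenvectors)
  expect_lt(max(abs(rebuilt - C)), 1e-10)
  expect_equal(sum(pc$eigenvalues), sum(diag(C)), tolerance = 1e-12)
  # orthonormal eigenvectors
  expect_lt(max(abs(crossprod(pc$eigenvectors) - diag(k))), 1e-10)
})

test_that("dPCA is invariant under 360 degree angle shifts", {
  set.seed(8)
  ang <- matrix(runif(40, -180, 180), 10, 4)
  e1 <- dpca(ang)$eigenvalues
  e2 <- dpca(ang + 360)$eigenvalues
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("planted mode-variance ordering is recovered", {
  set.seed(9)
  nf <- 500
  ang <- matrix(0, nf, 3)
  ang[, 1] <- 40 * sin(seq(0, 8 * pi, length.out = nf))   # large mode
  ang[, 2] <- 10 * sin(seq(0, 50, length.out = nf))       # small mode
  pc <- dpca(ang, n_components = 4)
  # PC1 loads on angle 1's sin/cos pair, not angle 2's
  load1 <- sum(pc$eigenvectors[c(1, 4), 1]^2)
  load2 <- sum(pc$eigenvectors[c(2, 5), 1]^2)
  expect_gt(load1, load2)
  expect_gt(pc$eigenvalues[1], pc$eigenvalues[2])
  expect_equal(pc$eigenvalues, sort(pc$eigenvalues, decreasing = TRUE))
})

test_that("free-energy surfaces follow the Boltzmann inversion", {
  kT <- 0.0019872041 * 303
  # all frames in one bin
  one <- free_energy_surface(matrix(1, 20, 2), bins = 5)
  expect_equal(sum(one$counts > 0), 1L)
  expect_equal(one$F[one$counts > 0], 0)
  expect_true(all(is.na(one$F[one$counts == 0])))
  # two bins with counts N and ~N/e differ by ~kT
  n1 <- 2000; n2 <- 736
  proj <- rbind(matrix(0.1, n1, 2), matrix(0.9, n2, 2))
  fes <- free_energy_surface(proj, bins = 2, temperature = 303)
  dF <- max(fes$F, na.rm = TRUE) - min(fes$F, na.rm = TRUE)
  expect_equal(dF, kT * log(n1 / n2), tolerance = 1e-12)
  expect_equal(dF, 0.602, tolerance = 0.002)
  # uniform occupancy: all occupied bins at F = 0
  u <- free_energy_surface(cbind(rep(c(0.25, 0.75), 50), rep(c(0.25, 0.75), 50)),
                           bins = 2)
  expect_true(all(u$F[u$counts > 0] == 0))
  # minimum over occupied bins is 0 and F >= 0
  expect_equal(min(fes$F, na.rm = TRUE), 0)
  expect_true(all(fes$F >= 0, na.rm = TRUE))
})
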