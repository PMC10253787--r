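# Synthetic tetrameric channel generator.
#
# Builds an idealised four-fold bundle of pore-lining alpha-helices around
# the z axis, a gate ring of tunable aperture, planted donor-H-acceptor
# triplets with prescribed geometry and occupancy, and water pseudo-atoms
# that traverse (or fail to traverse) the pore. Every planted quantity is
# recorded in a ground-truth manifest so analyses can be tested against
# known answers.

#' Specification of a synthetic channel system
#'
#' @param n_subunits number of pore-lining helices (default 4, tetramer).
#' @param helix_residues residues per helix.
#' @param first_resno author residue number of the first helix residue
#'   (default 658, mimicking an S6 helix spanning 658-692).
#' @param helix_radius_from_axis distance of each helix centroid from the
#'   channel (z) axis, Angstrom.
#' @param helix_tilt_tangential_deg tilt of the helix principal axis within
#'   the plane perpendicular to the radial vector; this is exactly the
#'   twist angle the geometry module should recover.
#' @param helix_tilt_radial_deg tilt within the z-radial plane; invisible
#'   to the twist angle by construction.
#' @param gate_aperture target minimal pore radius, Angstrom (closed value
#'   when a two-level schedule is used).
#' @param gate_aperture_open open-state aperture used for the fraction
#'   `gate_open_fraction` of frames.
#' @param gate_open_fraction fraction of frames simulated at
#'   `gate_aperture_open`; the exact count `round(fraction * n_frames)` is
#'   planted and recorded in the manifest.
#' @param gate_ring_atoms atoms in the gate ring (multiple of `n_subunits`
#'   preserves the n-fold symmetry).
#' @param gate_z axial position of the gate ring, Angstrom.
#' @param per_residue_sigma isotropic per-coordinate Gaussian fluctuation
#'   (Angstrom) per helix residue; scalar or vector of length
#'   `helix_residues`. The expected RMSF of a residue is `sigma * sqrt(3)`.
#' @param planted_hbonds list of planted hydrogen bonds; each element a
#'   list with fields `occupancy` (fraction of frames the bond geometry is
#'   satisfied), and optionally `d_on` (A-D distance when formed, default
#'   2.8), `angle_on` (A-H-D angle when formed, default 180), `d_off`
#'   (A-D distance when broken, default 4.5) and `label`.
#' @param n_waters_traversing waters that cross the pore monotonically from
#'   below the lower gate plane to above the upper gate plane.
#' @param n_waters_blocked waters that oscillate across the lower gate
#'   plane only and must not be counted as permeation events.
#' @param n_frames trajectory frames.
#' @param stride_ps time between frames, ps.
#' @param seed RNG seed; a fixed seed gives bit-identical trajectories.
#' @param label state label carried into analyses (e.g. "oxidized").
#' @return object of class `channel_spec`.
#' @export
channel_spec <- function(n_subunits = 4L,
                         helix_residues = 35L,
                         first_resno = 658L,
                         helix_radius_from_axis = 14,
                         helix_tilt_tangential_deg = 25,
                         helix_tilt_radial_deg = 0,
                         gate_aperture = 0.59,
                         gate_aperture_open = 2.31,
                         gate_open_fraction = 0,
                         gate_ring_atoms = 24L,
                         gate_z = 0,
                         per_residue_sigma = 0.5,
                         planted_hbonds = list(),
                         n_waters_traversing = 0L,
                         n_waters_blocked = 0L,
                         n_frames = 2000L,
                         stride_ps = 250,
                         seed = 42L,
                         label = "state") {
  spec <- list(n_subunits = as.integer(n_subunits),
               helix_residues = as.integer(helix_residues),
               first_resno = as.integer(first_resno),
               helix_radius_from_axis = helix_radius_from_axis,
               helix_tilt_tangential_deg = helix_tilt_tangential_deg,
               helix_tilt_radial_deg = helix_tilt_radial_deg,
               gate_aperture = gate_aperture,
               gate_aperture_open = gate_aperture_open,
               gate_open_fraction = gate_open_fraction,
               gate_ring_atoms = as.integer(gate_ring_atoms),
               gate_z = gate_z,
               per_residue_sigma = per_residue_sigma,
               planted_hbonds = planted_hbonds,
               n_waters_traversing = as.integer(n_waters_traversing),
               n_waters_blocked = as.integer(n_waters_blocked),
               n_frames = as.integer(n_frames),
               stride_ps = stride_ps,
               seed = as.integer(seed),
               label = label)
  validate_channel_spec(spec)
  structure(spec, class = "channel_spec")
}

validate_channel_spec <- function(spec) {
  with(spec, {
    if (n_subunits < 1L) stop("n_subunits must be >= 1")
    if (helix_residues < 4L) stop("helix_residues must be >= 4")
    if (helix_radius_from_axis <= 0) stop("helix_radius_from_axis must be positive")
    if (gate_aperture <= 0 || gate_aperture_open <= 0)
      stop("gate apertures must be positive (negative axis clearance is impossible)")
    if (gate_open_fraction < 0 || gate_open_fraction > 1)
      stop("gate_open_fraction must be in [0, 1]")
    if (any(per_residue_sigma < 0)) stop("per_residue_sigma must be >= 0")
    if (!length(per_residue_sigma) %in% c(1L, helix_residues))
      stop("per_residue_sigma must be scalar or one value per helix residue")
    if (n_frames < 1L) stop("n_frames must be >= 1")
    for (hb in planted_hbonds) {
      occ <- hb$occupancy
      if (is.null(occ) || occ < 0 || occ > 1)
        stop("planted hbond occupancy must be in [0, 1]")
    }
  })
  invisible(spec)
}

# ---- ideal helix construction ------------------------------------------

# Place atom D from A, B, C with bond length r (C-D), bond angle theta
# (B-C-D, degrees) and torsion phi (A-B-C-D, degrees). NeRF construction.
place_atom <- function(A, B, C, r, theta, phi) {
  theta <- deg2rad(theta); phi <- deg2rad(phi)
  bc <- unit_vec(C - B)
  n <- unit_vec(c((B - A)[2] * bc[3] - (B - A)[3] * bc[2],
                  (B - A)[3] * bc[1] - (B - A)[1] * bc[3],
                  (B - A)[1] * bc[2] - (B - A)[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal backbone (N, CA, C, O per residue) from canonical phi/psi angles.
# Returns a (4 * n_res) x 3 matrix in N, CA, C, O order per residue.
build_helix_backbone <- function(n_res, phi = -57, psi = -47, omega = 180) {
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  coords <- matrix(NA_real_, 4L * n_res, 3L)
  rowi <- function(res, atom) 4L * (res - 1L) + atom  # atom: 1=N 2=CA 3=C 4=O
  # seed residue in the xy plane
  coords[rowi(1, 1), ] <- c(0, 0, 0)
  coords[rowi(1, 2), ] <- c(b_NCA, 0, 0)
  ang <- deg2rad(180 - a_NCAC)
  coords[rowi(1, 3), ] <- coords[rowi(1, 2), ] + b_CAC * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    N <- coords[rowi(i, 1), ]; CA <- coords[rowi(i, 2), ]; C <- coords[rowi(i, 3), ]
    # carbonyl O: torsion psi - 180 about N-CA-C
    coords[rowi(i, 4), ] <- place_atom(N, CA, C, b_CO, a_CACO, psi - 180)
    if (i < n_res) {
      Nn <- place_atom(N, CA, C, b_CN, a_CACN, psi)
      CAn <- place_atom(CA, C, Nn, b_NCA, a_CNCA, omega)
      Cn <- place_atom(C, Nn, CAn, b_CAC, a_NCAC, phi)
      coords[rowi(i + 1, 1), ] <- Nn
      coords[rowi(i + 1, 2), ] <- CAn
      coords[rowi(i + 1, 3), ] <- Cn
    }
  }
  coords
}

# Rotate coordinates so the CA principal axis lies along +z (first->last CA
# pointing up) and the centroid sits at the origin.
orient_helix <- function(coords, n_res) {
  ca <- coords[4L * (seq_len(n_res) - 1L) + 2L, , drop = FALSE]
  cen <- colMeans(ca)
  ax <- eigen(stats::cov(ca), symmetric = TRUE)$vectors[, 1]
  if (sum(ax * (ca[n_res, ] - ca[1, ])) < 0) ax <- -ax
  z <- c(0, 0, 1)
  v <- c(ax[2] * z[3] - ax[3] * z[2],
         ax[3] * z[1] - ax[1] * z[3],
         ax[1] * z[2] - ax[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(ax * z)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  sweep(coords, 2, cen) %*% t(R)
}

# ---- topology layout ---------------------------------------------------

# Atom bookkeeping for one spec. Returns list(top, blocks) where blocks
# maps logical groups to atom index ranges.
channel_topology <- function(spec) {
  nres <- spec$helix_residues
  chains <- LETTERS[seq_len(spec$n_subunits)]
  helix_top <- do.call(rbind, lapply(chains, function(ch) {
    data.frame(elety = rep(c("N", "CA", "C", "O"), nres),
               resid = "ALA",
               chain = ch,
               resno = rep(spec$first_resno + seq_len(nres) - 1L, each = 4L),
               elem = rep(c("N", "C", "C", "O"), nres),
               stringsAsFactors = FALSE)
  }))
  ring_top <- if (spec$gate_ring_atoms > 0L) {
    data.frame(elety = sprintf("C%02d", seq_len(spec$gate_ring_atoms)),
               resid = "GAT", chain = "G", resno = 1L, elem = "C",
               stringsAsFactors = FALSE)
  }
  nhb <- length(spec$planted_hbonds)
  hb_top <- if (nhb > 0L) {
    do.call(rbind, lapply(seq_len(nhb), function(b) {
      data.frame(elety = c("N", "HN", "O"),
                 resid = c("DNR", "DNR", "ACP"),
                 chain = "X",
                 resno = c(b, b, 100L + b),
                 elem = c("N", "H", "O"),
                 stringsAsFactors = FALSE)
    }))
  }
  nw <- spec$n_waters_traversing + spec$n_waters_blocked
  wat_top <- if (nw > 0L) {
    data.frame(elety = "OW", resid = "HOH", chain = "W",
               resno = seq_len(nw), elem = "O", stringsAsFactors = FALSE)
  }
  top <- rbind(helix_top, ring_top, hb_top, wat_top)
  top$eleno <- seq_len(nrow(top))
  n_helix <- nrow(helix_top)
  n_ring <- if (is.null(ring_top)) 0L else nrow(ring_top)
  n_hb <- if (is.null(hb_top)) 0L else nrow(hb_top)
  blocks <- list(helix = seq_len(n_helix),
                 ring = n_helix + seq_len(n_ring),
                 hbond = n_helix + n_ring + seq_len(n_hb),
                 water = n_helix + n_ring + n_hb +
                   seq_len(if (is.null(wat_top)) 0L else nrow(wat_top)))
  list(top = top, blocks = blocks)
}

# reference coordinates (n_atoms x 3) for a given gate aperture
reference_coords <- function(spec, aperture, ring_radius_c = 1.70) {
  nres <- spec$helix_residues
  helix0 <- orient_helix(build_helix_backbone(nres), nres)
  tilt <- rot_x(deg2rad(spec$helix_tilt_tangential_deg)) %*%
    rot_y(deg2rad(spec$helix_tilt_radial_deg))
  helix1 <- helix0 %*% t(tilt)
  helix1[, 1] <- helix1[, 1] + spec$helix_radius_from_axis
  per_chain <- lapply(seq_len(spec$n_subunits) - 1L, function(k) {
    helix1 %*% t(rot_z(2 * pi * k / spec$n_subunits))
  })
  coords <- do.call(rbind, per_chain)
  if (spec$gate_ring_atoms > 0L) {
    th <- 2 * pi * (seq_len(spec$gate_ring_atoms) - 1L) / spec$gate_ring_atoms
    rr <- aperture + ring_radius_c
    coords <- rbind(coords, cbind(rr * cos(th), rr * sin(th), spec$gate_z))
  }
  nhb <- length(spec$planted_hbonds)
  if (nhb > 0L) {
    for (b in seq_len(nhb)) {
      g <- hbond_triplet_coords(spec, b, on = TRUE)
      coords <- rbind(coords, g)
    }
  }
  nw <- spec$n_waters_traversing + spec$n_waters_blocked
  if (nw > 0L) {
    lower <- spec$gate_z - 5
    wpos <- t(vapply(seq_len(nw), function(w) {
      ang <- 2 * pi * w / max(nw, 1L)
      c(0.3 * cos(ang), 0.3 * sin(ang), lower - 4)
    }, numeric(3)))
    coords <- rbind(coords, wpos)
  }
  coords
}

# D, H, A coordinates for planted bond b (rows: D, H, A)
hbond_triplet_coords <- function(spec, b, on) {
  hb <- spec$planted_hbonds[[b]]
  d_on <- if (is.null(hb$d_on)) 2.8 else hb$d_on
  angle_on <- if (is.null(hb$angle_on)) 180 else hb$angle_on
  d_off <- if (is.null(hb$d_off)) 4.5 else hb$d_off
  ang <- 2 * pi * (b - 1) / max(length(spec$planted_hbonds), 1L)
  base <- c(30 * cos(ang), 30 * sin(ang), spec$gate_z - 10 + 4 * b)
  u <- c(cos(ang + pi / 4), sin(ang + pi / 4), 0)  # bond direction
  w <- c(0, 0, 1)                                  # in-plane normal for bent bonds
  D <- base
  H <- base + 1.0 * u
  A <- if (on) {
    if (abs(angle_on - 180) < 1e-9) {
      base + d_on * u
    } else {
      # triangle D-H-A with |DH| = 1, angle at H = angle_on, |AD| = d_on
      alpha <- deg2rad(angle_on)
      rho <- cos(alpha) + sqrt(cos(alpha)^2 - 1 + d_on^2)
      dir <- -cos(alpha) * u + sin(alpha) * w  # angle alpha away from H->D
      H + rho * unit_vec(dir)
    }
  } else {
    base + d_off * u
  }
  rbind(D, H, A)
}

#' Build the reference structure of a synthetic channel
#'
#' Places `n_subunits` ideal alpha-helical backbone traces with exact
#' n-fold symmetry about the z axis, a gate ring whose axis clearance
#' equals `gate_aperture` analytically (ring radius = aperture + the Bondi
#' carbon radius 1.70), planted hydrogen-bond triplets in their formed
#' geometry, and waters at their starting positions.
#'
#' @param spec a [channel_spec()].
#' @return a [structure_frame()].
#' @export
build_reference <- function(spec) {
  validate_channel_spec(spec)
  lay <- channel_topology(spec)
  coords <- reference_coords(spec, aperture = spec$gate_aperture)
  structure_frame(lay$top, mat2vec(coords))
}

#' Simulate a synthetic trajectory
#'
#' Helix atoms are displaced from the reference by i.i.d. Gaussian noise
#' with the per-coordinate sigma of their residue. The gate ring follows a
#' two-level aperture schedule when `gate_open_fraction > 0` (the exact
#' open-frame count is planted). Planted hydrogen bonds satisfy their
#' geometric criteria in exactly `round(occupancy * n_frames)` frames.
#' Traversing waters move monotonically from below the lower gate plane
#' (gate_z - 5) to above the upper gate plane (gate_z + 5); blocked waters
#' oscillate across the lower plane only.
#'
#' @param spec a [channel_spec()].
#' @return a [trajectory()] with a ground-truth `manifest` attribute (see
#'   [truth_manifest()]).
#' @export
simulate_trajectory <- function(spec) {
  validate_channel_spec(spec)
  lay <- channel_topology(spec)
  nf <- spec$n_frames
  natom <- nrow(lay$top)
  withr::with_seed(spec$seed, {
    # gate aperture schedule (exact open count)
    n_open <- round(spec$gate_open_fraction * nf)
    open_frames <- if (n_open > 0L) sort(sample.int(nf, n_open)) else integer(0)
    aperture <- rep(spec$gate_aperture, nf)
    aperture[open_frames] <- spec$gate_aperture_open
    # planted bond schedules (exact per-bond counts)
    hb_on <- lapply(spec$planted_hbonds, function(hb) {
      k <- round(hb$occupancy * nf)
      if (k > 0L) sort(sample.int(nf, k)) else integer(0)
    })
    ref <- reference_coords(spec, aperture = spec$gate_aperture)
    xyz <- matrix(NA_real_, nf, 3L * natom)
    # per-atom sigma for helix atoms
    sig_res <- rep(spec$per_residue_sigma, length.out = spec$helix_residues)
    sig_atom <- rep(rep(sig_res, each = 4L), times = spec$n_subunits)
    hix <- lay$blocks$helix
    lower <- spec$gate_z - 5
    upper <- spec$gate_z + 5
    nw_t <- spec$n_waters_traversing
    nw_b <- spec$n_waters_blocked
    for (f in seq_len(nf)) {
      fr <- ref
      if (length(hix) && any(sig_atom > 0)) {
        fr[hix, ] <- fr[hix, ] +
          matrix(stats::rnorm(length(hix) * 3L, sd = sig_atom), ncol = 3L)
      }
      if (spec$gate_ring_atoms > 0L) {
        th <- 2 * pi * (seq_len(spec$gate_ring_atoms) - 1L) / spec$gate_ring_atoms
        rr <- aperture[f] + 1.70
        fr[lay$blocks$ring, ] <- cbind(rr * cos(th), rr * sin(th), spec$gate_z)
      }
      if (length(spec$planted_hbonds)) {
        for (b in seq_along(spec$planted_hbonds)) {
          rows <- lay$blocks$hbond[(3L * (b - 1L) + 1L):(3L * b)]
          fr[rows, ] <- hbond_triplet_coords(spec, b, on = f %in% hb_on[[b]])
        }
      }
      if (nw_t + nw_b > 0L) {
        wrows <- lay$blocks$water
        prog <- if (nf > 1L) (f - 1) / (nf - 1) else 0.5
        for (w in seq_len(nw_t + nw_b)) {
          ang <- 2 * pi * w / (nw_t + nw_b)
          lat <- c(0.3 * cos(ang), 0.3 * sin(ang))
          z <- if (w <= nw_t) {
            (lower - 4) + prog * ((upper + 4) - (lower - 4))
          } else {
            lower - 2.5 + 3 * sin(2 * pi * (3 * prog + w / 7))
          }
          fr[wrows[w], ] <- c(lat, z)
        }
      }
      xyz[f, ] <- mat2vec(fr)
    }
    traj <- trajectory(lay$top, xyz, stride_ps = spec$stride_ps)
    attr(traj, "manifest") <- build_manifest(spec, nf, aperture, hb_on)
    traj
  })
}

build_manifest <- function(spec, nf, aperture, hb_on) {
  hb_truth <- if (length(spec$planted_hbonds)) {
    data.frame(
      label = vapply(seq_along(spec$planted_hbonds), function(b) {
        lb <- spec$planted_hbonds[[b]]$label
        if (is.null(lb)) paste0("bond", b) else lb
      }, character(1)),
      donor_resno = seq_along(spec$planted_hbonds),
      acceptor_resno = 100L + seq_along(spec$planted_hbonds),
      occupancy = vapply(hb_on, length, integer(1)) / nf,
      stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(0), donor_resno = integer(0),
               acceptor_resno = integer(0), occupancy = numeric(0))
  }
  list(label = spec$label,
       seed = spec$seed,
       n_frames = nf,
       stride_ps = spec$stride_ps,
       n_subunits = spec$n_subunits,
       chains = LETTERS[seq_len(spec$n_subunits)],
       first_resno = spec$first_resno,
       last_resno = spec$first_resno + spec$helix_residues - 1L,
       per_residue_sigma = rep(spec$per_residue_sigma,
                               length.out = spec$helix_residues),
       tilt_tangential_deg = spec$helix_tilt_tangential_deg,
       tilt_radial_deg = spec$helix_tilt_radial_deg,
       gate_z = spec$gate_z,
       upper_gate_z = spec$gate_z + 5,
       lower_gate_z = spec$gate_z - 5,
       aperture_closed = spec$gate_aperture,
       aperture_open = spec$gate_aperture_open,
       gate_open_fraction_planted = sum(aperture == spec$gate_aperture_open &
                                          spec$gate_open_fraction > 0) / nf,
       permeable_fraction_at_1.15 = mean(aperture > 1.15),
       mean_aperture = mean(aperture),
       n_waters_traversing = spec$n_waters_traversing,
       n_waters_blocked = spec$n_waters_blocked,
       hbonds = hb_truth)
}

#' Ground-truth manifest of a synthetic trajectory
#'
#' @param traj a trajectory produced by [simulate_trajectory()].
#' @return the manifest list recorded by the generator.
#' @export
truth_manifest <- function(traj) {
  m <- attr(traj, "manifest")
  if (is.null(m)) stop("trajectory carries no ground-truth manifest")
  m
}

#' Write a synthetic dataset to disk
#'
#' Writes reference PDB, DCD trajectory and the JSON ground-truth manifest.
#'
#' @param traj trajectory from [simulate_trajectory()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, named list of the three paths.
#' @export
write_dataset <- function(traj, dir, prefix = "channel") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(topology = file.path(dir, paste0(prefix, ".pdb")),
                trajectory = file.path(dir, paste0(prefix, ".dcd")),
                manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  write_trajectory(traj, paths$topology, paths$trajectory)
  jsonlite::write_json(truth_manifest(traj), paths$manifest,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Generate a matched pair of state trajectories
#'
#' Two trajectories sharing one topology but differing in gate aperture
#' schedule, tilt angles, fluctuation profile and planted hydrogen bonds;
#' the differences are recorded as ground truth for recovery tests.
#'
#' @param spec_closed,spec_open [channel_spec()]s for the two states. They
#'   must agree in every topology-determining field.
#' @return list with the two trajectories (named by their labels) and a
#'   `truth` list of planted state differences.
#' @export
morph_states <- function(spec_closed, spec_open) {
  topo_fields <- c("n_subunits", "helix_residues", "first_resno",
                   "gate_ring_atoms", "n_frames")
  for (f in topo_fields) {
    if (!identical(spec_closed[[f]], spec_open[[f]]))
      stop("topology mismatch between specs in field '", f, "'")
  }
  if (spec_closed$n_waters_traversing + spec_closed$n_waters_blocked !=
        spec_open$n_waters_traversing + spec_open$n_waters_blocked)
    stop("topology mismatch between specs in field 'total waters'")
  if (length(spec_closed$planted_hbonds) != length(spec_open$planted_hbonds))
    stop("topology mismatch: different numbers of planted hydrogen bonds")
  t1 <- simulate_trajectory(spec_closed)
  t2 <- simulate_trajectory(spec_open)
  m1 <- truth_manifest(t1); m2 <- truth_manifest(t2)
  truth <- list(
    labels = c(m1$label, m2$label),
    twist_difference_deg = m2$tilt_tangential_deg - m1$tilt_tangential_deg,
    permeable_fraction = c(m1$permeable_fraction_at_1.15,
                           m2$permeable_fraction_at_1.15),
    hbond_occupancy_delta = if (nrow(m1$hbonds)) {
      m1$hbonds$occupancy - m2$hbonds$occupancy
    } else {
      numeric(0)
    },
    sigma_difference = m2$per_residue_sigma - m1$per_residue_sigma)
  out <- list(t1, t2)
  names(out) <- make.unique(c(m1$label, m2$label))
  out$truth <- truth
  out
}

#' Study-condition specification pair
#'
#' The default synthetic two-state experiment the package is exercised on:
#' a reduced/closed state (starting aperture 0.59 A, S6-like tangential
#' tilt 25 deg, 15% of frames open) versus an oxidized/partially open state
#' (open aperture 2.31 A, tilt 30.7 deg, 60% of frames open), with one
#' redox-sensitive planted hydrogen bond (occupancy 0.85 reduced vs 0.05
#' oxidized) and one redox-insensitive bond (0.50 in both).
#'
#' @param seed base RNG seed; the oxidized state uses `seed + 1`.
#' @param n_frames frames per state.
#' @return list with `reduced` and `oxidized` [channel_spec()]s.
#' @export
study_specs <- function(seed = 42L, n_frames = 2000L) {
  hb_red <- list(list(occupancy = 0.85, label = "gateK-gateM"),
                 list(occupancy = 0.50, label = "control"))
  hb_oxi <- list(list(occupancy = 0.05, label = "gateK-gateM"),
                 list(occupancy = 0.50, label = "control"))
  list(
    reduced = channel_spec(helix_tilt_tangential_deg = 25,
                           gate_aperture = 0.59, gate_aperture_open = 2.31,
                           gate_open_fraction = 0.15,
                           planted_hbonds = hb_red,
                           n_waters_traversing = 2L, n_waters_blocked = 8L,
                           n_frames = n_frames, seed = seed,
                           label = "reduced"),
    oxidized = channel_spec(helix_tilt_tangential_deg = 30.7,
                            gate_aperture = 0.59, gate_aperture_open = 2.31,
                            gate_open_fraction = 0.60,
                            planted_hbonds = hb_oxi,
                            n_waters_traversing = 8L, n_waters_blocked = 2L,
                            n_frames = n_frames, seed = seed + 1L,
                            label = "oxidized"))
}
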