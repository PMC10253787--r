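# HOLE-style pore radius profiling along the channel axis, minimal-radius
# time series, water-permeability classification and permeation counting.
#
# Structures are assumed pre-oriented with the pore axis along z (the
# synthetic generator guarantees this; see orient_pore_axis() for real
# structures).

#' Pore radius profile of one frame
#'
#' For each z on the grid, finds the radius of the largest probe sphere
#' whose centre lies in that z plane within `lateral_bound` of the running
#' centre line, i.e. maximises `min_i(|p - atom_i| - vdw_i)`. The search is
#' an exhaustive coarse lateral grid refined by a shrinking-step pattern
#' search (deterministic; no annealing). Radii are capped at `max_radius`
#' and flagged. Slices follow the previous slice's optimal centre,
#' HOLE-style.
#'
#' @param frame a [structure_frame()].
#' @param radii per-atom van der Waals radii; default [assign_vdw()] with
#'   the Bondi table on the `sel` atoms.
#' @param sel atoms forming the pore wall (default `"protein"`; waters and
#'   ions should be excluded).
#' @param z_range length-2 numeric, axial range (default: z range of the
#'   selected atoms).
#' @param z_step grid spacing along z, Angstrom.
#' @param max_radius search cap, Angstrom.
#' @param lateral_bound maximal lateral distance of the probe centre from
#'   the running centre, Angstrom.
#' @param coarse_step coarse lateral grid spacing, Angstrom.
#' @param tol pattern-search termination step, Angstrom.
#' @param center_start initial centre guess (x, y) for the first slice.
#' @return data.frame with columns `z`, `radius`, `x`, `y`, `capped`.
#' @export
pore_radius_profile <- function(frame, radii = NULL, sel = "protein",
                                z_range = NULL, z_step = 0.25,
                                max_radius = 10, lateral_bound = 8,
                                coarse_step = 0.25, tol = 1e-3,
                                center_start = c(0, 0)) {
  stopifnot(inherits(frame, "structure_frame"))
  idx <- as_indices(sel, frame)
  co <- frame_coords(frame)[idx, , drop = FALSE]
  if (is.null(radii)) {
    radii <- assign_vdw(frame)[idx]
  } else if (length(radii) == n_atoms(frame)) {
    radii <- radii[idx]
  } else if (length(radii) != length(idx)) {
    stop("radii must cover all atoms or exactly the selected atoms")
  }
  if (is.null(z_range)) z_range <- range(co[, 3])
  zs <- seq(z_range[1], z_range[2], by = z_step)
  out <- matrix(NA_real_, length(zs), 4L)
  cx <- center_start[1]; cy <- center_start[2]
  for (k in seq_along(zs)) {
    r <- .pore_slice_cpp(co, radii, zs[k], cx, cy,
                         lateral_bound, coarse_step, max_radius, tol)
    out[k, ] <- r
    if (r[4] < 0.5) { cx <- r[2]; cy <- r[3] } else { cx <- center_start[1]; cy <- center_start[2] }
  }
  data.frame(z = zs, radius = out[, 1], x = out[, 2], y = out[, 3],
             capped = out[, 4] > 0.5)
}

#' Minimal pore radius time series
#'
#' Profiles every frame of a trajectory and extracts the per-frame minimum
#' radius and its axial location (ties broken towards the smallest z).
#'
#' @param traj a [trajectory()].
#' @param ... passed to [pore_radius_profile()] (`sel`, `z_range`,
#'   `z_step`, `max_radius`, ...).
#' @param vdw a [vdw_table()] used to assign radii once for all frames.
#' @param sel pore-wall selection, resolved once.
#' @return object of class `pore_profile`: list with `z_grid`, `radius`
#'   (frames x z matrix), `capped` (logical matrix), `min_radius`,
#'   `min_radius_z` (per-frame vectors) and `any_capped` per frame.
#' @export
min_radius_series <- function(traj, sel = "protein", vdw = vdw_table(), ...) {
  stopifnot(inherits(traj, "trajectory"))
  sel_obj <- if (inherits(sel, "selection")) sel else resolve_selection(traj, sel)
  radii_all <- assign_vdw(traj, vdw)
  nf <- n_frames(traj)
  first <- pore_radius_profile(get_frame(traj, 1L), radii = radii_all,
                               sel = sel_obj, ...)
  nz <- nrow(first)
  rad <- matrix(NA_real_, nf, nz)
  cap <- matrix(FALSE, nf, nz)
  rad[1L, ] <- first$radius; cap[1L, ] <- first$capped
  if (nf > 1L) {
    for (f in 2:nf) {
      p <- pore_radius_profile(get_frame(traj, f), radii = radii_all,
                               sel = sel_obj, ...)
      rad[f, ] <- p$radius; cap[f, ] <- p$capped
    }
  }
  min_i <- apply(rad, 1L, which.min)
  structure(list(z_grid = first$z,
                 radius = rad,
                 capped = cap,
                 min_radius = rad[cbind(seq_len(nf), min_i)],
                 min_radius_z = first$z[min_i],
                 any_capped = apply(cap, 1L, any)),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("pore_profile:", nrow(x$radius), "frames,", length(x$z_grid),
      "z slices; min radius", round(min(x$min_radius), 3), "-",
      round(max(x$min_radius), 3), "A\n")
  invisible(x)
}

#' Water-permeable fraction of frames
#'
#' Fraction of frames whose minimal pore radius strictly exceeds the
#' water-permeability threshold (default 1.15 Angstrom).
#'
#' @param series a `pore_profile` from [min_radius_series()] or a numeric
#'   vector of per-frame minimal radii.
#' @param threshold radius threshold, Angstrom.
#' @return object of class `permeability_stats`: list with
#'   `permeable_fraction`, `threshold`, `n_frames`.
#' @export
permeable_fraction <- function(series, threshold = 1.15) {
  r <- if (inherits(series, "pore_profile")) series$min_radius else as.numeric(series)
  if (length(r) == 0L) stop("empty minimal-radius series")
  structure(list(permeable_fraction = mean(r > threshold),
                 threshold = threshold,
                 n_frames = length(r)),
            class = "permeability_stats")
}

#' @export
print.permeability_stats <- function(x, ...) {
  cat(sprintf("permeable fraction: %.3f (min radius > %.2f A, %d frames)\n",
              x$permeable_fraction, x$threshold, x$n_frames))
  invisible(x)
}

#' Count complete water permeation events
#'
#' A permeation event is one complete traversal of both gate planes by one
#' water, entered from one side and exited on the other, while its lateral
#' distance from the pore (z) axis stays within `lateral_bound` between the
#' crossings. Partial entries and oscillations across a single plane do not
#' count.
#'
#' @param traj a [trajectory()].
#' @param water_sel selection of the water oxygen atoms (default resname
#'   based).
#' @param upper_gate_z,lower_gate_z gate plane heights, Angstrom
#'   (`upper_gate_z > lower_gate_z`).
#' @param lateral_bound maximal lateral distance from the axis, Angstrom.
#' @return object of class `water_flux`: list with `n_permeation_events`
#'   and `events` (data.frame: water atom index, resno, entry_frame,
#'   exit_frame, direction `"up"`/`"down"`).
#' @export
count_permeations <- function(traj, water_sel = "water, element O",
                              upper_gate_z, lower_gate_z, lateral_bound = 8) {
  stopifnot(inherits(traj, "trajectory"))
  if (!(upper_gate_z > lower_gate_z))
    stop("gate planes must satisfy upper_gate_z > lower_gate_z")
  idx <- as_indices(water_sel, traj)
  events <- list()
  for (i in idx) {
    xs <- traj$xyz[, 3L * i - 2L]
    ys <- traj$xyz[, 3L * i - 1L]
    zs <- traj$xyz[, 3L * i]
    lat_ok <- sqrt(xs^2 + ys^2) <= lateral_bound
    zone <- ifelse(zs > upper_gate_z, 1L, ifelse(zs < lower_gate_z, -1L, 0L))
    side <- NA_integer_   # side the water entered from
    entry <- NA_integer_
    valid <- FALSE
    for (f in seq_along(zone)) {
      z <- zone[f]
      if (z == 0L) {
        if (is.na(side)) next            # started between the planes
        valid <- valid && lat_ok[f]
      } else if (is.na(side) || z == side) {
        side <- z; entry <- f; valid <- TRUE
      } else {
        # reached the opposite side; direct jumps (-1 -> +1) also land here
        if (valid) {
          events[[length(events) + 1L]] <- data.frame(
            atom = i, resno = traj$top$resno[i],
            entry_frame = entry, exit_frame = f,
            direction = if (side == -1L) "up" else "down",
            stringsAsFactors = FALSE)
        }
        side <- z; entry <- f; valid <- TRUE
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(atom = integer(0), resno = integer(0),
               entry_frame = integer(0), exit_frame = integer(0),
               direction = character(0), stringsAsFactors = FALSE)
  structure(list(n_permeation_events = nrow(ev), events = ev,
                 upper_gate_z = upper_gate_z, lower_gate_z = lower_gate_z,
                 lateral_bound = lateral_bound),
            class = "water_flux")
}

#' @export
print.water_flux <- function(x, ...) {
  cat("water_flux:", x$n_permeation_events, "complete permeation event(s)\n")
  invisible(x)
}

#' Align the pore axis of a structure to z
#'
#' For real structures not already oriented: translates the centroid of the
#' pore-lining selection to the origin (x, y) and rotates the dominant
#' inertia axis of that selection onto z.
#'
#' @param frame a [structure_frame()].
#' @param pore_sel selection of pore-lining Calpha atoms.
#' @return the re-oriented `structure_frame`.
#' @export
orient_pore_axis <- function(frame, pore_sel = "calpha") {
  idx <- as_indices(pore_sel, frame)
  co <- frame_coords(frame)
  cen <- colMeans(co[idx, , drop = FALSE])
  ax <- eigen(stats::cov(co[idx, , drop = FALSE]), symmetric = TRUE)$vectors[, 1]
  if (ax[3] < 0) ax <- -ax
  z <- c(0, 0, 1)
  v <- c(ax[2] * z[3] - ax[3] * z[2],
         ax[3] * z[1] - ax[1] * z[3],
         ax[1] * z[2] - ax[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(ax * z)
  R <- if (s < 1e-12) diag(3) else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  structure_frame(frame$top, mat2vec(sweep(co, 2, cen) %*% t(R)),
                  frame_time = frame$frame_time)
}
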