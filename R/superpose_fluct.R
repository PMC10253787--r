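# Least-squares superposition, RMSD/RMSF, and the fractional RMSF
# comparison between two states.

#' Superpose a trajectory onto a reference
#'
#' Each frame is rigid-body transformed to minimise the RMSD over the fit
#' selection (Kabsch least-squares rotation, via [bio3d::fit.xyz()]); the
#' transformation is applied to all atoms.
#'
#' @param traj a [trajectory()].
#' @param fit a [resolve_selection()] selection or selection text; default
#'   the backbone of all residues.
#' @param reference `"first_frame"` or a [structure_frame()] sharing the
#'   trajectory topology.
#' @return the superposed trajectory.
#' @export
superpose <- function(traj, fit = "backbone", reference = "first_frame") {
  stopifnot(inherits(traj, "trajectory"))
  idx <- as_indices(fit, traj)
  if (length(idx) < 3L)
    stop("degenerate fit: need at least 3 fit atoms, got ", length(idx))
  ref_xyz <- if (identical(reference, "first_frame")) {
    traj$xyz[1L, ]
  } else if (inherits(reference, "structure_frame")) {
    reference$xyz
  } else {
    stop("reference must be \"first_frame\" or a structure_frame")
  }
  # collinearity check on the fit atoms of the reference
  m <- vec2mat(ref_xyz)[idx, , drop = FALSE]
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-10 * max(ev[1], 1))
    stop("degenerate fit: fit atoms are (nearly) collinear")
  xi <- xyz_ind(idx)
  fitted <- bio3d::fit.xyz(fixed = ref_xyz, mobile = traj$xyz,
                           fixed.inds = xi, mobile.inds = xi)
  if (!is.matrix(fitted)) fitted <- matrix(fitted, nrow = 1)
  out <- trajectory(traj$top, fitted, stride_ps = traj$stride_ps)
  attr(out, "manifest") <- attr(traj, "manifest")
  out
}

#' Per-frame RMSD against a reference
#'
#' `RMSD_t = sqrt(mean_i |r_i(t) - r_i(ref)|^2)` over the selected atoms.
#' The trajectory is assumed already superposed (see [superpose()]).
#'
#' @inheritParams superpose
#' @param sel selection (object, text or indices) over which to average.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, sel = "backbone", reference = "first_frame") {
  stopifnot(inherits(traj, "trajectory"))
  idx <- as_indices(sel, traj)
  ref_xyz <- if (identical(reference, "first_frame")) traj$xyz[1L, ]
             else reference$xyz
  xi <- xyz_ind(idx)
  d <- sweep(traj$xyz[, xi, drop = FALSE], 2, ref_xyz[xi])
  sqrt(rowSums(d^2) / length(idx))
}

#' Per-residue RMSF profile
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` for one representative atom
#' per residue (default Calpha) within the analysis selection. The
#' trajectory should be superposed first.
#'
#' @param traj superposed [trajectory()].
#' @param sel selection restricting the analysed residues (default all).
#' @param atom representative atom name per residue.
#' @param state_label label stored on the profile.
#' @param average_chains if `TRUE`, RMSF values are averaged across chains
#'   per residue number.
#' @return object of class `rmsf_profile`: data.frame with `chain`,
#'   `resno`, `rmsf` plus attributes.
#' @export
rmsf_profile <- function(traj, sel = NULL, atom = "CA",
                         state_label = "state", average_chains = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$top
  idx <- if (is.null(sel)) seq_len(nrow(top)) else as_indices(sel, traj)
  idx <- idx[top$elety[idx] == atom]
  if (length(idx) == 0L)
    stop("no '", atom, "' atoms in the RMSF selection")
  if (nrow(traj$xyz) < 2L)
    warning("single-frame trajectory: RMSF is identically zero")
  rmsf <- vapply(idx, function(i) {
    m <- traj$xyz[, (3L * i - 2L):(3L * i), drop = FALSE]
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  }, numeric(1))
  out <- data.frame(chain = top$chain[idx], resno = top$resno[idx],
                    rmsf = rmsf, stringsAsFactors = FALSE)
  if (average_chains) {
    agg <- stats::aggregate(rmsf ~ resno, data = out, FUN = mean)
    out <- data.frame(chain = "*", resno = agg$resno, rmsf = agg$rmsf,
                      stringsAsFactors = FALSE)
  }
  structure(out, class = c("rmsf_profile", "data.frame"),
            state_label = state_label, atom = atom)
}

#' Fractional RMSF difference between two states
#'
#' Per residue, `delta_frac = 2 * (RMSF1 - RMSF2) / (RMSF1 + RMSF2)`,
#' a unitless quantity bounded in \[-2, 2\]; the degenerate case
#' `RMSF1 + RMSF2 = 0` is set to 0 by convention.
#'
#' @param p1,p2 [rmsf_profile()]s over identical residue sets.
#' @return object of class `fluct_comparison`: data.frame with `chain`,
#'   `resno`, `rmsf1`, `rmsf2`, `delta_frac`.
#' @export
delta_rmsf <- function(p1, p2) {
  stopifnot(inherits(p1, "rmsf_profile"), inherits(p2, "rmsf_profile"))
  if (!identical(p1$chain, p2$chain) || !identical(p1$resno, p2$resno))
    stop("RMSF profiles are not aligned: residue sets differ")
  s <- p1$rmsf + p2$rmsf
  delta <- ifelse(s > 0, 2 * (p1$rmsf - p2$rmsf) / s, 0)
  structure(data.frame(chain = p1$chain, resno = p1$resno,
                       rmsf1 = p1$rmsf, rmsf2 = p2$rmsf,
                       delta_frac = delta, stringsAsFactors = FALSE),
            class = c("fluct_comparison", "data.frame"),
            state_labels = c(attr(p1, "state_label"),
                             attr(p2, "state_label")))
}
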