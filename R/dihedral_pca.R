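# Backbone dihedral extraction, circular-variable covariance PCA,
# projections, and free-energy surface estimation.

#' Extract backbone phi/psi dihedral series
#'
#' Standard phi (C', N, CA, C) and psi (N, CA, C, N') torsions from
#' consecutive backbone atoms, per frame, wrapped to (-180, 180]. Terminal
#' residues lacking a dihedral are excluded; peptide bonds with a C-N
#' distance above 2.0 Angstrom in the time-mean structure are treated as
#' chain breaks and the spanning dihedrals skipped with a warning.
#'
#' @param traj a [trajectory()].
#' @param sel optional selection restricting the residues analysed.
#' @return object of class `dihedral_series`: list with `angles` (frames x
#'   n_dihedrals matrix, degrees), `type` (`"phi"`/`"psi"`), `resno`,
#'   `chain`.
#' @export
extract_dihedrals <- function(traj, sel = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$top
  idx_all <- if (is.null(sel)) seq_len(nrow(top)) else as_indices(sel, traj)
  cols <- list(); type <- character(0); resno <- integer(0); chain <- character(0)
  ref <- vec2mat(colMeans(traj$xyz))  # bond check on the mean structure
  n_breaks <- 0L
  for (ch in unique(top$chain[idx_all])) {
    sub <- idx_all[top$chain[idx_all] == ch]
    res_list <- sort(unique(top$resno[sub]))
    bb <- function(rn, name) {
      i <- sub[top$resno[sub] == rn & top$elety[sub] == name]
      if (length(i) == 1L) i else NA_integer_
    }
    Ni <- vapply(res_list, bb, integer(1), name = "N")
    CAi <- vapply(res_list, bb, integer(1), name = "CA")
    Ci <- vapply(res_list, bb, integer(1), name = "C")
    nres <- length(res_list)
    if (nres < 2L) next
    bonded <- rep(FALSE, nres - 1L)  # peptide bond i -> i+1 intact?
    for (i in seq_len(nres - 1L)) {
      if (!is.na(Ci[i]) && !is.na(Ni[i + 1]) && res_list[i + 1] == res_list[i] + 1L) {
        bonded[i] <- sqrt(sum((ref[Ci[i], ] - ref[Ni[i + 1], ])^2)) <= 2.0
        if (!bonded[i]) n_breaks <- n_breaks + 1L
      }
    }
    tors <- function(i1, i2, i3, i4) {
      dihedral_angle(vec2mat_cols(traj$xyz, i1), vec2mat_cols(traj$xyz, i2),
                     vec2mat_cols(traj$xyz, i3), vec2mat_cols(traj$xyz, i4))
    }
    for (i in seq_len(nres)) {
      ok4 <- function(...) !anyNA(c(...))
      if (i > 1L && bonded[i - 1L] && ok4(Ci[i - 1], Ni[i], CAi[i], Ci[i])) {
        cols[[length(cols) + 1L]] <- wrap180(tors(Ci[i - 1], Ni[i], CAi[i], Ci[i]))
        type <- c(type, "phi"); resno <- c(resno, res_list[i]); chain <- c(chain, ch)
      }
      if (i < nres && bonded[i] && ok4(Ni[i], CAi[i], Ci[i], Ni[i + 1])) {
        cols[[length(cols) + 1L]] <- wrap180(tors(Ni[i], CAi[i], Ci[i], Ni[i + 1]))
        type <- c(type, "psi"); resno <- c(resno, res_list[i]); chain <- c(chain, ch)
      }
    }
  }
  if (n_breaks > 0L)
    warning(n_breaks, " chain break(s) (C-N distance > 2.0 A): spanning ",
            "dihedrals skipped")
  if (length(cols) == 0L) stop("no complete backbone dihedral found")
  structure(list(angles = do.call(cbind, cols), type = type,
                 resno = resno, chain = chain),
            class = "dihedral_series")
}

# coordinates of one atom across frames as n_frames x 3 matrix
vec2mat_cols <- function(xyz, i) {
  xyz[, (3L * i - 2L):(3L * i), drop = FALSE]
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat("dihedral_series:", nrow(x$angles), "frames x", ncol(x$angles),
      "dihedrals (", sum(x$type == "phi"), "phi,", sum(x$type == "psi"),
      "psi )\n")
  invisible(x)
}

#' Dihedral principal component analysis
#'
#' Each angle theta is mapped to the pair (sin theta, cos theta) to remove
#' the -180/180 periodicity (standard dPCA); the covariance matrix of the
#' stacked variables is eigen-decomposed and frames are projected onto the
#' top components. Set `circular = FALSE` to run the PCA on the raw wrapped
#' angles instead, for comparison.
#'
#' @param series a [extract_dihedrals()] result, or a plain frames x
#'   angles matrix of dihedrals in degrees.
#' @param n_components number of components to report/project.
#' @param circular use the sin/cos mapping (default) or raw angles.
#' @return object of class `dpca_result`: list with `eigenvalues`
#'   (descending, >= 0), `eigenvectors` (orthonormal columns),
#'   `projections` (frames x n_components), `explained_variance`
#'   (fractions), `total_variance`.
#' @export
dpca <- function(series, n_components = 2L, circular = TRUE) {
  ang <- if (inherits(series, "dihedral_series")) series$angles else as.matrix(series)
  if (nrow(ang) < 2L) stop("dihedral PCA needs at least 2 frames")
  X <- if (circular) {
    th <- deg2rad(ang)
    cbind(sin(th), cos(th))
  } else {
    ang
  }
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  nc <- min(n_components, length(ev))
  Xc <- sweep(X, 2, colMeans(X))
  proj <- Xc %*% e$vectors[, seq_len(nc), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(nc))
  tot <- sum(ev)
  structure(list(eigenvalues = ev,
                 eigenvectors = e$vectors,
                 projections = proj,
                 explained_variance = if (tot > 0) ev[seq_len(nc)] / tot
                                      else rep(0, nc),
                 total_variance = tot,
                 circular = circular),
            class = "dpca_result")
}

#' @export
print.dpca_result <- function(x, ...) {
  cat("dpca_result:", nrow(x$projections), "frames;",
      "PC1/PC2 explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Free-energy surface over two principal components
#'
#' 2D histogram of the projections converted to
#' `F = -kB T ln(count / max_count)` in kcal/mol. Empty bins are `NA`
#' (undefined) rather than infinite; the lowest occupied bin has F = 0.
#'
#' @param proj a [dpca()] result or a 2-column matrix of projections.
#' @param bins number of bins per axis.
#' @param temperature temperature in K (default 303, a typical simulation
#'   temperature for these systems).
#' @return object of class `free_energy_surface`: list with `x_mid`,
#'   `y_mid` (bin centres), `F` (bins x bins, kcal/mol), `counts`,
#'   `temperature`, `kT`.
#' @export
free_energy_surface <- function(proj, bins = 50L, temperature = 303) {
  if (inherits(proj, "dpca_result")) proj <- proj$projections
  proj <- as.matrix(proj)
  if (ncol(proj) < 2L) stop("need two projection columns (PC1, PC2)")
  kB <- 0.0019872041  # kcal/mol/K
  kT <- kB * temperature
  rng <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r + c(-0.5, 0.5) else r
  }
  xb <- seq(rng(proj[, 1])[1], rng(proj[, 1])[2], length.out = bins + 1L)
  yb <- seq(rng(proj[, 2])[1], rng(proj[, 2])[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(proj[, 1], xb, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(proj[, 2], yb, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (k in seq_len(nrow(proj))) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  }
  Fmat <- matrix(NA_real_, bins, bins)
  occ <- counts > 0L
  Fmat[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(x_mid = (xb[-1] + xb[-length(xb)]) / 2,
                 y_mid = (yb[-1] + yb[-length(yb)]) / 2,
                 F = Fmat, counts = counts,
                 temperature = temperature, kT = kT),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("free_energy_surface:", sum(x$counts > 0), "occupied bins; F range 0 -",
      round(max(x$F, na.rm = TRUE), 3), "kcal/mol at", x$temperature, "K\n")
  invisible(x)
}

#' @describeIn free_energy_surface filled-contour plot of the surface.
#' @param x a `free_energy_surface`.
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.free_energy_surface <- function(x, ...) {
  graphics::filled.contour(x$x_mid, x$y_mid, x$F,
                           color.palette = function(n) grDevices::hcl.colors(n, "Blue-Red"),
                           xlab = "PC1", ylab = "PC2", ...)
  invisible(x)
}
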