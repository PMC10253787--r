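# Radius-of-gyration series, helix twist angles, pairwise Calpha distance
# matrices and state distance-difference / correlation maps.

#' Radius of gyration time series
#'
#' `Rg = sqrt(mean_i |r_i - centroid|^2)` over the selected atoms,
#' unweighted, per frame.
#'
#' @param traj a [trajectory()].
#' @param sel selection of (heavy) atoms defining the region.
#' @param label region label stored on the series.
#' @return object of class `gyration_series`: data.frame with `frame`,
#'   `rg`.
#' @export
rg_series <- function(traj, sel = "heavy", label = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- as_indices(sel, traj)
  xi <- xyz_ind(idx)
  n <- length(idx)
  rg <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- vec2mat(traj$xyz[f, xi])
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  }, numeric(1))
  if (is.null(label)) {
    label <- if (inherits(sel, "selection")) sel$label
             else if (is.character(sel)) sel else "region"
  }
  structure(data.frame(frame = seq_along(rg), rg = rg),
            class = c("gyration_series", "data.frame"), label = label)
}

#' Helix twist angle of one frame
#'
#' The helix principal axis is the dominant eigenvector of the 3x3
#' positional covariance of the helix Calpha atoms (equivalent to the
#' least-squares line fit), with its sign fixed towards +z. The radial
#' vector r is the unit vector from the z axis to the helix centroid (zero
#' z component). The twist angle is the angle between z and the principal
#' axis projected onto the plane perpendicular to r, in degrees, bounded in
#' \[0, 90\].
#'
#' @param frame a [structure_frame()].
#' @param helix selection of the helix (Calpha atoms are taken from it);
#'   default the S6-like span 658-692.
#' @param chain restrict to one chain id (`NULL`: use the selection as is).
#' @return object of class `twist_frame`: list with `chain`,
#'   `principal_axis`, `radial_vector`, `twist_angle` (degrees; `NA` with
#'   `degenerate = TRUE` when the projection vanishes).
#' @export
twist_angle <- function(frame, helix = "residues 658-692", chain = NULL) {
  stopifnot(inherits(frame, "structure_frame"))
  idx <- as_indices(helix, frame)
  idx <- idx[frame$top$elety[idx] == "CA"]
  if (!is.null(chain)) idx <- idx[frame$top$chain[idx] == chain]
  if (length(idx) < 3L)
    stop("twist angle needs at least 3 Calpha atoms in the helix selection")
  ca <- frame_coords(frame)[idx, , drop = FALSE]
  ax <- eigen(stats::cov(ca), symmetric = TRUE)$vectors[, 1]
  if (ax[3] < 0) ax <- -ax
  cen <- colMeans(ca)
  r_xy <- c(cen[1], cen[2], 0)
  if (sqrt(sum(r_xy^2)) < 1e-9)
    stop("helix centroid lies on the z axis: radial vector undefined")
  r_hat <- unit_vec(r_xy)
  proj <- ax - sum(ax * r_hat) * r_hat
  np <- sqrt(sum(proj^2))
  if (np < 1e-8) {
    ang <- NA_real_
    degen <- TRUE
  } else {
    cosang <- min(1, max(-1, proj[3] / np))  # proj . z / |proj|
    ang <- rad2deg(acos(cosang))
    if (ang > 90) ang <- 180 - ang
    degen <- FALSE
  }
  structure(list(chain = if (is.null(chain)) unique(frame$top$chain[idx]) else chain,
                 principal_axis = ax, radial_vector = r_hat,
                 twist_angle = ang, degenerate = degen),
            class = "twist_frame")
}

#' Per-frame, per-chain twist angle series
#'
#' Applies [twist_angle()] to every frame for each chain found in the helix
#' selection and adds the across-chain mean per frame.
#'
#' @param traj a [trajectory()].
#' @param helix helix selection (text or [resolve_selection()]).
#' @param chains chains to analyse; default all chains present in the
#'   selection.
#' @return data.frame with `frame`, `chain` (including `"mean"`), `angle`.
#' @export
twist_series <- function(traj, helix = "residues 658-692", chains = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- if (inherits(helix, "selection")) helix else resolve_selection(traj, helix)
  if (is.null(chains)) {
    chains <- sort(unique(traj$top$chain[sel$indices]))
  }
  res <- do.call(rbind, lapply(chains, function(ch) {
    ang <- vapply(seq_len(n_frames(traj)), function(f) {
      twist_angle(get_frame(traj, f), helix = sel, chain = ch)$twist_angle
    }, numeric(1))
    data.frame(frame = seq_along(ang), chain = ch, angle = ang,
               stringsAsFactors = FALSE)
  }))
  mean_ang <- stats::aggregate(angle ~ frame, data = res, FUN = mean)
  rbind(res, data.frame(frame = mean_ang$frame, chain = "mean",
                        angle = mean_ang$angle, stringsAsFactors = FALSE))
}

#' Time-averaged Calpha distance matrix of one subunit
#'
#' Entry (i, j) is the time mean of the Calpha-Calpha distance between
#' residues i and j of the given chain. Residues lacking a Calpha are
#' dropped with a warning.
#'
#' @param traj a [trajectory()].
#' @param chain chain id of the subunit.
#' @param state_label label stored on the matrix.
#' @return object of class `distance_matrix`: list with `D` (symmetric,
#'   zero diagonal), `resno`, `chain`, `state_label`.
#' @export
distance_matrix <- function(traj, chain, state_label = "state") {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$top
  idx <- which(top$chain == chain & top$elety == "CA")
  if (length(idx) < 2L) stop("chain ", chain, " has fewer than 2 Calpha atoms")
  resno_chain <- sort(unique(top$resno[top$chain == chain &
                                         !(top$resid %in% c("HOH", "WAT", "TIP3", "SOL"))]))
  missing <- setdiff(resno_chain, top$resno[idx])
  if (length(missing))
    warning("residue(s) without Calpha dropped: ", paste(missing, collapse = ", "))
  o <- order(top$resno[idx])
  idx <- idx[o]
  xi <- xyz_ind(idx)
  n <- length(idx)
  acc <- matrix(0, n, n)
  for (f in seq_len(n_frames(traj))) {
    acc <- acc + as.matrix(stats::dist(vec2mat(traj$xyz[f, xi])))
  }
  D <- acc / n_frames(traj)
  dimnames(D) <- NULL
  structure(list(D = D, resno = top$resno[idx], chain = chain,
                 state_label = state_label),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix: chain", x$chain, "-", length(x$resno), "residues,",
      "state", x$state_label, "\n")
  invisible(x)
}

#' Distance-difference and correlation map between two states
#'
#' `delta = D1 - D2` per residue pair, and the correlation map. With the
#' default `corr_on = "delta"`, `C[i, j]` is the Pearson correlation of
#' rows i and j of `delta` (each residue's vector of distance changes to
#' all others); with `corr_on = "states"` it correlates row i of `D1` with
#' row j of `D2` instead. Rows with zero variance give `NA` entries,
#' flagged rather than forced to 1.
#'
#' @param D1,D2 [distance_matrix()] objects over identical residue sets.
#' @param corr_on `"delta"` (default) or `"states"`, see above.
#' @return object of class `state_comparison`: list with `delta`, `corr`,
#'   `resno`, `state_labels`, `zero_variance_rows`.
#' @export
compare_states <- function(D1, D2, corr_on = c("delta", "states")) {
  stopifnot(inherits(D1, "distance_matrix"), inherits(D2, "distance_matrix"))
  corr_on <- match.arg(corr_on)
  if (!identical(D1$resno, D2$resno))
    stop("distance matrices are not aligned: residue sets differ")
  delta <- D1$D - D2$D
  if (corr_on == "delta") {
    sds <- apply(delta, 1L, stats::sd)
    zero_var <- sds < .Machine$double.eps^.5
    C <- suppressWarnings(stats::cor(t(delta)))
    C[zero_var, ] <- NA_real_
    C[, zero_var] <- NA_real_
    diag(C)[!zero_var] <- 1
  } else {
    zero_var <- apply(D1$D, 1L, stats::sd) < .Machine$double.eps^.5 |
      apply(D2$D, 1L, stats::sd) < .Machine$double.eps^.5
    C <- suppressWarnings(stats::cor(t(D1$D), t(D2$D)))
    C[zero_var, ] <- NA_real_
    C[, zero_var] <- NA_real_
  }
  structure(list(delta = delta, corr = C, resno = D1$resno,
                 state_labels = c(D1$state_label, D2$state_label),
                 zero_variance_rows = which(zero_var)),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("state_comparison:", paste(x$state_labels, collapse = " vs "),
      "- max |delta| =", round(max(abs(x$delta)), 3), "A\n")
  invisible(x)
}

#' @describeIn compare_states heatmap of the distance-difference map
#'   (`what = "delta"`) or the correlation map (`what = "corr"`).
#' @param x a `state_comparison`.
#' @param what which map to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.state_comparison <- function(x, what = c("delta", "corr"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  graphics::image(x$resno, x$resno, m,
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  xlab = "residue", ylab = "residue",
                  main = if (what == "delta") {
                    paste("distance difference,", paste(x$state_labels, collapse = " - "))
                  } else {
                    "correlation of distance changes"
                  }, ...)
  invisible(x)
}
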