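# Fixture builders shared across tests. Everything is constructed in code;
# no data files.

flat <- function(m) as.numeric(t(m))

mk_top <- function(n, elety = "CA", resno = seq_len(n), chain = "A",
                   elem = "C", resid = "ALA") {
  data.frame(elety = rep(elety, length.out = n),
             resid = rep(resid, length.out = n),
             chain = rep(chain, length.out = n),
             resno = rep(resno, length.out = n),
             elem = rep(elem, length.out = n),
             stringsAsFactors = FALSE)
}

mk_frame <- function(coords, ...) {
  structure_frame(mk_top(nrow(coords), ...), flat(coords))
}

mk_traj <- function(frames, top = NULL, stride_ps = 1) {
  if (is.null(top)) top <- mk_top(nrow(frames[[1]]))
  trajectory(top, do.call(rbind, lapply(frames, flat)), stride_ps = stride_ps)
}

# ring of n atoms at ring_radius in the plane z
ring_coords <- function(n, ring_radius, z, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + ring_radius * cos(th), center[2] + ring_radius * sin(th), z)
}

rotate_z <- function(coords, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  coords %*% t(R)
}

# Brute-force lateral grid search for the largest probe in a slice: the
# independent oracle for the pore profiler. Exhaustive 2D grid, no local
# search shared with the implementation.
pore_slice_oracle <- function(coords, radii, z, center = c(0, 0),
                              bound = 8, grid = 0.05, cap = 10) {
  xs <- seq(center[1] - bound, center[1] + bound, by = grid)
  ys <- seq(center[2] - bound, center[2] + bound, by = grid)
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x - center[1])^2 + (g$y - center[2])^2 <= bound^2, ]
  f <- rep(Inf, nrow(g))
  for (i in seq_len(nrow(coords))) {
    d <- sqrt((g$x - coords[i, 1])^2 + (g$y - coords[i, 2])^2 +
                (z - coords[i, 3])^2) - radii[i]
    f <- pmin(f, d)
  }
  min(max(f), cap)
}

# constructed hbond occupancy records for differential tests
mk_records <- function(keys, occ, label = "state") {
  parts <- strsplit(keys, "|", fixed = TRUE)
  structure(data.frame(donor_id = vapply(parts, `[`, character(1), 1),
                       hydrogen_id = vapply(parts, `[`, character(1), 1),
                       acceptor_id = vapply(parts, `[`, character(1), 2),
                       occupancy = occ, stringsAsFactors = FALSE),
            class = c("hbond_records", "data.frame"),
            state_label = label, n_frames = 100L)
}
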