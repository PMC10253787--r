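# Geometric hydrogen-bond detection, per-bond occupancy over a trajectory,
# and differential occupancy between two states.

#' Hydrogen-bond geometric criteria
#'
#' A bond between acceptor A, donor hydrogen H and donor heavy atom D is
#' present iff `d(A, D) < max_ad_distance` AND
#' `angle(A, H, D) > min_ahd_angle`, both strict.
#'
#' @param max_ad_distance maximal acceptor-donor distance, Angstrom.
#' @param min_ahd_angle minimal A-H-D angle (at the hydrogen), degrees.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_ad_distance = 3.0, min_ahd_angle = 135) {
  stopifnot(max_ad_distance > 0, min_ahd_angle > 0, min_ahd_angle <= 180)
  structure(list(max_ad_distance = max_ad_distance,
                 min_ahd_angle = min_ahd_angle),
            class = "hbond_criteria")
}

# Donor table: every hydrogen paired with its covalent heavy atom (nearest
# eligible donor element within 1.2 A in the pairing frame).
find_donors <- function(x, frame_index = 1L, donor_elements = c("N", "O")) {
  top <- get_top(x)
  co <- if (inherits(x, "trajectory")) frame_coords(x, frame_index) else frame_coords(x)
  h_idx <- which(top$elem == "H")
  if (length(h_idx) == 0L)
    stop("no hydrogens in the topology: hydrogen-bond analysis needs a ",
         "protonated topology")
  heavy_idx <- which(top$elem %in% donor_elements)
  pairs <- lapply(h_idx, function(h) {
    d <- sqrt(colSums((t(co[heavy_idx, , drop = FALSE]) - co[h, ])^2))
    j <- which.min(d)
    if (length(j) && d[j] < 1.2) data.frame(donor = heavy_idx[j], hydrogen = h)
  })
  out <- do.call(rbind, pairs)
  if (is.null(out))
    stop("no hydrogen is within 1.2 A of a donor element (",
         paste(donor_elements, collapse = ", "), ")")
  out
}

acceptor_indices <- function(x, acceptor_elements = c("N", "O")) {
  which(get_top(x)$elem %in% acceptor_elements)
}

# per-frame presence matrix for all candidate (donor, acceptor) pairs.
# Returns list(pairs, present [frames x pairs]) where pairs has columns
# donor, hydrogen, acceptor.
hbond_presence <- function(traj, criteria, donors, acceptors) {
  top <- traj$top
  combos <- do.call(rbind, lapply(seq_len(nrow(donors)), function(k) {
    a <- acceptors[acceptors != donors$donor[k] & acceptors != donors$hydrogen[k]]
    a <- a[!(top$chain[a] == top$chain[donors$donor[k]] &
               top$resno[a] == top$resno[donors$donor[k]])]  # skip same residue
    if (length(a)) data.frame(donor = donors$donor[k],
                              hydrogen = donors$hydrogen[k], acceptor = a)
  }))
  if (is.null(combos))
    return(list(pairs = data.frame(), present = matrix(FALSE, n_frames(traj), 0)))
  nf <- n_frames(traj)
  present <- matrix(FALSE, nf, nrow(combos))
  cosmin <- cos(deg2rad(criteria$min_ahd_angle))
  for (k in seq_len(nrow(combos))) {
    Dx <- traj$xyz[, xyz_ind(combos$donor[k]), drop = FALSE]
    Hx <- traj$xyz[, xyz_ind(combos$hydrogen[k]), drop = FALSE]
    Ax <- traj$xyz[, xyz_ind(combos$acceptor[k]), drop = FALSE]
    dAD <- sqrt(rowSums((Ax - Dx)^2))
    ok_d <- dAD < criteria$max_ad_distance
    if (!any(ok_d)) next
    hd <- Dx - Hx
    ha <- Ax - Hx
    cosang <- rowSums(hd * ha) / (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
    # angle > min_angle  <=>  cos(angle) < cos(min_angle), strict
    present[, k] <- ok_d & (cosang < cosmin)
  }
  list(pairs = combos, present = present)
}

#' Detect hydrogen bonds in one frame
#'
#' @param frame a [structure_frame()] with hydrogens.
#' @param criteria a [hbond_criteria()].
#' @param donors optional data.frame with columns `donor`, `hydrogen`
#'   (atom indices); inferred from atom naming by default (H bonded to the
#'   nearest eligible heavy atom < 1.2 Angstrom).
#' @param acceptors optional acceptor atom indices; default all N/O atoms.
#' @param donor_elements,acceptor_elements eligible element sets (S is
#'   excluded by default).
#' @return data.frame of present bonds: donor/hydrogen/acceptor indices,
#'   chain/resno/atom-name annotations, `distance_ad` and `angle_ahd`.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria(),
                          donors = NULL, acceptors = NULL,
                          donor_elements = c("N", "O"),
                          acceptor_elements = c("N", "O")) {
  stopifnot(inherits(frame, "structure_frame"))
  traj1 <- trajectory(frame$top, matrix(frame$xyz, nrow = 1))
  if (is.null(donors)) donors <- find_donors(frame, donor_elements = donor_elements)
  if (is.null(acceptors)) acceptors <- acceptor_indices(frame, acceptor_elements)
  hp <- hbond_presence(traj1, criteria, donors, acceptors)
  keep <- which(hp$present[1L, ])
  co <- frame_coords(frame)
  out <- hp$pairs[keep, , drop = FALSE]
  if (nrow(out)) {
    annot <- function(i) paste0(frame$top$chain[i], frame$top$resno[i], ":",
                                frame$top$elety[i])
    out$donor_id <- vapply(out$donor, annot, character(1))
    out$hydrogen_id <- vapply(out$hydrogen, annot, character(1))
    out$acceptor_id <- vapply(out$acceptor, annot, character(1))
    out$distance_ad <- sqrt(rowSums((co[out$acceptor, , drop = FALSE] -
                                       co[out$donor, , drop = FALSE])^2))
    hd <- co[out$donor, , drop = FALSE] - co[out$hydrogen, , drop = FALSE]
    ha <- co[out$acceptor, , drop = FALSE] - co[out$hydrogen, , drop = FALSE]
    out$angle_ahd <- rad2deg(acos(pmin(1, pmax(-1,
      rowSums(hd * ha) / (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))))))
  }
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For every candidate donor(-hydrogen)/acceptor pair, the fraction of
#' frames in which the geometric criteria are satisfied. When a donor
#' carries several hydrogens the bond counts as present if any of them
#' satisfies the angle criterion. Pairs never present are omitted.
#'
#' @inheritParams detect_hbonds
#' @param traj a [trajectory()] with hydrogens.
#' @param state_label label stored on the records.
#' @return object of class `hbond_records`: data.frame with donor/acceptor
#'   annotations and `occupancy`.
#' @export
hbond_occupancy <- function(traj, criteria = hbond_criteria(),
                            donors = NULL, acceptors = NULL,
                            donor_elements = c("N", "O"),
                            acceptor_elements = c("N", "O"),
                            state_label = "state") {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(donors)) donors <- find_donors(traj, donor_elements = donor_elements)
  if (is.null(acceptors)) acceptors <- acceptor_indices(traj, acceptor_elements)
  hp <- hbond_presence(traj, criteria, donors, acceptors)
  if (nrow(hp$pairs) == 0L) {
    out <- data.frame(donor_id = character(0), acceptor_id = character(0),
                      hydrogen_id = character(0), occupancy = numeric(0))
    return(structure(out, class = c("hbond_records", "data.frame"),
                     state_label = state_label, n_frames = n_frames(traj)))
  }
  top <- traj$top
  annot <- function(i) paste0(top$chain[i], top$resno[i], ":", top$elety[i])
  key_da <- paste(vapply(hp$pairs$donor, annot, character(1)),
                  vapply(hp$pairs$acceptor, annot, character(1)), sep = "|")
  groups <- split(seq_len(nrow(hp$pairs)), key_da)
  rows <- lapply(groups, function(g) {
    pres <- if (length(g) == 1L) hp$present[, g] else apply(hp$present[, g, drop = FALSE], 1L, any)
    occ <- mean(pres)
    if (occ == 0) return(NULL)
    counts <- colSums(hp$present[, g, drop = FALSE])
    best_h <- hp$pairs$hydrogen[g[which.max(counts)]]
    data.frame(donor_id = annot(hp$pairs$donor[g[1]]),
               hydrogen_id = annot(best_h),
               acceptor_id = annot(hp$pairs$acceptor[g[1]]),
               occupancy = occ, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(donor_id = character(0), hydrogen_id = character(0),
                      acceptor_id = character(0), occupancy = numeric(0))
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hbond_records", "data.frame"),
            state_label = state_label, n_frames = n_frames(traj))
}

#' Differential hydrogen bonds between two states
#'
#' Bonds whose absolute occupancy difference exceeds `threshold` (strict),
#' sorted by decreasing `|delta|`. Bonds present in only one state use
#' occupancy 0 in the other.
#'
#' @param records1,records2 [hbond_occupancy()] outputs for the two states.
#' @param threshold minimal absolute occupancy difference (default 0.20).
#' @return object of class `differential_hbonds`: data.frame with
#'   `donor_id`, `acceptor_id`, `occupancy1`, `occupancy2`, `delta`.
#' @export
hbond_differential <- function(records1, records2, threshold = 0.20) {
  key <- function(r) paste(r$donor_id, r$acceptor_id, sep = "|")
  all_keys <- union(key(records1), key(records2))
  occ <- function(r, k) {
    m <- match(k, key(r))
    ifelse(is.na(m), 0, r$occupancy[m])
  }
  o1 <- occ(records1, all_keys)
  o2 <- occ(records2, all_keys)
  delta <- o1 - o2
  keep <- abs(delta) > threshold
  parts <- strsplit(all_keys[keep], "|", fixed = TRUE)
  out <- data.frame(donor_id = vapply(parts, `[`, character(1), 1),
                    acceptor_id = vapply(parts, `[`, character(1), 2),
                    occupancy1 = o1[keep], occupancy2 = o2[keep],
                    delta = delta[keep], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("differential_hbonds", "data.frame"),
            threshold = threshold,
            state_labels = c(attr(records1, "state_label"),
                             attr(records2, "state_label")))
}
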