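#' Construct a structure frame
#'
#' A `structure_frame` holds one set of atomic coordinates together with the
#' topology metadata (atom names, residues, chains, elements) every analysis
#' in the package consumes. Coordinates are stored as a flat numeric vector
#' `(x1, y1, z1, x2, ...)` in Angstrom, the layout used by bio3d.
#'
#' @param top data.frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `chain`, `resno` (author residue numbering)
#'   and `elem` (element symbol). An `eleno` serial column is added when
#'   missing.
#' @param xyz numeric vector of length `3 * nrow(top)`.
#' @param frame_time optional time stamp in ps.
#' @return object of class `structure_frame`.
#' @export
structure_frame <- function(top, xyz, frame_time = NA_real_) {
  top <- as.data.frame(top, stringsAsFactors = FALSE)
  need <- c("elety", "resid", "chain", "resno", "elem")
  miss <- setdiff(need, names(top))
  if (length(miss)) stop("topology lacks column(s): ", paste(miss, collapse = ", "))
  if (!"eleno" %in% names(top)) top$eleno <- seq_len(nrow(top))
  xyz <- as.numeric(xyz)
  if (length(xyz) != 3L * nrow(top))
    stop("coordinate count (", length(xyz) / 3, ") does not match topology atom count (",
         nrow(top), ")")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure frame")
  structure(list(top = top, xyz = xyz, frame_time = frame_time),
            class = "structure_frame")
}

#' Construct a trajectory
#'
#' Ordered frames sharing one topology; the unit all analyses consume.
#'
#' @param top topology data.frame (see [structure_frame()]).
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns.
#' @param stride_ps time between stored frames, ps.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(top, xyz, stride_ps = NA_real_) {
  top <- as.data.frame(top, stringsAsFactors = FALSE)
  if (!"eleno" %in% names(top)) top$eleno <- seq_len(nrow(top))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (ncol(xyz) != 3L * nrow(top))
    stop("frame width (", ncol(xyz), ") does not match 3 x atom count (",
         3L * nrow(top), ")")
  structure(list(top = top, xyz = xyz, stride_ps = stride_ps),
            class = "trajectory")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat("structure_frame:", nrow(x$top), "atoms,",
      length(unique(x$top$chain)), "chain(s)\n")
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$xyz), "frames x", nrow(x$top), "atoms",
      if (!is.na(x$stride_ps)) paste0("(stride ", x$stride_ps, " ps)") else "", "\n")
  invisible(x)
}

#' Number of frames / atoms
#' @param x a `trajectory` or `structure_frame`.
#' @export
n_frames <- function(x) if (inherits(x, "trajectory")) nrow(x$xyz) else 1L

#' @rdname n_frames
#' @export
n_atoms <- function(x) nrow(x$top)

#' Coordinates of one frame as an n x 3 matrix
#' @param x a `trajectory` or `structure_frame`.
#' @param i frame index (ignored for a single frame).
#' @export
frame_coords <- function(x, i = 1L) {
  if (inherits(x, "structure_frame")) return(vec2mat(x$xyz))
  vec2mat(x$xyz[i, ])
}

#' Extract one frame of a trajectory as a structure_frame
#' @inheritParams frame_coords
#' @export
get_frame <- function(x, i = 1L) {
  if (inherits(x, "structure_frame")) return(x)
  t_ps <- if (!is.na(x$stride_ps)) (i - 1) * x$stride_ps else NA_real_
  structure_frame(x$top, x$xyz[i, ], frame_time = t_ps)
}

get_top <- function(x) {
  if (is.data.frame(x)) x else x$top
}

#' Read a structure file
#'
#' Reads a PDB or mmCIF file into a [structure_frame()]. Author residue
#' numbering and chain identifiers are preserved. Multi-model files yield
#' the first model unless `model` is given.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"pdb"` or `"cif"`.
#' @param model model index for multi-model files (default 1).
#' @return a `structure_frame`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("empty structure: no atoms parsed from ", path)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nmod <- nrow(xyz)
  if (model < 1L || model > nmod)
    stop("model ", model, " requested but file has ", nmod, " model(s)")
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- bio3d::atom2ele(pdb$atom$elety)
  } else {
    blank <- is.na(elem) | elem == ""
    if (any(blank)) elem[blank] <- bio3d::atom2ele(pdb$atom$elety[blank])
  }
  top <- data.frame(eleno = pdb$atom$eleno,
                    elety = pdb$atom$elety,
                    resid = pdb$atom$resid,
                    chain = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
                    resno = pdb$atom$resno,
                    elem = toupper(elem),
                    stringsAsFactors = FALSE)
  structure_frame(top, xyz[model, ])
}

#' Write a structure frame to PDB
#'
#' @param frame a `structure_frame`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(frame, path) {
  stopifnot(inherits(frame, "structure_frame"))
  bio3d::write.pdb(file = path,
                   xyz = frame$xyz,
                   resno = frame$top$resno,
                   resid = frame$top$resid,
                   eleno = frame$top$eleno,
                   elety = frame$top$elety,
                   chain = ifelse(frame$top$chain == "", " ", frame$top$chain),
                   elesy = frame$top$elem)
  invisible(path)
}

# ---- DCD trajectory I/O ------------------------------------------------

# Minimal CHARMM-dialect DCD writer (bio3d reads but does not write DCD).
# Single-precision coordinates, no unit cell, no fixed atoms.
write_dcd <- function(xyz, path, stride_ps = 1) {
  xyz <- as.matrix(xyz)
  nf <- nrow(xyz)
  natom <- ncol(xyz) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    payload <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf        # frames in file
    icntrl[2] <- 1L        # first step
    icntrl[3] <- 1L        # save interval
    icntrl[4] <- nf        # total steps
    icntrl[20] <- 24L      # CHARMM version flag
    writeBin(icntrl[1:9], c2, size = 4, endian = "little")
    # timestep in AKMA units, stored single precision
    writeBin(as.numeric(stride_ps / 0.0488882129), c2, size = 4, endian = "little")
    writeBin(icntrl[11:20], c2, size = 4, endian = "little")
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeChar(sprintf("%-80s", "written by gatescan"), c2, nchars = 80, eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(natom), c2, size = 4, endian = "little"))
  ix <- seq(1L, 3L * natom, by = 3L)
  for (f in seq_len(nf)) {
    fr <- xyz[f, ]
    rec(function(c2) writeBin(as.numeric(fr[ix]), c2, size = 4, endian = "little"))
    rec(function(c2) writeBin(as.numeric(fr[ix + 1L]), c2, size = 4, endian = "little"))
    rec(function(c2) writeBin(as.numeric(fr[ix + 2L]), c2, size = 4, endian = "little"))
  }
  invisible(path)
}

# Expected byte size of a DCD with the header write_dcd produces.
dcd_expected_frames <- function(path, natom) {
  header <- (8 + 84) + (8 + 84) + (8 + 4)
  per_frame <- 3 * (8 + 4 * natom)
  max(0L, as.integer((file.size(path) - header) %/% per_frame))
}

#' Write a trajectory to disk
#'
#' Writes the topology as a PDB file and the coordinates as a CHARMM-format
#' DCD file.
#'
#' @param traj a `trajectory`.
#' @param topology_path output PDB path.
#' @param traj_path output DCD path.
#' @return invisibly, a list with the two paths.
#' @export
write_trajectory <- function(traj, topology_path, traj_path) {
  stopifnot(inherits(traj, "trajectory"))
  write_structure(get_frame(traj, 1L), topology_path)
  write_dcd(traj$xyz, traj_path,
            stride_ps = if (is.na(traj$stride_ps)) 1 else traj$stride_ps)
  invisible(list(topology = topology_path, trajectory = traj_path))
}

#' Read a trajectory (topology + DCD)
#'
#' @param topology PDB/mmCIF path or a `structure_frame`.
#' @param traj DCD file path.
#' @param stride_ps time between frames, ps; when `NULL` an attempt is made
#'   to take it from the trajectory object later (stored as `NA`).
#' @return a `trajectory`.
#' @export
read_trajectory <- function(topology, traj, stride_ps = NULL) {
  top_frame <- if (inherits(topology, "structure_frame")) topology
               else read_structure(topology)
  natom <- n_atoms(top_frame)
  xyz <- tryCatch(bio3d::read.dcd(traj, verbose = FALSE),
                  error = function(e) {
                    # the reader can leave its connection open on failure
                    cons <- showConnections()
                    for (i in rownames(cons)[cons[, "description"] == traj]) {
                      try(close(getConnection(as.integer(i))), silent = TRUE)
                    }
                    got <- dcd_expected_frames(traj, natom)
                    stop("partial or corrupt trajectory '", traj, "': ",
                         conditionMessage(e), " (", got,
                         " complete frame(s) recoverable)", call. = FALSE)
                  })
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * natom)
    stop("topology/trajectory atom-count mismatch: topology has ", natom,
         " atoms, trajectory frames have ", ncol(xyz) %/% 3L)
  trajectory(top_frame$top, xyz,
             stride_ps = if (is.null(stride_ps)) NA_real_ else stride_ps)
}

# ---- selections --------------------------------------------------------

#' Resolve an atom selection
#'
#' Resolves a small textual selection grammar against a topology. Clauses
#' are separated by `,` or `;` and combined with AND:
#'
#' * `chain A B` — chain identifiers
#' * `residues 432-713 720` (or `resno ...`) — inclusive residue-number
#'   ranges and single numbers; `-`, en dash and `:` all work as range
#'   separators
#' * `resname HOH GAT` — residue names
#' * `atoms CA CB` (or `name ...`) — atom names
#' * `backbone` — atoms N, CA, C, O
#' * `calpha` — atoms CA
#' * `heavy` — element not H
#' * `water` / `protein` — by residue name (HOH, WAT, TIP3, SOL)
#' * `element O N` — element symbols
#'
#' @param topology a topology data.frame, `structure_frame` or `trajectory`.
#' @param spec selection text, e.g. `"chain A, residues 432-713, backbone"`.
#' @param label optional label stored on the selection.
#' @return object of class `selection` with fields `label`, `spec`,
#'   `indices` (strictly increasing atom indices).
#' @export
resolve_selection <- function(topology, spec, label = spec) {
  top <- get_top(topology)
  keep <- rep(TRUE, nrow(top))
  water_names <- c("HOH", "WAT", "TIP3", "SOL")
  clauses <- trimws(unlist(strsplit(spec, "[,;]")))
  clauses <- clauses[clauses != ""]
  for (cl in clauses) {
    toks <- strsplit(gsub("–", "-", cl), "[[:space:]]+")[[1]]
    kw <- tolower(toks[1])
    args <- toks[-1]
    keep <- keep & switch(kw,
      chain = top$chain %in% args,
      residues = , resno = {
        sel <- rep(FALSE, nrow(top))
        for (a in args) {
          if (grepl("^-?[0-9]+[-:][0-9]+$", a)) {
            # split on the LAST '-' or ':' so negative starts survive
            m <- regmatches(a, regexec("^(-?[0-9]+)[-:]([0-9]+)$", a))[[1]]
            rng <- as.integer(m[2:3])
            sel <- sel | (top$resno >= rng[1] & top$resno <= rng[2])
          } else {
            sel <- sel | top$resno == as.integer(a)
          }
        }
        sel
      },
      resname = top$resid %in% toupper(args),
      atoms = , name = {
        unknown <- setdiff(toupper(args), unique(top$elety))
        if (length(unknown))
          warning("atom name(s) not in topology: ", paste(unknown, collapse = ", "))
        top$elety %in% toupper(args)
      },
      backbone = top$elety %in% c("N", "CA", "C", "O"),
      calpha = top$elety == "CA",
      heavy = top$elem != "H",
      water = top$resid %in% water_names,
      protein = !(top$resid %in% water_names),
      element = top$elem %in% toupper(args),
      stop("unknown selection keyword: '", kw, "' in clause '", cl, "'")
    )
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("empty selection for spec '", spec, "'")
  structure(list(label = label, spec = spec, indices = idx),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

as_indices <- function(sel, topology = NULL) {
  if (inherits(sel, "selection")) return(sel$indices)
  if (is.character(sel)) {
    if (is.null(topology)) stop("a textual selection needs a topology")
    return(resolve_selection(topology, sel)$indices)
  }
  as.integer(sel)
}

# ---- van der Waals radii ----------------------------------------------

#' Van der Waals radius table
#'
#' `"bondi"` is the Bondi (1964) set used by default for pore profiling;
#' `"hole_simple"` mirrors the "simple" radius set shipped with the HOLE
#' program.
#'
#' @param set `"bondi"` or `"hole_simple"`.
#' @param default_radius radius (Angstrom) for elements absent from the set.
#' @return object of class `vdw_table`.
#' @export
vdw_table <- function(set = c("bondi", "hole_simple"), default_radius = 1.70) {
  set <- match.arg(set)
  stopifnot(default_radius > 0)
  radii <- switch(set,
    bondi = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
              P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98),
    hole_simple = c(H = 1.00, C = 1.85, N = 1.75, O = 1.65, S = 2.00,
                    P = 2.10))
  structure(list(set = set, radii = radii, default_radius = default_radius),
            class = "vdw_table")
}

#' Assign van der Waals radii to every atom
#'
#' Unknown elements receive `default_radius` and are reported in a message.
#'
#' @param topology topology data.frame, `structure_frame` or `trajectory`.
#' @param table a [vdw_table()].
#' @return numeric vector of per-atom radii (Angstrom).
#' @export
assign_vdw <- function(topology, table = vdw_table()) {
  top <- get_top(topology)
  elem <- toupper(top$elem)
  r <- unname(table$radii[elem])
  unknown <- is.na(r)
  if (any(unknown)) {
    message(sum(unknown), " atom(s) with element outside the '", table$set,
            "' table (", paste(unique(elem[unknown]), collapse = ", "),
            "): using default radius ", table$default_radius, " A")
    r[unknown] <- table$default_radius
  }
  r
}
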