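# Orchestration of the full two-state comparison from a single config:
# superposition/RMSF -> pore profiling -> geometry -> hydrogen bonds ->
# dihedral PCA, then all pairwise state comparisons.

#' Build a pipeline run configuration
#'
#' Defaults mirror the analysis constants used throughout the package:
#' backbone fit over residues 432-713, S6 helix 658-692, water
#' permeability threshold 1.15 Angstrom, hydrogen-bond criteria 3.0
#' Angstrom / 135 degrees, differential occupancy threshold 0.20, and
#' free-energy surfaces at 303 K. Every default is overridable.
#'
#' @param states list of state descriptors; each a list with `label` and
#'   either `traj` (an in-memory [trajectory()]) or `topology` +
#'   `trajectory` file paths.
#' @param fit_spec superposition selection text.
#' @param helix_spec S6-style helix selection for twist angles.
#' @param pore_sel pore-wall selection for radius profiling.
#' @param rg_specs named list of region selections for radius-of-gyration
#'   series.
#' @param water_sel water-oxygen selection for permeation counting.
#' @param gates list with `upper_z`/`lower_z` plane heights (Angstrom) or
#'   `upper`/`lower` residue selection texts whose mean Calpha z defines
#'   the planes; `NULL` uses the synthetic manifest when available.
#' @param permeability_threshold pore radius above which a frame counts as
#'   water permeable, Angstrom.
#' @param hbond hydrogen-bond criteria, see [hbond_criteria()].
#' @param differential_threshold occupancy-difference threshold.
#' @param snapshot list with `last_ns` and `stride_ps` for
#'   [snapshot_select()]; `NULL` analyses all frames.
#' @param pore list of [min_radius_series()] arguments (`z_range`,
#'   `z_step`, `max_radius`, `lateral_bound`).
#' @param pca list with `bins` and `temperature` for the free-energy
#'   surface.
#' @param out_dir output directory for stage CSVs and the report JSON;
#'   `NULL` keeps everything in memory.
#' @return object of class `run_config`.
#' @export
run_config <- function(states,
                       fit_spec = "residues 432-713, backbone",
                       helix_spec = "residues 658-692",
                       pore_sel = "protein",
                       rg_specs = list(pore = "protein, heavy"),
                       water_sel = "water, element O",
                       gates = NULL,
                       permeability_threshold = 1.15,
                       hbond = hbond_criteria(3.0, 135),
                       differential_threshold = 0.20,
                       snapshot = NULL,
                       pore = list(z_step = 0.25, max_radius = 10,
                                   lateral_bound = 8, z_range = NULL),
                       pca = list(bins = 50L, temperature = 303),
                       out_dir = NULL) {
  labels <- vapply(states, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("state labels must be unique")
  for (s in states) {
    if (is.null(s[["traj"]])) {
      for (p in c(s$topology, s$trajectory)) {
        if (!file.exists(p)) stop("input file not found: ", p)
      }
    }
  }
  structure(list(states = states, fit_spec = fit_spec,
                 helix_spec = helix_spec, pore_sel = pore_sel,
                 rg_specs = rg_specs, water_sel = water_sel, gates = gates,
                 permeability_threshold = permeability_threshold,
                 hbond = hbond,
                 differential_threshold = differential_threshold,
                 snapshot = snapshot, pore = pore, pca = pca,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$hbond)) {
    y$hbond <- hbond_criteria(
      max_ad_distance = y$hbond$max_ad_distance %||% 3.0,
      min_ahd_angle = y$hbond$min_ahd_angle %||% 135)
  }
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select trailing snapshots at a given cadence
#'
#' Keeps frames from the trailing `last_ns` window of the trajectory,
#' resampled at `stride_ps`. The number of output frames is
#' `floor(last_ns * 1000 / stride_ps)`, taken evenly across the window.
#'
#' @param traj a [trajectory()] with a known `stride_ps`.
#' @param last_ns length of the trailing window, ns.
#' @param stride_ps output cadence, ps (default: keep the trajectory's own
#'   stride).
#' @return the sliced `trajectory`.
#' @export
snapshot_select <- function(traj, last_ns, stride_ps = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (last_ns <= 0) stop("last_ns must be positive: empty selection")
  if (is.na(traj$stride_ps))
    stop("trajectory has no time metadata: supply stride_ps when reading it")
  if (is.null(stride_ps)) stride_ps <- traj$stride_ps
  nf <- n_frames(traj)
  window <- round(last_ns * 1000 / traj$stride_ps)
  if (window > nf) {
    warning("requested window (", last_ns, " ns = ", window,
            " frames) exceeds trajectory length (", nf, "): using all frames")
    window <- nf
  }
  start <- nf - window + 1L
  n_out <- floor(last_ns * 1000 / stride_ps)
  n_out <- min(n_out, window)
  if (n_out < 1L) stop("stride_ps longer than the window: empty selection")
  keep <- unique(round(seq(start, nf, length.out = n_out)))
  out <- trajectory(traj$top, traj$xyz[keep, , drop = FALSE],
                    stride_ps = stride_ps)
  attr(out, "manifest") <- attr(traj, "manifest")
  out
}

resolve_gates <- function(config, traj) {
  g <- config$gates
  if (!is.null(g) && !is.null(g$upper_z) && !is.null(g$lower_z))
    return(list(upper_z = g$upper_z, lower_z = g$lower_z))
  if (!is.null(g) && !is.null(g$upper) && !is.null(g$lower)) {
    mean_z <- function(spec) {
      idx <- as_indices(spec, traj)
      idx_ca <- idx[traj$top$elety[idx] == "CA"]
      if (length(idx_ca)) idx <- idx_ca
      mean(frame_coords(traj, 1L)[idx, 3])
    }
    return(list(upper_z = mean_z(g$upper), lower_z = mean_z(g$lower)))
  }
  m <- attr(traj, "manifest")
  if (!is.null(m)) return(list(upper_z = m$upper_gate_z, lower_z = m$lower_gate_z))
  stop("gate planes undefined: supply config$gates")
}

load_state <- function(s) {
  tr <- if (!is.null(s[["traj"]])) s[["traj"]]
        else read_trajectory(s[["topology"]], s[["trajectory"]],
                             stride_ps = s[["stride_ps"]])
  tr
}

write_stage_csv <- function(out_dir, label, stage, df) {
  if (is.null(out_dir)) return(invisible(NULL))
  d <- file.path(out_dir, label)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, file.path(d, paste0(stage, ".csv")), row.names = FALSE)
}

run_stage <- function(report, state_label, stage, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr()),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  if (!res$ok)
    warning("stage '", stage, "' failed for state '", state_label, "': ",
            res$error)
  res
}

#' Run the full two-state analysis pipeline
#'
#' Executes, for each state: superposition, RMSF, pore profiling with
#' permeability statistics and water permeation counts, radius-of-gyration
#' series, twist angles, per-subunit distance matrices, hydrogen-bond
#' occupancy, and dihedral PCA with a free-energy surface; then the
#' pairwise state comparisons (fractional RMSF difference,
#' distance-difference/correlation maps, differential hydrogen bonds) for
#' the first two states. A failing stage is recorded in the report and the
#' remaining stages proceed. The pipeline is a pure function of its inputs:
#' repeated runs write byte-identical CSVs.
#'
#' @param config a [run_config()].
#' @return object of class `gatescan_report`: nested list with per-state
#'   summaries and state-difference tables; written to
#'   `out_dir/report.json` when an output directory is configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  states <- list()
  for (s in config$states) {
    label <- s$label
    traj <- load_state(s)
    if (!is.null(config$snapshot)) {
      traj <- snapshot_select(traj, config$snapshot$last_ns,
                              config$snapshot$stride_ps)
    }
    traj <- superpose(traj, fit = config$fit_spec)
    gates <- resolve_gates(config, traj)
    st <- list(label = label, stages = list())

    r <- run_stage(st, label, "fluct", function() {
      prof <- rmsf_profile(traj, atom = "CA", state_label = label)
      write_stage_csv(out_dir, label, "rmsf", as.data.frame(prof))
      prof
    })
    st$rmsf <- if (r$ok) r$value
    st$stages$fluct <- r$ok

    r <- run_stage(st, label, "pore", function() {
      args <- c(list(traj = traj, sel = config$pore_sel), config$pore)
      args <- args[!vapply(args, is.null, logical(1))]
      series <- do.call(min_radius_series, args)
      perm <- permeable_fraction(series, config$permeability_threshold)
      # systems without waters still get radius/permeability statistics
      flux <- tryCatch(count_permeations(traj, water_sel = config$water_sel,
                                         upper_gate_z = gates$upper_z,
                                         lower_gate_z = gates$lower_z),
                       error = function(e) NULL)
      write_stage_csv(out_dir, label, "pore",
                      data.frame(frame = seq_along(series$min_radius),
                                 min_radius = series$min_radius,
                                 min_radius_z = series$min_radius_z))
      list(series = series, perm = perm, flux = flux)
    })
    st$pore <- if (r$ok) r$value
    st$stages$pore <- r$ok

    r <- run_stage(st, label, "geometry", function() {
      rg <- lapply(names(config$rg_specs), function(nm) {
        g <- rg_series(traj, config$rg_specs[[nm]], label = nm)
        write_stage_csv(out_dir, label, paste0("rg_", nm), as.data.frame(g))
        g
      })
      names(rg) <- names(config$rg_specs)
      tw <- twist_series(traj, helix = config$helix_spec)
      write_stage_csv(out_dir, label, "twist", tw)
      chains <- sort(unique(traj$top$chain[as_indices(config$helix_spec, traj)]))
      dm <- distance_matrix(traj, chain = chains[1], state_label = label)
      write_stage_csv(out_dir, label, "distance_matrix",
                      data.frame(resno = dm$resno, dm$D))
      list(rg = rg, twist = tw, dmat = dm)
    })
    st$geometry <- if (r$ok) r$value
    st$stages$geometry <- r$ok

    r <- run_stage(st, label, "hbond", function() {
      recs <- hbond_occupancy(traj, criteria = config$hbond,
                              state_label = label)
      write_stage_csv(out_dir, label, "hbonds", as.data.frame(recs))
      recs
    })
    st$hbonds <- if (r$ok) r$value
    st$stages$hbond <- r$ok

    r <- run_stage(st, label, "pca", function() {
      dh <- extract_dihedrals(traj, sel = config$fit_spec)
      pc <- dpca(dh, n_components = 2L)
      fes <- free_energy_surface(pc, bins = config$pca$bins,
                                 temperature = config$pca$temperature)
      write_stage_csv(out_dir, label, "pca_projections",
                      data.frame(frame = seq_len(nrow(pc$projections)),
                                 pc$projections))
      list(pca = pc, fes = fes)
    })
    st$pca <- if (r$ok) r$value
    st$stages$pca <- r$ok

    states[[label]] <- st
  }

  comparisons <- NULL
  if (length(states) >= 2L) {
    s1 <- states[[1]]; s2 <- states[[2]]
    comparisons <- list()
    if (!is.null(s1$rmsf) && !is.null(s2$rmsf)) {
      comparisons$delta_rmsf <- delta_rmsf(s1$rmsf, s2$rmsf)
      write_stage_csv(out_dir, "comparison", "delta_rmsf",
                      as.data.frame(comparisons$delta_rmsf))
    }
    if (!is.null(s1$geometry) && !is.null(s2$geometry)) {
      comparisons$distance <- compare_states(s1$geometry$dmat, s2$geometry$dmat)
      write_stage_csv(out_dir, "comparison", "distance_delta",
                      data.frame(resno = comparisons$distance$resno,
                                 comparisons$distance$delta))
      write_stage_csv(out_dir, "comparison", "distance_correlation",
                      data.frame(resno = comparisons$distance$resno,
                                 comparisons$distance$corr))
    }
    if (!is.null(s1$hbonds) && !is.null(s2$hbonds)) {
      comparisons$hbonds <- hbond_differential(s1$hbonds, s2$hbonds,
                                               config$differential_threshold)
      write_stage_csv(out_dir, "comparison", "differential_hbonds",
                      as.data.frame(comparisons$hbonds))
    }
  }

  summary_row <- function(st) {
    list(label = st$label,
         mean_min_radius = if (!is.null(st$pore)) mean(st$pore$series$min_radius),
         permeable_fraction = if (!is.null(st$pore)) st$pore$perm$permeable_fraction,
         n_permeation_events = if (!is.null(st$pore)) st$pore$flux$n_permeation_events,
         mean_twist_deg = if (!is.null(st$geometry)) {
           tw <- st$geometry$twist
           mean(tw$angle[tw$chain == "mean"], na.rm = TRUE)
         },
         stages_ok = st$stages)
  }
  report <- structure(list(states = states,
                           comparisons = comparisons,
                           summary = lapply(states, summary_row)),
                      class = "gatescan_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  list(summary = report$summary,
       differential_hbonds = if (!is.null(report$comparisons$hbonds))
         as.data.frame(report$comparisons$hbonds),
       max_abs_delta_rmsf = if (!is.null(report$comparisons$delta_rmsf))
         max(abs(report$comparisons$delta_rmsf$delta_frac)),
       max_abs_delta_distance = if (!is.null(report$comparisons$distance))
         max(abs(report$comparisons$distance$delta)))
}

#' @export
print.gatescan_report <- function(x, ...) {
  cat("gatescan_report:", length(x$states), "state(s)\n")
  for (s in x$summary) {
    cat(sprintf("  %s: mean min radius %s A, permeable fraction %s, mean twist %s deg\n",
                s$label,
                if (is.null(s$mean_min_radius)) "-" else sprintf("%.2f", s$mean_min_radius),
                if (is.null(s$permeable_fraction)) "-" else sprintf("%.3f", s$permeable_fraction),
                if (is.null(s$mean_twist_deg)) "-" else sprintf("%.1f", s$mean_twist_deg)))
  }
  if (!is.null(x$comparisons$hbonds))
    cat("  differential H-bonds:", nrow(x$comparisons$hbonds), "\n")
  invisible(x)
}
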