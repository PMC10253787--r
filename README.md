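# gatescan

Trajectory analysis of redox- and conformation-gated tetrameric ion
channels, for structural biologists and simulators who need to compare two
states of the same channel — oxidized vs reduced, open vs closed — from
molecular dynamics output.

Given a topology plus trajectory per state, `gatescan` computes, per state
and as state differences:

* **Superposition / flexibility** — Kabsch least-squares superposition,
  per-frame RMSD, per-residue RMSF, and the fractional fluctuation
  difference
  `ΔRMSF/RMSF̄ = 2(RMSF₁ − RMSF₂)/(RMSF₁ + RMSF₂)` ∈ [−2, 2].
* **Pore geometry** — HOLE-style pore radius profiles
  `R(z) = max_p min_i (‖p − aᵢ‖ − rᵢ)` along the channel (z) axis, the
  minimal-radius time series, the water-permeable fraction of frames
  (minimal radius strictly > 1.15 Å by default), and complete water
  permeation events across the two gate planes.
* **Domain geometry** — radius-of-gyration series; S6 twist angles (angle
  between ẑ and the helix principal axis projected onto the plane
  perpendicular to the radial vector r̂, in [0°, 90°]); per-subunit mean
  Cα distance matrices with distance-difference maps ΔD and row-wise
  Pearson correlation heatmaps.
* **Hydrogen bonds** — geometric criteria d(A,D) < 3.0 Å and
  ∠(A–H–D) > 135° (both strict), per-bond occupancy, and the differential
  table of bonds whose occupancy changes by more than 0.20 between states.
* **Dihedral PCA** — backbone φ/ψ extraction, PCA on (sin θ, cos θ)
  variables, projections onto PC1/PC2, and free-energy surfaces
  `F = −k_B T ln(n/n_max)` (kcal/mol, default 303 K).

A synthetic tetrameric-channel generator (`channel_spec()`,
`simulate_trajectory()`, `morph_states()`) provides trajectories with fully
known ground truth — gate aperture schedules, per-residue fluctuation
amplitudes, planted hydrogen bonds, traversing waters — so the whole
pipeline is testable without undeposited simulation data.

## Worked example

Two synthetic states under the default study conditions: a reduced/closed
channel (aperture 0.59 Å, S6 tilt 25°, 15% open frames) versus an
oxidized/partially open one (open aperture 2.31 Å, tilt 30.7°, 60% open
frames), with one redox-sensitive planted hydrogen bond.

```r
library(gatescan)
specs <- study_specs(seed = 1, n_frames = 400)
pair <- morph_states(specs$reduced, specs$oxidized)
cfg <- run_config(
  states = list(list(label = "reduced",  traj = pair$reduced),
                list(label = "oxidized", traj = pair$oxidized)),
  fit_spec = "residues 658-692, backbone",
  helix_spec = "residues 658-692",
  pore = list(z_range = c(-4, 4)))
report <- run_pipeline(cfg)
print(report)
#> gatescan_report: 2 state(s)
#>   reduced: mean min radius 0.85 A, permeable fraction 0.150, mean twist 25.0 deg
#>   oxidized: mean min radius 1.62 A, permeable fraction 0.600, mean twist 30.7 deg
#>   differential H-bonds: 1
as.data.frame(report$comparisons$hbonds)
#>   donor_id acceptor_id occupancy1 occupancy2 delta
#> 1     X1:N      X101:O       0.85       0.05   0.8
```

Reading: the oxidized state is water-permeable in 60% of frames versus 15%
when reduced; its S6-like helices are twisted 5.7° further; and exactly one
hydrogen bond changes occupancy by more than the 0.20 threshold — the
planted redox-sensitive bond, present 85% of the time in the reduced state
and 5% in the oxidized one. All three numbers equal the generator's planted
ground truth.

Real data enter the same way: `states = list(list(label = "oxi",
topology = "top.pdb", trajectory = "traj.dcd", stride_ps = 100))`, with
gate planes given as heights or residue selections via `gates = ...`, and
`snapshot = list(last_ns = 500, stride_ps = 250)` to analyse 2000 trailing
snapshots. A thin CLI wrapper lives at `inst/scripts/gatescan.R`
(subcommands `synth` and `run`).

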