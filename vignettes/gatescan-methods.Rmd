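---
title: "gatescan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gatescan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tetrameric cation channels of the TRP family open and close by small,
coupled rearrangements of their pore-lining helices. A recurring analysis
task is to compare two conformational or chemical states of the same
channel — open versus closed, or a cysteine pair in its oxidized
(disulfide-bonded) versus reduced (free thiol) form — from molecular
dynamics trajectories, and to quantify where the states differ: in
per-residue flexibility, pore geometry and water conduction, helix
orientation, inter-residue distances, hydrogen bonding, and collective
backbone motion.

`gatescan` implements that comparison as a reusable, tested pipeline. Each
stage is an ordinary exported function over a small S3 data model (a
`structure_frame`, a `trajectory`, a `selection`), and `run_pipeline()`
chains them for a two-state experiment. Because production trajectories of
membrane channels are rarely redistributable, the package ships a
synthetic-channel generator with exhaustively known ground truth; the test
suite and the acceptance script exercise every stage against it.

```{r, eval = FALSE}
library(gatescan)
specs <- study_specs(seed = 1, n_frames = 2000)
pair <- morph_states(specs$reduced, specs$oxidized)
cfg <- run_config(
  states = list(list(label = "reduced", traj = pair$reduced),
                list(label = "oxidized", traj = pair$oxidized)),
  fit_spec = "residues 658-692, backbone",
  helix_spec = "residues 658-692",
  pore = list(z_range = c(-4, 4)),
  out_dir = "run_out")
report <- run_pipeline(cfg)
```

## The synthetic channel: what it emulates, and what it does not

`channel_spec()` describes a four-fold pseudo-symmetric bundle of ideal
α-helical backbone traces (N, CA, C, O per residue, built from canonical
φ = −57°, ψ = −47° by natural-extension chain growth) placed at a given
radius from the z axis, which is the pore axis by construction. Each helix
may be tilted *tangentially* (within the plane perpendicular to its radial
vector — this is precisely the twist angle the geometry stage measures) and
*radially* (within the z–radial plane — invisible to the twist angle by
construction). A gate ring of carbon pseudo-atoms is placed so that the
axis clearance equals the requested aperture analytically (ring radius =
aperture + 1.70 Å, the Bondi carbon radius). Optional extras: planted
donor–H–acceptor triplets whose geometry satisfies the hydrogen-bond
criteria in exactly `round(occupancy * n_frames)` frames; waters (single
`OW` pseudo-atoms) that either traverse the pore monotonically or oscillate
across the lower gate plane only; and a two-level aperture schedule with an
exact planted open-frame count.

`simulate_trajectory()` adds i.i.d. Gaussian displacement per helix atom,
per frame, with a per-residue σ (per coordinate), so the expected RMSF of a
residue is exactly σ√3. Every planted quantity — σ profile, tilt angles,
aperture schedule and implied permeable fraction, bond occupancies, water
counts, gate planes — is recorded in a manifest (`truth_manifest()`), and
recovery tests read truth only from the manifest.

What the generator deliberately does **not** emulate: temporal
autocorrelation (noise is white, so no relaxation times), anharmonic or
correlated residue motion (dihedral-PCA mode-recovery tests instead plant
modes directly in constructed dihedral series), membrane and solvent
environment, side chains, and any force-field energetics. Passing tests
therefore demonstrate that each estimator recovers the geometric and
statistical quantity it claims to measure — not that the pipeline's
defaults are optimal for any particular real system.

Default study conditions (`study_specs()`): a reduced/closed state with
closed aperture 0.59 Å, S6-like tangential tilt 25° and 15% open frames,
versus an oxidized/partially open state with open aperture 2.31 Å, tilt
30.7° and 60% open frames; one redox-sensitive planted hydrogen bond
(occupancy 0.85 vs 0.05) and one insensitive control (0.50 in both);
σ = 0.5 Å everywhere (RMSF ≈ 0.87 Å, rigid-helix territory). These mirror
the starting geometries and permeability statistics reported for
closed/open TRPV1 models in the redox-gating literature the package is
aimed at, and they are fixed: tests and the acceptance script treat them as
the experiment, not as tuning knobs.

## Superposition, RMSF, and the fractional difference

Frames are superposed by the Kabsch least-squares rotation over a fit
selection (default: the backbone of the transmembrane region, residues
432–713 in TRPV1 numbering; for the synthetic bundle, the helix backbone),
with the transform applied to all atoms. RMSF is computed per residue from
one representative atom (default Cα; whether a published profile used Cα or
all heavy atoms is often unstated, so the choice is an explicit, logged
default). The two-state comparison uses the fractional difference

$$\Delta \mathrm{RMSF}/\overline{\mathrm{RMSF}}
  = \frac{2\,(\mathrm{RMSF}_1 - \mathrm{RMSF}_2)}
         {\mathrm{RMSF}_1 + \mathrm{RMSF}_2},$$

a unitless, symmetric quantity bounded in [−2, 2]; the degenerate case
RMSF₁ + RMSF₂ = 0 is defined as 0. Per-chain profiles and a chain-averaged
profile are both available (`average_chains = TRUE`), since a tetramer
yields four estimates per residue position.

## Pore profiling

At each height z on a grid (default step 0.25 Å) the profiler finds the
largest probe sphere centred in that plane that touches no atom's van der
Waals surface, i.e. it maximises

$$f(p) = \min_i \big( \lVert p - a_i \rVert - r_i \big)$$

over probe centres p in the plane. Radii come from the Bondi table by
default (the HOLE "simple" set is available via
`vdw_table("hole_simple")`; unknown elements fall back to 1.70 Å). Values
are capped at `max_radius` (default 10 Å) and capped slices are flagged.

The search is deliberately **local**: five deterministic starts near the
previous slice's optimal centre, each climbed by a shrinking-step compass
pattern search (initial step 0.25 Å, terminating at 10⁻³ Å), then a coarse
grid around the incumbent and a final climb. Tracking the previous centre
is what lets the profiler follow the pore through a membrane-less
structure: a *global* search within the full lateral bound (default 8 Å)
would escape through the vacuum between the gate ring and the helix bundle,
where the lipid would be. Two useful consequences of the comparison-only
search: the result is exactly invariant in shape under a uniform shift of
all vdW radii (enlarging every radius by δ lowers every profile value by
exactly δ while the nearest-atom identity is unchanged), and repeated runs
are bit-identical — there is no annealing schedule and no RNG.

The per-frame minimum radius and its z location (ties toward smaller z)
form the gating time series. A frame is *water permeable* when its minimal
radius strictly exceeds 1.15 Å (the conventional threshold; a stricter
hydrophobic-gate criterion of ~2.0 Å is sometimes used instead, so the
threshold is a parameter, not a constant). Water permeation events are
counted per water as complete traversals of both gate planes — entered from
one side, exited on the other, with the lateral distance from the axis
within a bound for every in-between frame; oscillations across a single
plane and laterally escaping paths never count. Gate planes default to the
synthetic manifest's planes; for real structures they can be given as
heights or as residue selections (e.g. the selectivity-filter residues for
the upper gate and the S6 bundle-crossing residue for the lower gate).

## Domain geometry

*Radius of gyration* is the unweighted root-mean-square distance of the
selected (heavy) atoms to their centroid, per frame — a deliberate match to
the common "expansion/contraction" usage rather than a mass-weighted
moment.

*Twist angle*: the helix principal axis is the dominant eigenvector of the
3×3 positional covariance of the helix Cα atoms (equivalent to a
least-squares line fit), sign-fixed toward +z; the radial vector r̂ points
from the z axis to the helix centroid (the centroid is the natural anchor;
the definition leaves it open). The twist angle is the angle between ẑ and
the principal axis projected onto the plane perpendicular to r̂, bounded in
[0°, 90°]. Because r̂ ⊥ ẑ, the projection removes exactly the radial
component: tangential tilt is recovered identically and radial tilt is
annihilated, which the generator exploits as ground truth. A vanishing
projection (axis nearly parallel to r̂) is flagged degenerate rather than
reported as an angle.

*Distance maps*: the per-subunit Cα–Cα distance matrix is averaged over
frames; two states are compared by ΔD = D₁ − D₂ and a correlation map. By
default C[i, j] is the Pearson correlation of rows i and j of ΔD — each
residue's vector of distance changes to all others — which highlights
groups of residues that move as units between states. The alternative
reading (correlating D₁ rows against D₂ rows) is available with
`corr_on = "states"`. Zero-variance rows are reported as `NA` and listed,
never silently set to 1.

## Hydrogen bonds

A bond between acceptor A, donor hydrogen H and donor heavy atom D is
present in a frame iff d(A, D) < 3.0 Å **and** the A–H–D angle at the
hydrogen exceeds 135°, both strict — the boundary d = 3.0 Å is absent.
Hydrogens are paired to their covalent donor as the nearest N/O within
1.2 Å (S is excluded by default; element sets are parameters), same-residue
donor–acceptor pairs are skipped, and a donor with several hydrogens counts
as bonded if any of them satisfies the angle. Occupancy is the fraction of
frames a pair is present; pairs never present are omitted. The differential
table keeps bonds whose absolute occupancy difference between states
exceeds 0.20 (strict), using 0 for a bond absent from one state, sorted by
magnitude. The 20% rule is interpreted as an absolute difference in
occupancy, not a relative change.

## Dihedral PCA and free-energy surfaces

Backbone φ/ψ angles are extracted per frame from consecutive N, CA, C
atoms; terminal residues lack one dihedral each, and peptide bonds whose
C–N distance exceeds 2.0 Å in the time-mean structure are treated as chain
breaks (the mean structure, not a single frame, so that white-noise jitter
cannot fake a break). Each angle θ is mapped to (sin θ, cos θ) — the
standard dPCA device that removes the ±180° seam — and the covariance of
the stacked variables is eigen-decomposed; a raw-angle mode
(`circular = FALSE`) exists for comparison. Eigenvalues are clamped at 0
against numerical noise; trace conservation (Σλ = total variance) holds to
10⁻¹⁰ and is asserted in the tests.

The free-energy surface over (PC1, PC2) is the Boltzmann inversion of a 2D
histogram, F = −k_B·T·ln(n/n_max) in kcal/mol (k_B = 0.0019872041
kcal/mol/K), with empty bins undefined (`NA`) rather than infinite, the
lowest occupied bin at exactly 0, and defaults of 50×50 bins at T = 303 K —
the simulation temperature of the systems this pipeline targets (one
published account draws the same contours "at 300 K"; the temperature is a
parameter and the configured value is used exactly).

## Pipeline, determinism, and problem sizes

`run_pipeline()` runs the stages per state, isolates stage failures (a
failing stage is recorded and warned about; the rest proceed), writes one
CSV per stage plus a JSON report when an output directory is configured,
and computes the pairwise comparisons for the first two states. The
pipeline is a pure function of (inputs, config, seeds): reruns produce
byte-identical outputs, which the tests assert literally.

`snapshot_select(last_ns, stride_ps)` takes `floor(last_ns·1000/stride_ps)`
frames evenly from the trailing window — e.g. 2000 snapshots from the last
500 ns of a 100 ps-stride trajectory — accommodating the common cadences
(100 ps storage, 250 ps analysis) without requiring integer stride ratios.

Problem sizes used by the shipped tests and the acceptance script were
chosen as the smallest that pin each statistic well inside its tolerance:
2000 frames for parameter recovery (RMSF sampling error ≈ 1% per residue at
that depth, against a 5% tolerance; occupancies, permeation counts and
permeable fractions are planted exactly and recovered exactly at any
depth), 400–500 frames for distributional checks, and a 3 Å lateral bound
with a 0.05 Å brute-force grid for the profiler-versus-oracle comparisons
(a wider bound would make the vacuum outside a narrow constructed ring the
global optimum — the locality artifact the tracker exists to avoid).

## Known limitations

* The pore profiler assumes the pore axis is (aligned to) z;
  `orient_pore_axis()` provides an inertia-based pre-alignment for real
  structures, but strongly bent pores that a curved-centreline method would
  follow are out of scope.
* Water permeation counting uses a cylindrical lateral bound, not the
  instantaneous pore surface.
* Hydrogen-bond detection requires an explicitly protonated topology; no
  hydrogens are inferred.
* The synthetic generator's white noise makes time-correlation quantities
  (autocorrelation, relaxation) meaningless on synthetic data; only
  time-averaged statistics are validated there.
* Selections are chain/residue-number/atom-name based; no sequence-aware
  alignment between differently numbered constructs is attempted.
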