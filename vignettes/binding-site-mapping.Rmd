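---
title: "Mapping binding sites from docking poses with 3D self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping binding sites from docking poses with 3D self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somsite)
```

## The idea

When a chemical library is blind-docked over a whole protein surface, the
poses are not uniformly spread: regions that can actually bind ligands
collect many mutually consistent poses, while the rest of the surface
receives scattered, low-consensus placements. `somsite` turns that
observation into a binding-site predictor. All heavy-atom coordinates of
all retained docking poses form a 3D point cloud; a three-dimensional
non-periodic Kohonen self-organizing map (SOM) is trained on that cloud,
and regions of the map where neighboring neurons end up close together in
space — low values of the unified distance matrix (U-matrix) — mark dense,
homogeneous pose clusters. Connected sets of such low-U neurons
("consensual clusters", CCs) are the candidate binding sites, ranked by
neuron count.

This complements classical geometric cavity detection: a grid-based
cavity detector says where the protein *could* accommodate a ligand,
while the pose-consensus map says where docked ligands actually *want* to
go, and the two are cross-referenced (cavity membership, neuron density
per cavity).

## The model and its pieces

### Cavity detection

Space is discretized on a 0.5 Å grid. A probe-center position is allowed
when a probe sphere placed there overlaps no atom, i.e. its distance to
every atom is at least vdW(atom) + probe radius (the Lee–Richards
solvent-accessible convention). The solvent-accessible volume is the
union of 1.4 Å probe spheres over all allowed centers, including interior
centers with no path to the outside. Bulk solvent is what a 10 Å sphere
can sweep rolling in from outside: the union of bulk spheres over allowed
bulk centers that are 26-connected to the grid boundary. Cavities are the
first volume minus the second, clustered by 26-connectivity; clusters
smaller than 96 voxels (12 Å³, about one water molecule) are discarded
and the survivors labeled in decreasing volume order.

Two implementation notes. First, the sphere-coverage step is computed
with an exact Euclidean distance transform of the allowed-center masks,
which keeps the detector O(grid). Second, it matters that coverage — not
the raw center mask — defines the volumes: the naive "center accessible
to small probe but not to bulk probe" rule would wrap every structure in
a spurious shell between the two contact surfaces. `accessibility_mask()`
exposes the center-level masks for inspection; `detect_cavities()` works
on swept volumes.

The vdW radii default to the Bondi table (`default_vdw_radii()`) and can
be overridden; published cavity volumes from other implementations depend
on the radius table used, so exact volume reproduction may require radius
calibration.

### The SOM

The pose-atom cloud (n points) is analyzed by PCA: components V1..V3 with
lengths S1 ≥ S2 ≥ S3 (square roots of the covariance eigenvalues). Map
dimensions (I, J, K) are integers approximately proportional to the
lengths with I·J·K close to a target size of 15³ = 3375 neurons
(`map_dims()`); degenerate lengths are floored at S1/100 so flat or
linear clouds still give a 3D lattice (every dimension at least 2).
Neurons are initialized on a regular lattice spanning the projection
range of the data along each component.

Training presents every point once per cycle in a seeded random order,
with two phases: one cycle with radius decaying 7.5 → 3.75 and learning
rate 1 → 0.5, then ten cycles with 3.75 → 1 and 0.5 → 0.1. Both decay
exponentially within a phase, with the decay constant set to the phase's
total step count divided by 10, the step counter running across the
phase's cycles. Each presentation finds the best-matching unit (BMU,
Euclidean; ties go to the smallest flat index) and moves every neuron w
by α_t · exp(−d²/(2 r_t²)) · (x − w), where d is the distance in
map-index space to the BMU. The Gaussian kernel applied to all neurons is
the convention we adopt (the radius schedule alone does not pin down the
kernel); a hard radius cutoff is available via `kernel = "cutoff"` and
gives the same qualitative behavior. Same seed, same input: bit-identical
maps — the permutations are the only randomness and they are drawn from a
seeded generator.

### Thresholding and clusters

The U-value of a neuron is the mean Euclidean distance to its up-to-26
direct lattice neighbors (fewer at faces/edges/corners; the map is
non-periodic). The cutoff t_U separating consensual regions from
barriers is set automatically: Gaussian mixtures with 1..10 components
(unequal variances) are fitted to the U-value distribution, the component
count is chosen by BIC, and t_U = μ + σ of the largest-weight component.
The mixture fitting is delegated to `mclust`; its model-based
hierarchical initialization subsamples inputs larger than 2000 values
through the RNG, so the fit is seeded too.

Neurons with U ≤ t_U are aggregated by 26-connectivity into consensual
clusters, ranked by neuron count (ties: lower mean U, then smallest
member index). Per cluster, an overlap radius r_CC is derived the same
way: the distances between each member and its axis neighbors (±1 along
one lattice index) inside the cluster are fitted with a two-component
mixture and r_CC = μ + σ of the dominant component. On a perfectly
regular lattice all the distances are equal and that value is returned
directly. We read the cluster-radius neighbor count in the source
protocol ("4 neighbors per neuron except at the borders") as a 2D-slice
convention and use the six 3D axis neighbors restricted to cluster
members; this is a documented interpretation, not a stated rule.

### Evaluation

Given a reference (co-crystal) ligand, the precision of a cluster is the
fraction of ligand atoms within r_CC of any cluster neuron ("within"
means ≤ r_CC; the alternative reading "equal or superior" that appears
once in the source text would make precision measure non-overlap).
Success for a target requires precision above a threshold of 0.25 in the
default protocol; fixed radii of 1.6 Å (threshold 0.25, all atoms) and
2.0 Å (threshold 0.15, heavy atoms) are provided as the standard
literature comparison settings. Top1/Top3 success ask whether the hit is
the rank-1 cluster or within ranks 1–3. A separate, stricter occurrence
accounting marks a target as failed when the ligand overlaps zero or two
or more clusters.

### Chemical features and enrichment

Each docked fragment can be decomposed into circular substructures: the
environment of every heavy atom at radii 0–3 bonds, filtered to 3–7
heavy atoms, each assigned an order-invariant canonical identifier
(a Weisfeiler–Lehman hash of the rooted environment; identity semantics
require only stability across runs and atom orderings). The "diameter up
to 7 non-hydrogen atoms" phrasing of the source conflates bond diameter
and atom count; radius ≤ 3 plus the explicit 3–7 atom filter covers both
readings. The geometric center of each occurrence in each pose is a
point; SOMs trained on these centers are typically more acute than
atom-coordinate SOMs because averaging shrinks within-fragment spread.

A feature identifier is "docked at the active site" when any of its
centers lies within r_CC of an AS-cluster neuron. With F the docked
universe, F_AS the AS subset and F_A the features also present in known
active ligands, the package computes the enrichments |F_A|/|F|,
|F_A∩F_AS|/|F_AS|, |F_A∩F_AS̄|/|F_AS̄|, the sensitivity
Se = |F_A∩F_AS|/|F_A|, the specificity
Sp = |(F∖F_A)∩F_AS̄|/|F∖F_A| and the discrimination ratio Se/(1−Sp).
Significance is assessed by randomization: the AS set's identities are
resampled uniformly without replacement (preserving its size) a large
number of times (default one million in production; tests and the
bundled script use 10⁴–10⁵) and the Z-score is the distance of the
observed value from the null mean in null standard deviations; |Z| > 4
is called strongly significant. Uniform without-replacement resampling
is our choice of null law — it preserves |F_AS| exactly and makes the
null Se hypergeometric, which the tests exploit as a closed-form check.

## What the synthetic generators emulate

Everything above is testable offline because the package ships
generators with known ground truth:

* `make_hollow_receptor()` tiles carbon pseudo-atoms on concentric
  spherical shells (innermost layer at inner_radius + vdW), so the
  swept-volume void is analytically a ball and the truth volume is
  4/3 π r³. A flood-fill self-check guarantees sealedness; an optional
  mouth turns the void into an open pocket.
* `sample_poses()` plants 1–3 Gaussian pose pockets plus a diffuse
  uniform background, with scores normal around per-pocket means so the
  favored pocket scores best. The default study conditions
  (`planted_pocket_specs()`) are a 0.8-weight pocket at the origin, a
  0.15-weight pocket 18 Å away, 5% background, pocket sd 1 Å, 50 ligands
  × 20 poses, 3–8 heavy atoms per ligand, score means −8/−6/−4 (sd 0.5).
  The weights and pose count follow the planted-pocket recovery
  conditions; the remaining values were fixed once as realistic for
  fragment-sized ligands in a ~40 Å docking box. The `per_ligand` mode
  additionally gives each ligand a home site (85% of its poses) with
  strays going to the background — the pattern needed for meaningful
  never-docks-at-AS feature sets.
* `make_toy_library()` builds random connected C/N/O/S graphs (4–12
  heavy atoms, valence-correct, occasional ring) with SMILES output, and
  `embed_molecule()` gives them rigid 3D templates.

What these fixtures do *not* emulate: real docking energetics,
conformational flexibility (pose "ligands" are rigid), receptor-shaped
pose exclusion, and the chemistry of real fragment space. Passing tests
therefore demonstrate that the machinery — grids, maps, thresholds,
clusters, statistics — behaves as specified, not that the method's
published benchmark performance transfers; reproducing published
benchmark numbers requires external receptor/ligand sets and a docking
engine.

## Numerical choices and degenerate inputs

* Grid origins are snapped to multiples of the spacing, so translating a
  structure by grid multiples reproduces voxel counts exactly.
* BMU ties and cluster-count ties have deterministic tie-breaks (smallest
  flat index; lower mean U).
* Mixture fits that fail (tiny or near-degenerate inputs) fall back to
  mean + sd; inputs with variance below 1e-12 short-circuit to the common
  value.
* Clusters with no intra-cluster axis-neighbor pair have no r_CC; they
  are reported with `NA` and skipped by precision (an error if forced).
* Enrichment ratios with empty denominator sets are reported as `NA`
  (absent), never as 0; Se/(1−Sp) is `Inf` when Sp = 1 and Se > 0.
* Pose score ties at the max-poses cutoff keep file order (stable sort).
* Problem sizes in the test-suite and the acceptance script are chosen
  for fast, stable statistics: SOMs of 343–3375 neurons, 1000-pose
  clouds, 10–20 seeds per recovery estimate, 10⁴–10⁵ randomizations.

## Known limitations

* The cavity detector reports voxelized volumes; at 0.5 Å spacing a
  ~900 Å³ void is systematically underestimated by roughly 10% relative
  to a refined-grid evaluation. Volume *comparisons* (ordering, density
  normalization) are unaffected.
* PDBQT parsing covers the AutoDock Vina output dialect (MODEL blocks,
  `REMARK VINA RESULT`); exotic PDBQT flavors may need conversion.
* The simple SMILES writer/parser handles the uncharged organic subset
  the toy generator emits; general chemistry should enter via SDF.
* Feature identity is hash-based; distinct environments colliding to one
  identifier is astronomically unlikely but not impossible, and
  identifiers are not interchangeable with other packages' fingerprint
  ids.

## A minimal run

```{r pipeline, eval = FALSE}
sim <- sample_poses(planted_pocket_specs(), n_ligands = 50, seed = 1)
report <- run_pipeline(run_config(
  poses = sim$pose_sets,
  reference_ligand = sim$truth$reference_ligand,
  seed = 1, out_dir = "somsite_out"))
report$ccs[[1]]      # rank-1 cluster: neuron count, r_CC, centroid
report$evaluation    # precision per cluster, Top1/Top3 flags
```

The same stages are available individually (`detect_cavities()`,
`som_fit()`, `compute_umatrix()`, `umatrix_threshold()`,
`extract_ccs()`, `evaluate_target()`, `decompose()`,
`enrichment_report()`) for custom protocols.
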