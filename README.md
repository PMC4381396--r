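# somsite

Binding-site identification from docking poses with 3D self-organizing
maps.

## The problem

Finding where a ligand can bind on a protein surface is the first step of
structure-based drug design. Geometric cavity detectors say where a
pocket *exists*; `somsite` additionally asks where docked molecules
*congregate*. Blind-docking a chemical library over the whole protein
yields thousands of poses whose atoms pile up in genuinely bindable
pockets and scatter elsewhere. The package condenses that pose cloud into
a ranked list of candidate binding sites, and — when the library is
decomposed into chemical substructures — tells you which moieties
preferentially map into the active site.

It is aimed at computational chemists and structural bioinformaticians
who already have docking output (SDF / mol2 / PDBQT pose files with
scores) and want automated, reproducible site prediction plus
fragment-level chemical insight.

## The method

1. **Cavities** (optional, for characterization): space is discretized on
   a 0.5 Å grid; the solvent-accessible volume (union of 1.4 Å probe
   spheres over allowed Lee–Richards centers, interior included) minus
   the bulk-swept volume (10 Å probe rolling in from outside) is
   clustered by 26-connectivity; clusters under 12 Å³ are dropped.
2. **SOM**: all heavy-atom coordinates of all retained poses (the 20
   lowest-energy per ligand by default) train a 3D non-periodic Kohonen
   map. PCA sets the lattice orientation and the dimensions
   (I·J·K ≈ 15³, proportional to the cloud's principal lengths); training
   runs two exponential-decay phases, radius 7.5 → 3.75 then 3.75 → 1 (in
   lattice units), learning rate 1 → 0.5 then 0.5 → 0.1.
3. **Consensual clusters**: per neuron, the U-value is the mean distance
   to its ≤ 26 lattice neighbors. A BIC-selected Gaussian mixture on the
   U-values gives the cutoff t_U = μ + σ of the dominant component;
   neurons below it form 26-connected clusters ranked by size. Each
   cluster gets an overlap radius r_CC = μ + σ of the dominant mode of
   its intra-cluster neighbor distances.
4. **Evaluation / enrichment**: precision = fraction of reference-ligand
   atoms within r_CC of a cluster; success = precision > 0.25 (fixed-
   radius 1.6 Å / 2.0 Å conventions available). Morgan-style circular
   features (3–7 heavy atoms) of the docked fragments are located by
   their geometric centers; sensitivity, specificity and randomization
   Z-scores quantify how strongly "active" features concentrate in the
   active site.

Everything is deterministic under a single integer seed.

## Worked example

A synthetic screen with a known answer: 1000 poses (50 ligands × 20),
80% concentrated in a pocket at the origin, 15% in a second pocket 18 Å
away, 5% diffuse background.

```r
library(somsite)

sim <- sample_poses(planted_pocket_specs(), n_ligands = 50, seed = 1)
pts <- pose_coordinates(sim$pose_sets)

som <- som_fit(pts, seed = 1)
um  <- umatrix_threshold(compute_umatrix(som), seed = 1)
ccs <- extract_ccs(um, som)
ev  <- evaluate_target(ccs, som, sim$truth$reference_ligand)
```

which prints (via the objects' `print` methods):

```
som_map 34 x 10 x 10 (3400 neurons), trained (seed 1)
t_U = 0.633 A (GMM with 5 components)
CC rank 1: 1900 neurons, r_CC 0.407 A, centroid (-0.19, 0.02, 0.07)
CC rank 2: 19 neurons, r_CC 0.485 A, centroid (18.53, -0.30, 0.67)
CC rank 3: 1 neurons, r_CC NA A, centroid (18.40, 1.59, 1.46)
precisions: 1.00, 0.00, NA
hit at rank 1; Top1 TRUE, Top3 TRUE
```

Reading this: the map stretched along the pocket-pocket axis (34 × 10 ×
10); the rank-1 cluster sits 0.2 Å from the true major pocket center and
captures 100% of the probe ligand's atoms within its 0.41 Å consensus
radius, so the site is identified at rank 1 (Top1 success). The rank-2
cluster is the planted secondary pocket at (18, 0, 0). Single-neuron
clusters have no internal neighbor distances, hence no radius and no
precision.

For real data, replace the generator with your files:

```r
cfg <- run_config(receptor = "receptor.pdb",
                  poses = Sys.glob("poses/*.pdbqt"), pose_format = "pdbqt",
                  reference_ligand = "xtal_ligand.mol2",
                  seed = 1, out_dir = "out")
report <- run_pipeline(cfg)   # out/report.json, neuron PDB, cavity DX
```

A thin command-line wrapper lives at `inst/scripts/somsite.R`
(`run`, `cavities`, `synth` subcommands).

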