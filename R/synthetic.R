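# Synthetic fixtures with known ground truth: hollow receptors with an
# analytically known void, pose clouds with planted pockets, and small
# random molecule libraries. These generators emit the same objects and
# file formats the real pipeline consumes, so every stage is testable
# without external data.

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a hollow spherical pseudo-receptor
#'
#' Carbon pseudo-atoms tile concentric spherical shells. The innermost
#' atom layer sits at inner_radius + vdW, so the solvent-accessible void
#' (union of probe spheres over allowed interior centers) is, up to
#' tiling bumps, a ball of radius \code{inner_radius}: the truth volume
#' is 4/3 pi inner_radius^3. An optional mouth (cone of
#' removed atoms around +z) converts the interior cavity into an open
#' surface pocket. Sealedness of mouthless shells is verified by a
#' flood-fill self-check.
#'
#' @param inner_radius Radius of the probe-accessible void, Angstrom
#'   (> 2.8, i.e. twice the default probe).
#' @param shell_thickness Radial extent of the atom shell, Angstrom
#'   (default 2).
#' @param atom_spacing Approximate atom-atom spacing on each layer,
#'   Angstrom (default 1.0; must be <= 1.5 for a sealed shell).
#' @param mouth_radius Optional mouth radius, Angstrom; \code{NULL}
#'   (default) keeps the shell sealed.
#' @param probe Probe radius the void is calibrated for (default 1.4).
#' @param seed Integer seed (small random jitter of atom positions).
#' @return List with \code{structure} (a \code{protein_structure}) and
#'   \code{truth} (analytic void volume, void center, parameters).
#' @export
make_hollow_receptor <- function(inner_radius, shell_thickness = 2.0,
                                 atom_spacing = 1.0, mouth_radius = NULL,
                                 probe = 1.4, seed = 1L) {
  if (inner_radius <= 2 * probe)
    stopf("inner_radius must exceed twice the probe radius")
  if (atom_spacing > 1.5)
    stopf("atom_spacing > 1.5 A cannot guarantee a sealed shell")
  vdw <- 1.7 # carbon pseudo-atoms
  r0 <- inner_radius + vdw
  layers <- seq(r0, r0 + shell_thickness, by = atom_spacing * 0.75)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  xyz <- do.call(rbind, lapply(layers, function(rl) {
    n <- max(12L, ceiling(4 * pi * rl^2 / atom_spacing^2))
    pts <- fibonacci_sphere(n, rl)
    pts + matrix(rnorm(3 * n, sd = 0.03), ncol = 3)
  }))
  if (!is.null(mouth_radius)) {
    half_angle <- atan2(mouth_radius, inner_radius)
    ang <- acos(pmin(1, pmax(-1, xyz[, 3] / sqrt(rowSums(xyz^2)))))
    xyz <- xyz[ang > half_angle, , drop = FALSE]
  }
  if (nrow(xyz) == 0L) stopf("no shell atoms left")
  st <- new_protein_structure(xyz, rep("C", nrow(xyz)),
                              rep(vdw, nrow(xyz)), id = "synthetic-shell")
  if (is.null(mouth_radius)) {
    # flood-fill self-check: the center must not be reachable by the probe
    am <- accessibility_mask(st, probe, spacing = 0.5)
    center_idx <- round((-am$origin) / 0.5) + 1L
    if (am$bulk[center_idx[1], center_idx[2], center_idx[3]])
      stopf("shell is leaky: probe reaches the interior (reduce atom_spacing)")
  }
  list(structure = st,
       truth = list(void_volume = 4 / 3 * pi * inner_radius^3,
                    void_center = c(0, 0, 0),
                    inner_radius = inner_radius, probe = probe,
                    sealed = is.null(mouth_radius)))
}

#' Pocket specification for synthetic pose clouds
#' @param center Length-3 pocket center (Angstrom).
#' @param spread Gaussian sd of pose centers around it (Angstrom).
#' @param weight Fraction of poses landing in this pocket.
#' @param score_mean Mean docking score of poses in this pocket (lower =
#'   better).
#' @param label Pocket name.
#' @return A \code{pocket_spec} list.
#' @export
pocket_spec <- function(center, spread = 1.0, weight, score_mean = -8,
                        label = "pocket") {
  if (spread <= 0) stopf("spread must be positive")
  structure(list(center = as.numeric(center), spread = spread,
                 weight = weight, score_mean = score_mean, label = label),
            class = "pocket_spec")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: uniform over O(3) -> force det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Sample synthetic docked pose sets with planted pockets
#'
#' Each ligand is a rigid random cluster of heavy atoms (its "template").
#' Every pose places that template, randomly rotated, at a center drawn
#' from one of the pockets (Gaussian around the pocket center) or from
#' the diffuse uniform background; scores are normal around the pocket's
#' mean so the favored pocket scores lower. The remaining probability
#' mass after the pockets' weights is the background weight.
#'
#' @param pockets List of \code{pocket_spec} (weights summing to <= 1).
#' @param n_ligands Number of ligands.
#' @param poses_per_ligand Poses per ligand (default 20).
#' @param atoms_per_ligand Integer range for heavy-atom counts (default
#'   c(3, 8)).
#' @param background_box 2 x 3 matrix of lower/upper bounds of the
#'   diffuse background (default: pockets' bounding box padded by 10 A).
#' @param background_score Mean score of background poses (default -4).
#' @param score_sd Score noise sd (default 0.5).
#' @param molecules Optional list of \code{mol_graph}: poses then use the
#'   embedded molecule geometry as template (enables feature analysis).
#' @param per_ligand If \code{TRUE}, each ligand first draws a "home"
#'   component from the weights and then concentrates its poses there
#'   (85 percent home, the rest diffuse background), emulating
#'   ligand-specific site preference; the default \code{FALSE} assigns
#'   every pose independently.
#' @param seed Integer seed.
#' @return List with \code{pose_sets} (list of \code{pose_set}) and
#'   \code{truth}: per-pose pocket assignment table, the pocket specs,
#'   and a \code{reference_ligand} placed at the heaviest pocket's
#'   center.
#' @export
sample_poses <- function(pockets, n_ligands, poses_per_ligand = 20L,
                         atoms_per_ligand = c(3L, 8L),
                         background_box = NULL, background_score = -4,
                         score_sd = 0.5, molecules = NULL,
                         per_ligand = FALSE, seed = 1L) {
  if (n_ligands < 1L) stopf("need at least one ligand")
  w <- vapply(pockets, `[[`, numeric(1), "weight")
  if (any(w < 0) || sum(w) > 1 + 1e-9) stopf("pocket weights must be >= 0 and sum to <= 1")
  w_bg <- max(0, 1 - sum(w))
  centers <- do.call(rbind, lapply(pockets, `[[`, "center"))
  if (is.null(background_box))
    background_box <- rbind(apply(centers, 2, min) - 10,
                            apply(centers, 2, max) + 10)
  if (any(background_box[2, ] <= background_box[1, ]))
    stopf("degenerate background box")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  probs <- c(w, w_bg)
  truth_rows <- list()
  pose_sets <- vector("list", n_ligands)
  for (li in seq_len(n_ligands)) {
    lid <- sprintf("lig%03d", li)
    if (is.null(molecules)) {
      n_atoms <- sample(seq(atoms_per_ligand[1], atoms_per_ligand[2]), 1L)
      template <- matrix(rnorm(3 * n_atoms, sd = 1.2), ncol = 3)
      template <- sweep(template, 2, colMeans(template))
      elements <- rep("C", n_atoms)
    } else {
      mol <- molecules[[(li - 1L) %% length(molecules) + 1L]]
      template <- embed_molecule(mol, seed = seed + li)
      template <- sweep(template, 2, colMeans(template))
      elements <- mol$elements
      lid <- mol$id
    }
    home <- if (per_ligand) sample.int(length(probs), 1L, prob = probs)
            else NA_integer_
    poses <- vector("list", poses_per_ligand)
    for (pi in seq_len(poses_per_ligand)) {
      comp <- if (per_ligand) {
        # stray poses scatter into the background, not the other pockets
        if (runif(1) < 0.85) home else length(probs)
      } else sample.int(length(probs), 1L, prob = probs)
      if (comp <= length(pockets)) {
        pk <- pockets[[comp]]
        ctr <- rnorm(3, pk$center, pk$spread)
        score <- rnorm(1, pk$score_mean, score_sd)
        label <- pk$label
      } else {
        ctr <- runif(3, background_box[1, ], background_box[2, ])
        score <- rnorm(1, background_score, score_sd)
        label <- "background"
      }
      xyz <- template %*% t(random_rotation())
      xyz <- sweep(xyz, 2, ctr, `+`)
      poses[[pi]] <- list(pose_index = pi, xyz = xyz, element = elements,
                          score = score)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(ligand_id = lid, pose_index = pi, assignment = label)
    }
    pose_sets[[li]] <- truncate_poses(new_pose_set(lid, poses),
                                      poses_per_ligand)
  }
  names(pose_sets) <- vapply(pose_sets, `[[`, character(1), "ligand_id")
  major <- pockets[[which.max(w)]]
  ref_template <- matrix(rnorm(3 * 8, sd = 1.2), ncol = 3)
  ref_template <- sweep(ref_template, 2, colMeans(ref_template))
  ref <- reference_ligand(sweep(ref_template, 2, major$center, `+`))
  list(pose_sets = pose_sets,
       truth = list(assignments = do.call(rbind, truth_rows),
                    pockets = pockets, background_weight = w_bg,
                    per_ligand = per_ligand,
                    majority_pocket = major, reference_ligand = ref))
}

#' Default planted-pocket study conditions
#'
#' The two-pocket fixture used throughout the tests: a major pocket
#' (weight 0.8) at the origin, a minor pocket (weight 0.15) 18 A away,
#' and 5 percent diffuse background; pocket sd 1 A; scores favor the
#' major pocket (-8) over the minor (-6) and the background (-4).
#'
#' @return List of two \code{pocket_spec}.
#' @export
planted_pocket_specs <- function() {
  list(pocket_spec(c(0, 0, 0), spread = 1.0, weight = 0.80,
                   score_mean = -8, label = "major"),
       pocket_spec(c(18, 0, 0), spread = 1.0, weight = 0.15,
                   score_mean = -6, label = "minor"))
}

element_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L)

#' Generate a small random molecule library
#'
#' Random connected heavy-atom graphs of 4-12 atoms (C/N/O/S with valid
#' valences, single bonds, occasional one-ring closure), returned as
#' \code{mol_graph} objects with their SMILES strings. Deterministic
#' under the seed.
#'
#' @param n_molecules Number of molecules.
#' @param seed Integer seed.
#' @param n_atoms_range Heavy-atom count range (default c(4, 12)).
#' @return List of \code{mol_graph}; SMILES in attribute \code{smiles}
#'   and per-molecule \code{$smiles} field.
#' @export
make_toy_library <- function(n_molecules, seed = 1L,
                             n_atoms_range = c(4L, 12L)) {
  if (n_molecules < 1L) stopf("need n_molecules >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  mols <- lapply(seq_len(n_molecules), function(m) {
    n <- sample(seq(n_atoms_range[1], n_atoms_range[2]), 1L)
    ele <- sample(names(element_valence), n, replace = TRUE,
                  prob = c(0.70, 0.15, 0.10, 0.05))
    free <- element_valence[ele]
    bonds <- matrix(integer(0), ncol = 3)
    for (a in 2:n) {
      hosts <- which(free[seq_len(a - 1L)] > 0L)
      if (length(hosts) == 0L) { # restart-free fallback: bond to atom 1 as C
        ele[1] <- "C"; free[1] <- free[1] + 1L; hosts <- 1L
      }
      h <- hosts[sample.int(length(hosts), 1L)]
      bonds <- rbind(bonds, c(h, a, 1L))
      free[h] <- free[h] - 1L
      free[a] <- free[a] - 1L
    }
    # occasional single ring closure between non-adjacent atoms
    if (n >= 5L && runif(1) < 0.3) {
      cand <- which(free > 0L)
      if (length(cand) >= 2L) {
        pair <- sample(cand, 2L)
        adjacent <- any((bonds[, 1] == pair[1] & bonds[, 2] == pair[2]) |
                        (bonds[, 1] == pair[2] & bonds[, 2] == pair[1]))
        if (!adjacent) bonds <- rbind(bonds, c(min(pair), max(pair), 1L))
      }
    }
    mol <- mol_graph(ele, bonds, id = sprintf("toy%04d", m))
    mol$smiles <- write_smiles(mol)
    mol
  })
  names(mols) <- vapply(mols, `[[`, character(1), "id")
  attr(mols, "smiles") <- vapply(mols, `[[`, character(1), "smiles")
  mols
}

#' Embed a molecular graph in 3D
#'
#' Simple deterministic geometry for synthetic poses: atoms placed by a
#' breadth-first walk with 1.5 A bonds and short-range repulsion; not a
#' chemically refined conformer, just a rigid template with correct
#' connectivity-driven shape.
#'
#' @param mol A \code{mol_graph}.
#' @param seed Integer seed.
#' @return n x 3 coordinate matrix (Angstrom).
#' @export
embed_molecule <- function(mol, seed = 1L) {
  n <- length(mol$elements)
  adj <- mol_adjacency(mol)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- 0
  placed <- 1L # indices of placed atoms
  queue <- 1L
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (b in adj$nbr[[a]]) {
      if (!is.na(xyz[b, 1])) next
      min_sep <- 1.1
      for (attempt in seq_len(200)) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- xyz[a, ] + 1.5 * dir
        d <- sqrt(rowSums((xyz[placed, , drop = FALSE] -
                             matrix(cand, length(placed), 3, byrow = TRUE))^2))
        if (all(d > min_sep)) break
        if (attempt %% 50 == 0) min_sep <- min_sep * 0.8 # relax if crowded
      }
      xyz[b, ] <- cand
      placed <- c(placed, b)
      queue <- c(queue, b)
    }
  }
  xyz
}
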