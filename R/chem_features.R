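# Circular (Morgan-style) chemical features: decomposition of heavy-atom
# molecular graphs into centered circular substructures of radius 0..3
# bonds, filtered to 3-7 heavy atoms, with order-invariant integer
# identifiers; plus geometric feature centers per docked pose and their
# assignment to consensual clusters.

#' Construct a heavy-atom molecular graph
#'
#' @param elements Character vector of element symbols (heavy atoms only).
#' @param bonds Two-column integer matrix (or data.frame) of bonded atom
#'   index pairs; an optional third column gives the bond order (default
#'   1).
#' @param id Molecule identifier.
#' @return A \code{mol_graph}: list with \code{elements}, \code{bonds}
#'   (matrix with columns i, j, order), \code{id}.
#' @export
mol_graph <- function(elements, bonds, id = "mol") {
  elements <- toupper(as.character(elements))
  if (length(elements) < 1L) stopf("molecule '%s' has no atoms", id)
  if (any(elements == "H")) stopf("mol_graph holds heavy atoms only")
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0L) {
    if (ncol(bonds) == 2L) bonds <- cbind(bonds, 1L)
    storage.mode(bonds) <- "integer"
    if (any(bonds[, 1:2] < 1L | bonds[, 1:2] > length(elements)))
      stopf("bond index out of range in '%s'", id)
    if (any(bonds[, 1] == bonds[, 2])) stopf("self-bond in '%s'", id)
  } else bonds <- matrix(integer(0), ncol = 3)
  colnames(bonds) <- c("i", "j", "order")
  structure(list(elements = elements, bonds = bonds, id = id),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph '%s': %d heavy atoms, %d bonds\n", x$id,
              length(x$elements), nrow(x$bonds)))
  invisible(x)
}

mol_adjacency <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  ord <- vector("list", n)
  if (nrow(mol$bonds)) for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]; o <- mol$bonds[b, 3]
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  list(nbr = adj, order = ord)
}

# Canonical Weisfeiler-Lehman hash of the subgraph induced by `atoms`,
# rooted at `center`. Initial labels combine element and degree inside the
# subgraph; three refinement rounds then a final order-invariant combine.
wl_environment_id <- function(mol, atoms, center, adj) {
  sub <- sort(atoms)
  pos <- match(seq_along(mol$elements), sub) # atom -> position or NA
  nbr <- lapply(sub, function(a) {
    keep <- !is.na(pos[adj$nbr[[a]]])
    list(n = pos[adj$nbr[[a]]][keep], o = adj$order[[a]][keep])
  })
  lab <- vapply(seq_along(sub), function(p)
    paste0(mol$elements[sub[p]], "/", length(nbr[[p]]$n)), character(1))
  for (round in 1:3) {
    lab <- vapply(seq_along(sub), function(p) {
      msgs <- sort(paste0(nbr[[p]]$o, ":", lab[nbr[[p]]$n]))
      paste0(lab[p], "|", paste(msgs, collapse = ","))
    }, character(1))
    lab <- vapply(lab, function(s) as.character(hash31(s)), character(1),
                  USE.NAMES = FALSE)
  }
  root <- lab[match(center, sub)]
  hash31(paste0("R", root, "#", paste(sort(lab), collapse = ".")))
}

#' Decompose a molecule into circular chemical features
#'
#' Enumerates the circular environment of every heavy atom for radii 0..3
#' bonds (covering substructures up to 7 atoms across), keeps occurrences
#' with 3 to 7 heavy atoms, assigns each environment an order-invariant
#' canonical integer identifier, and deduplicates identical (identifier,
#' atom set) occurrences.
#'
#' @param mol A \code{mol_graph}.
#' @param radii Bond radii to enumerate (default 0:3).
#' @param min_atoms,max_atoms Heavy-atom count filter (defaults 3 and 7).
#' @return data.frame with columns \code{feature_id} (integer),
#'   \code{radius}, \code{heavy_atom_count}, \code{atoms} (list column of
#'   member atom indices), \code{ligand_id}.
#' @export
decompose <- function(mol, radii = 0:3, min_atoms = 3L, max_atoms = 7L) {
  if (!inherits(mol, "mol_graph")) stopf("mol must be a mol_graph")
  n <- length(mol$elements)
  adj <- mol_adjacency(mol)
  recs <- list()
  seen <- character(0)
  for (center in seq_len(n)) {
    reach <- center
    for (r in sort(radii)) {
      if (r > 0) {
        grown <- unique(c(reach, unlist(adj$nbr[reach])))
        if (length(grown) == length(reach) && r > 1) break # environment saturated
        reach <- grown
      }
      cnt <- length(reach)
      if (cnt < min_atoms || cnt > max_atoms) next
      fid <- wl_environment_id(mol, reach, center, adj)
      key <- paste0(fid, "@", paste(sort(reach), collapse = ","))
      if (key %in% seen) next
      seen <- c(seen, key)
      recs[[length(recs) + 1L]] <-
        list(feature_id = fid, radius = r, heavy_atom_count = cnt,
             atoms = sort(reach))
    }
  }
  if (length(recs) == 0L)
    return(data.frame(feature_id = integer(), radius = integer(),
                      heavy_atom_count = integer(),
                      atoms = I(list()), ligand_id = character()))
  out <- data.frame(
    feature_id = vapply(recs, `[[`, integer(1), "feature_id"),
    radius = vapply(recs, `[[`, integer(1), "radius"),
    heavy_atom_count = vapply(recs, `[[`, integer(1), "heavy_atom_count"))
  out$atoms <- I(lapply(recs, `[[`, "atoms"))
  out$ligand_id <- mol$id
  out
}

#' Geometric centers of feature occurrences in a docked pose
#'
#' @param features Feature table from \code{\link{decompose}}.
#' @param pose_xyz n x 3 heavy-atom coordinates of one docked pose, in the
#'   molecule's atom order (or use \code{index_map} when orders differ).
#' @param pose_index Pose index recorded in the output.
#' @param index_map Optional integer map: molecule atom i sits at pose row
#'   \code{index_map[i]}.
#' @return data.frame with \code{feature_id}, \code{ligand_id},
#'   \code{pose_index}, \code{x}, \code{y}, \code{z} (the arithmetic mean
#'   of the member atom coordinates).
#' @export
feature_centers <- function(features, pose_xyz, pose_index = 1L,
                            index_map = NULL) {
  pose_xyz <- as_xyz_matrix(pose_xyz, "pose coordinates")
  need <- if (nrow(features)) max(vapply(features$atoms, max, integer(1))) else 0L
  if (is.null(index_map)) {
    if (need > nrow(pose_xyz))
      stopf("pose has %d atoms but features reference atom %d; supply index_map",
            nrow(pose_xyz), need)
    index_map <- seq_len(nrow(pose_xyz))
  }
  ctr <- t(vapply(features$atoms, function(a)
    colMeans(pose_xyz[index_map[a], , drop = FALSE]), numeric(3)))
  data.frame(feature_id = features$feature_id,
             ligand_id = features$ligand_id,
             pose_index = pose_index,
             x = ctr[, 1], y = ctr[, 2], z = ctr[, 3])
}

#' Assign feature centers to the active-site cluster
#'
#' A feature identifier is "docked at the active site" if any of its
#' occurrence centers lies within the AS cluster's r_CC of any AS-cluster
#' neuron; identifiers with no center ever at the AS form the complement.
#'
#' @param centers Feature-center table (rows as from
#'   \code{\link{feature_centers}}, possibly many poses concatenated).
#' @param ccs List of \code{consensual_cluster}.
#' @param som The \code{som_map}.
#' @param as_rank Rank of the cluster designated as the active site.
#' @param radius Overlap radius (default: the AS cluster's r_CC).
#' @return List with \code{as_features} and \code{non_as_features}
#'   (integer identifier sets partitioning the observed identifiers) and
#'   the logical per-row \code{center_in_as}.
#' @export
assign_to_ccs <- function(centers, ccs, som, as_rank = 1L, radius = NULL) {
  ranks <- vapply(ccs, `[[`, integer(1), "rank")
  pos <- match(as_rank, ranks)
  if (is.na(pos)) stopf("no cluster with rank %d", as_rank)
  as_cc <- ccs[[pos]]
  radius <- radius %||% as_cc$r_cc
  if (!is.finite(radius)) stopf("AS cluster has no usable r_CC")
  xyz <- as.matrix(centers[, c("x", "y", "z")])
  dmin <- cpp_min_dist(xyz, som$codes[as_cc$members, , drop = FALSE])
  in_as <- dmin <= radius
  all_ids <- unique(centers$feature_id)
  as_ids <- unique(centers$feature_id[in_as])
  list(as_features = as_ids,
       non_as_features = setdiff(all_ids, as_ids),
       center_in_as = in_as)
}

#' Write a feature table to a tab-separated file
#' @param features Table from \code{\link{decompose}} (atoms list column
#'   is serialized as comma-separated indices).
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  out$atoms <- vapply(features$atoms, paste, character(1), collapse = ",")
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal SMILES support (subset emitted by make_toy_library) --------

#' Parse a simple SMILES string into a molecular graph
#'
#' Supports the organic-subset atoms C, N, O, S, P, F, Cl, Br, I (no
#' brackets, charges or aromatic lower-case forms), single/double/triple
#' bonds, branches and ring-closure digits — the dialect written by
#' \code{\link{write_smiles}} and \code{\link{make_toy_library}}. For
#' general chemistry read an SDF via ChemmineR instead.
#'
#' @param smiles SMILES string.
#' @param id Molecule id.
#' @return A \code{mol_graph}.
#' @export
parse_smiles <- function(smiles, id = smiles) {
  chars <- strsplit(smiles, "")[[1]]
  elements <- character(0)
  bonds <- matrix(integer(0), ncol = 3)
  stack <- integer(0)
  prev <- NA_integer_
  pending_order <- 1L
  rings <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stopf("unbalanced ')' in SMILES '%s'", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == "-") { pending_order <- 1L; i <- i + 1L; next }
    if (ch == "=") { pending_order <- 2L; i <- i + 1L; next }
    if (ch == "#") { pending_order <- 3L; i <- i + 1L; next }
    if (grepl("[0-9]", ch)) {
      key <- ch
      if (!is.null(rings[[key]])) {
        bonds <- rbind(bonds, c(rings[[key]], prev, pending_order))
        rings[[key]] <- NULL
      } else rings[[key]] <- prev
      pending_order <- 1L
      i <- i + 1L; next
    }
    ele <- toupper(ch)
    if (ch %in% c("C", "B") && i < length(chars) &&
        chars[i + 1L] %in% c("l", "r")) {
      ele <- paste0(ch, chars[i + 1L])
      i <- i + 1L
    }
    if (!toupper(ele) %in% c("C", "N", "O", "S", "P", "F", "CL", "BR", "I"))
      stopf("unsupported SMILES atom '%s' in '%s'", ele, smiles)
    elements <- c(elements, toupper(ele))
    idx <- length(elements)
    if (!is.na(prev)) bonds <- rbind(bonds, c(prev, idx, pending_order))
    pending_order <- 1L
    prev <- idx
    i <- i + 1L
  }
  if (length(rings)) stopf("unclosed ring bond in SMILES '%s'", smiles)
  if (length(stack)) stopf("unbalanced '(' in SMILES '%s'", smiles)
  mol_graph(elements, bonds, id = id)
}

#' Write a molecular graph as a simple SMILES string
#'
#' Depth-first traversal with branches and ring-closure digits; all bond
#' orders are emitted explicitly except single bonds.
#'
#' @param mol A \code{mol_graph} (must be connected).
#' @return SMILES string.
#' @export
write_smiles <- function(mol) {
  n <- length(mol$elements)
  adj <- mol_adjacency(mol)
  bond_sym <- function(o) c("", "=", "#")[o]
  # pass 1: DFS tree + back (ring-closure) edges
  visited <- logical(n)
  children <- vector("list", n)   # per atom: tree children in visit order
  child_ord <- vector("list", n)
  closure <- vector("list", n)    # per atom: closure strings to append
  ring_n <- 0L
  used <- new.env(parent = emptyenv()) # edges consumed as tree or ring
  edge_key <- function(a, b) paste(min(a, b), max(a, b), sep = "-")
  dfs <- function(a) {
    visited[a] <<- TRUE
    nbrs <- adj$nbr[[a]]; ords <- adj$order[[a]]
    for (q in seq_along(nbrs)) {
      b <- nbrs[q]
      key <- edge_key(a, b)
      if (!is.null(used[[key]])) next
      if (visited[b]) {
        # back edge discovered at its second endpoint: digit goes to both
        used[[key]] <- TRUE
        ring_n <<- ring_n + 1L
        if (ring_n > 9L) stopf("more than 9 ring closures not supported")
        d <- as.character(ring_n)
        closure[[a]] <<- c(closure[[a]], paste0(bond_sym(ords[q]), d))
        closure[[b]] <<- c(closure[[b]], d)
      } else {
        used[[key]] <- TRUE
        children[[a]] <<- c(children[[a]], b)
        child_ord[[a]] <<- c(child_ord[[a]], ords[q])
        dfs(b)
      }
    }
  }
  dfs(1L)
  if (!all(visited)) stopf("molecule '%s' is not connected", mol$id)
  # pass 2: emit
  emit <- function(a) {
    sym <- mol$elements[a]
    if (nchar(sym) == 2L) sym <- paste0(substr(sym, 1, 1),
                                        tolower(substr(sym, 2, 2)))
    out <- paste0(sym, paste(closure[[a]], collapse = ""))
    ch <- children[[a]]
    for (q in seq_along(ch)) {
      piece <- paste0(bond_sym(child_ord[[a]][q]), emit(ch[q]))
      out <- if (q < length(ch)) paste0(out, "(", piece, ")")
             else paste0(out, piece)
    }
    out
  }
  emit(1L)
}

#' Read molecules from an SDF file as molecular graphs
#'
#' Hydrogens are dropped; bond indices are remapped to the heavy-atom
#' subgraph.
#'
#' @param path SDF file.
#' @return List of \code{mol_graph} keyed by molecule name.
#' @export
read_molecules_sdf <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  out <- lapply(seq_along(ChemmineR::sdfid(sdfs)), function(m) {
    sdf <- sdfs[[m]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    ele <- toupper(sub("_.*$", "", rownames(ab)))
    heavy <- which(ele != "H")
    remap <- match(seq_along(ele), heavy)
    bonds <- if (nrow(bb)) {
      keep <- !is.na(remap[bb[, 1]]) & !is.na(remap[bb[, 2]])
      cbind(remap[bb[keep, 1]], remap[bb[keep, 2]], bb[keep, 3])
    } else matrix(integer(0), ncol = 3)
    mol_graph(ele[heavy], bonds, id = ChemmineR::sdfid(sdfs)[m])
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}
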