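# Reading receptors, docked pose sets and reference ligands; writing
# neuron/cavity pseudo-atom PDB files and pose SDF files.

#' Bondi van der Waals radii
#'
#' Default element-to-radius table (in Angstrom) used when reading
#' receptors. Any element can be overridden or added by name.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    ZN = 1.39, MG = 1.73, CA = 2.31, MN = 2.05, FE = 2.05, `NA` = 2.27,
    K = 2.75, CU = 1.40, NI = 1.63, CO = 2.00, CD = 1.58, HG = 1.55)
}

new_protein_structure <- function(xyz, element, radius, id = "structure") {
  xyz <- as_xyz_matrix(xyz, "atom coordinates")
  if (nrow(xyz) < 1L) stopf("a structure needs at least one atom")
  if (any(!is.finite(radius)) || any(radius <= 0))
    stopf("all vdW radii must be positive and finite")
  structure(list(xyz = xyz, element = toupper(element),
                 radius = as.numeric(radius), id = id),
            class = "protein_structure")
}

#' Read a receptor structure from a PDB file
#'
#' One atom per ATOM (and optionally HETATM) record. Hydrogens are dropped
#' by default; each element is assigned a van der Waals radius from
#' \code{radius_table}.
#'
#' @param path Path to a PDB file.
#' @param radius_table Named numeric vector mapping element symbols to vdW
#'   radii in Angstrom (default \code{\link{default_vdw_radii}}).
#' @param include_het Include HETATM records (default \code{FALSE}).
#' @param keep_hydrogens Keep hydrogen atoms (default \code{FALSE}).
#' @param default_radius Radius used for elements missing from the table;
#'   if \code{NULL} (default) an unknown element is an error.
#' @param id Label for the structure (default: file name).
#' @return A \code{protein_structure}: list with \code{xyz} (n x 3 matrix,
#'   Angstrom), \code{element}, \code{radius}, \code{id}.
#' @export
read_receptor <- function(path, radius_table = default_vdw_radii(),
                          include_het = FALSE, keep_hydrogens = FALSE,
                          default_radius = NULL, id = basename(path)) {
  if (!file.exists(path)) stopf("receptor file not found: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stopf("cannot parse PDB '%s': %s",
                                            path, conditionMessage(e)))
  at <- pdb$atom
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  ele <- toupper(at$elesy)
  missing_ele <- is.na(ele) | ele == ""
  if (any(missing_ele))
    ele[missing_ele] <- toupper(bio3d::atom2ele(at$elety[missing_ele]))
  if (!keep_hydrogens) {
    keep <- ele != "H" & ele != "D"
    at <- at[keep, , drop = FALSE]
    ele <- ele[keep]
  }
  if (nrow(at) == 0L) stopf("no heavy atoms in '%s'", path)
  names(radius_table) <- toupper(names(radius_table))
  rad <- unname(radius_table[ele])
  if (anyNA(rad)) {
    if (is.null(default_radius)) {
      unknown <- unique(ele[is.na(rad)])
      stopf("no vdW radius for element(s): %s (supply default_radius or extend radius_table)",
            paste(unknown, collapse = ", "))
    }
    rad[is.na(rad)] <- default_radius
  }
  new_protein_structure(cbind(at$x, at$y, at$z), ele, rad, id = id)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure '%s': %d atoms, %d elements\n",
              x$id, nrow(x$xyz), length(unique(x$element))))
  invisible(x)
}

new_pose_set <- function(ligand_id, poses) {
  if (length(poses) < 1L) stopf("pose set '%s' has no poses", ligand_id)
  for (p in poses) {
    if (nrow(p$xyz) < 1L) stopf("pose without atoms in '%s'", ligand_id)
    if (!is.finite(p$score)) stopf("non-finite score in '%s'", ligand_id)
  }
  structure(list(ligand_id = ligand_id, poses = poses), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("pose_set '%s': %d poses, scores [%.2f, %.2f]\n", x$ligand_id,
              length(x$poses), min(pose_scores(x)), max(pose_scores(x))))
  invisible(x)
}

#' Scores of all poses in a pose set
#' @param x A \code{pose_set}.
#' @return Numeric vector of docking scores.
#' @export
pose_scores <- function(x) vapply(x$poses, function(p) p$score, numeric(1))

truncate_poses <- function(ps, max_poses) {
  sc <- pose_scores(ps)
  # order() is stable: score ties keep file order, so truncation is
  # deterministic and idempotent
  ps$poses <- ps$poses[order(sc)[seq_len(min(max_poses, length(sc)))]]
  ps
}

#' Read docked ligand pose sets
#'
#' Reads multi-pose files in SDF, mol2 or PDBQT format. Per ligand, poses
#' are sorted by increasing docking score and truncated to the
#' \code{max_poses} lowest-energy poses. Scores are taken from an SDF data
#' tag, PDBQT \code{REMARK VINA RESULT} lines, or a sidecar score table.
#'
#' @param paths Character vector of pose files.
#' @param format One of \code{"sdf"}, \code{"mol2"}, \code{"pdbqt"}.
#' @param max_poses Maximum number of (lowest-score) poses kept per ligand.
#' @param score_tag SDF data field holding the docking score.
#' @param scores Optional sidecar score table: a data.frame (or path to a
#'   tab-separated file) with columns \code{ligand_id}, \code{pose_index},
#'   \code{score}. Required for formats without embedded scores.
#' @param heavy_only Drop hydrogen atoms from poses (default \code{TRUE}).
#' @return List of \code{pose_set} objects, keyed by ligand id.
#' @export
read_poses <- function(paths, format = c("sdf", "mol2", "pdbqt"),
                       max_poses = 20L, score_tag = "score",
                       scores = NULL, heavy_only = TRUE) {
  format <- match.arg(format)
  if (max_poses < 1L) stopf("max_poses must be positive")
  if (is.character(scores))
    scores <- read.table(scores, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  raw <- list() # each: list(ligand_id, pose_index, xyz, element, score or NA)
  for (path in paths) {
    if (!file.exists(path)) stopf("pose file not found: %s", path)
    raw <- c(raw, switch(format,
      sdf   = read_poses_sdf(path, score_tag),
      mol2  = read_poses_mol2(path),
      pdbqt = read_poses_pdbqt(path)))
  }
  if (length(raw) == 0L) stopf("no poses found in input")
  if (heavy_only) {
    raw <- lapply(raw, function(p) {
      keep <- toupper(p$element) != "H"
      if (!any(keep)) return(NULL)
      p$xyz <- p$xyz[keep, , drop = FALSE]
      p$element <- p$element[keep]
      p
    })
    raw <- Filter(Negate(is.null), raw)
    if (length(raw) == 0L) stopf("no heavy atoms in any pose")
  }
  for (idx in seq_along(raw)) {
    p <- raw[[idx]]
    if (is.na(p$score)) {
      if (is.null(scores))
        stopf("pose %d of ligand '%s' has no score and no sidecar table was given",
              p$pose_index, p$ligand_id)
      hit <- scores$ligand_id == p$ligand_id & scores$pose_index == p$pose_index
      if (sum(hit) != 1L)
        stopf("sidecar score table has %d entries for ligand '%s' pose %d",
              sum(hit), p$ligand_id, p$pose_index)
      raw[[idx]]$score <- scores$score[hit]
    }
  }
  ids <- vapply(raw, `[[`, character(1), "ligand_id")
  out <- lapply(split(raw, factor(ids, levels = unique(ids))), function(ps) {
    poses <- lapply(ps, function(p)
      list(pose_index = p$pose_index, xyz = p$xyz, element = p$element,
           score = p$score))
    truncate_poses(new_pose_set(ps[[1]]$ligand_id, poses), max_poses)
  })
  names(out) <- unique(ids)
  out
}

read_poses_sdf <- function(path, score_tag) {
  # zero-bond pose records are legitimate here; silence validSDF chatter
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  suppressWarnings(ChemmineR::cid(sdfs) <- ChemmineR::sdfid(sdfs))
  counter <- new.env(parent = emptyenv())
  lapply(seq_along(ChemmineR::cid(sdfs)), function(m) {
    sdf <- sdfs[[m]]
    ab <- ChemmineR::atomblock(sdf)
    ele <- sub("_.*$", "", rownames(ab))
    db <- ChemmineR::datablock(sdf)
    score <- if (score_tag %in% names(db))
      suppressWarnings(as.numeric(db[[score_tag]])) else NA_real_
    lid <- ChemmineR::sdfid(sdf)
    n_prev <- get0(lid, envir = counter, ifnotfound = 0L)
    assign(lid, n_prev + 1L, envir = counter)
    list(ligand_id = lid, pose_index = n_prev + 1L,
         xyz = unname(ab[, 1:3, drop = FALSE]), element = ele, score = score)
  })
}

read_poses_mol2 <- function(path) {
  txt <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", txt)
  if (length(starts) == 0L) stopf("no @<TRIPOS>MOLECULE record in '%s'", path)
  ends <- c(starts[-1] - 1L, length(txt))
  counter <- new.env(parent = emptyenv())
  lapply(seq_along(starts), function(m) {
    chunk <- txt[starts[m]:ends[m]]
    tf <- tempfile(fileext = ".mol2")
    on.exit(unlink(tf))
    writeLines(chunk, tf)
    mol <- bio3d::read.mol2(tf)
    at <- mol$atom
    # elety holds the SYBYL atom type (C.3, N.ar, ...); element = its stem
    ele <- toupper(sub("\\..*$", "", at$elety))
    lid <- if (nzchar(trimws(chunk[2]))) trimws(chunk[2]) else sprintf("mol%d", m)
    n_prev <- get0(lid, envir = counter, ifnotfound = 0L)
    assign(lid, n_prev + 1L, envir = counter)
    list(ligand_id = lid, pose_index = n_prev + 1L,
         xyz = cbind(at$x, at$y, at$z), element = ele, score = NA_real_)
  })
}

read_poses_pdbqt <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L) stopf("empty pose file: %s", path)
  lid <- sub("\\.pdbqt$", "", basename(path))
  models <- grep("^MODEL", txt)
  if (length(models) == 0L) { starts <- 1L; ends <- length(txt) }
  else { starts <- models; ends <- c(models[-1] - 1L, length(txt)) }
  lapply(seq_along(starts), function(m) {
    chunk <- txt[starts[m]:ends[m]]
    sc_line <- grep("^REMARK VINA RESULT:", chunk, value = TRUE)
    score <- if (length(sc_line))
      as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "", sc_line[1])),
                          "\\s+")[[1]][1]) else NA_real_
    at <- grep("^(ATOM|HETATM)", chunk, value = TRUE)
    if (length(at) == 0L) stopf("pose %d in '%s' has no atoms", m, path)
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54)))
    # PDBQT atom type in cols 78-79 (AutoDock type); first letter = element
    type <- toupper(trimws(substr(at, 78, 79)))
    ele <- ifelse(type %in% c("CL", "BR"), type, substr(type, 1, 1))
    list(ligand_id = lid, pose_index = m, xyz = xyz, element = ele,
         score = score)
  })
}

#' Read a reference (co-crystal) ligand
#'
#' @param path File in PDB, mol2 or SDF format (chosen by extension unless
#'   \code{format} is given).
#' @param format Optional explicit format.
#' @return A \code{reference_ligand}: list with \code{xyz} and logical
#'   \code{heavy} flags.
#' @export
read_reference_ligand <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("ligand file not found: %s", path)
  format <- format %||% tolower(sub(".*\\.", "", path))
  out <- switch(format,
    pdb = {
      pdb <- bio3d::read.pdb(path, verbose = FALSE)
      ele <- toupper(pdb$atom$elesy)
      bad <- is.na(ele) | ele == ""
      if (any(bad)) ele[bad] <- toupper(bio3d::atom2ele(pdb$atom$elety[bad]))
      list(xyz = cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z), ele = ele)
    },
    mol2 = {
      mol <- bio3d::read.mol2(path)
      list(xyz = cbind(mol$atom$x, mol$atom$y, mol$atom$z),
           ele = toupper(sub("\\..*$", "", mol$atom$elety)))
    },
    sdf = {
      sdf <- ChemmineR::read.SDFset(path)[[1]]
      ab <- ChemmineR::atomblock(sdf)
      list(xyz = unname(ab[, 1:3, drop = FALSE]),
           ele = sub("_.*$", "", rownames(ab)))
    },
    stopf("unsupported ligand format '%s'", format))
  if (nrow(out$xyz) < 1L) stopf("ligand '%s' has no atoms", path)
  reference_ligand(out$xyz, heavy = toupper(out$ele) != "H")
}

#' Construct a reference ligand from coordinates
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param heavy Logical heavy-atom flags (default: all heavy).
#' @return A \code{reference_ligand}.
#' @export
reference_ligand <- function(xyz, heavy = rep(TRUE, nrow(xyz))) {
  xyz <- as_xyz_matrix(xyz, "ligand coordinates")
  if (nrow(xyz) < 1L) stopf("a ligand needs at least one atom")
  structure(list(xyz = xyz, heavy = as.logical(heavy)),
            class = "reference_ligand")
}

#' Write SOM neurons as PDB pseudo-atoms
#'
#' One HETATM pseudo-atom per neuron, with a per-neuron scalar (U-value,
#' mean docking score, ...) stored in the B-factor column so the map can be
#' colored on the protein structure in any molecular viewer.
#'
#' @param som A trained \code{som_map}.
#' @param values Numeric vector, one value per neuron (flat order).
#' @param path Output PDB path.
#' @export
write_neuron_pdb <- function(som, values, path) {
  if (!inherits(som, "som_map")) stopf("som must be a som_map")
  if (!isTRUE(som$trained)) stopf("som must be trained before writing")
  n <- nrow(som$codes)
  if (length(values) != n)
    stopf("need one value per neuron (%d), got %d", n, length(values))
  bio3d::write.pdb(file = path, xyz = as.vector(t(som$codes)),
                   type = rep("HETATM", n), resno = seq_len(n),
                   resid = rep("NEU", n), eleno = seq_len(n),
                   elety = rep("C", n), chain = rep(" ", n),
                   o = rep(1, n), b = as.numeric(values))
  invisible(path)
}

#' Write pose sets to an SDF file
#'
#' Emits one V2000 record per pose (zero bond block; poses carry
#' coordinates only) with the docking score in a \code{score} data field
#' and the pose index in a \code{pose_index} field, so
#' \code{\link{read_poses}} round-trips.
#'
#' @param pose_sets A \code{pose_set} or list of them.
#' @param path Output file.
#' @export
write_pose_sdf <- function(pose_sets, path) {
  if (inherits(pose_sets, "pose_set")) pose_sets <- list(pose_sets)
  con <- file(path, "w")
  on.exit(close(con))
  for (ps in pose_sets) {
    for (p in ps$poses) {
      n <- nrow(p$xyz)
      ele <- if (!is.null(p$element)) p$element else rep("C", n)
      lines <- c(ps$ligand_id, "  somsite", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
                 sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         p$xyz[, 1], p$xyz[, 2], p$xyz[, 3], ele),
                 "M  END",
                 ">  <score>", format(p$score), "",
                 ">  <pose_index>", format(p$pose_index), "",
                 "$$$$")
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Write a sidecar score table for pose sets
#' @param pose_sets List of \code{pose_set}.
#' @param path Output tab-separated file with columns ligand_id,
#'   pose_index, score.
#' @export
write_score_table <- function(pose_sets, path) {
  if (inherits(pose_sets, "pose_set")) pose_sets <- list(pose_sets)
  rows <- do.call(rbind, lapply(pose_sets, function(ps)
    data.frame(ligand_id = ps$ligand_id,
               pose_index = vapply(ps$poses, `[[`, numeric(1), "pose_index"),
               score = pose_scores(ps))))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stack all pose atom coordinates of a set of ligands
#'
#' The coordinate cloud that feeds SOM training: every atom of every
#' retained pose of every ligand.
#'
#' @param pose_sets List of \code{pose_set}.
#' @return n x 3 matrix of coordinates (Angstrom) with attributes
#'   \code{ligand_id}, \code{pose_index} and \code{score} mapping each row
#'   to its pose.
#' @export
pose_coordinates <- function(pose_sets) {
  if (inherits(pose_sets, "pose_set")) pose_sets <- list(pose_sets)
  mats <- list(); lid <- list(); pid <- list(); sc <- list()
  for (ps in pose_sets) for (p in ps$poses) {
    mats[[length(mats) + 1L]] <- p$xyz
    n <- nrow(p$xyz)
    lid[[length(lid) + 1L]] <- rep(ps$ligand_id, n)
    pid[[length(pid) + 1L]] <- rep(p$pose_index, n)
    sc[[length(sc) + 1L]] <- rep(p$score, n)
  }
  out <- do.call(rbind, mats)
  attr(out, "ligand_id") <- unlist(lid)
  attr(out, "pose_index") <- unlist(pid)
  attr(out, "score") <- unlist(sc)
  out
}
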