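# Dual-probe cavity detection on a regular voxel grid.
#
# A cavity is the space a small solvent probe (1.4 A) can occupy but the
# bulk-solvent probe (10 A) cannot reach from outside: the accessible
# volume minus the boundary-connected component of the bulk-probe
# accessible volume. Voxels are clustered by 26-connectivity and clusters
# smaller than a water molecule (96 voxels at 0.5 A = 12 A^3) discarded.

grid_geometry <- function(structure, spacing, margin) {
  lo <- apply(structure$xyz, 2, min) - margin
  hi <- apply(structure$xyz, 2, max) + margin
  # snap the origin to multiples of the spacing for reproducibility
  origin <- floor(lo / spacing) * spacing
  dims <- as.integer(ceiling((hi - origin) / spacing)) + 1L
  list(origin = origin, dims = dims)
}

#' Solvent accessibility mask of a structure
#'
#' A voxel center is (geometrically) accessible iff a probe sphere
#' centered there overlaps no atom: distance(center, atom) >= vdW(atom) +
#' probe for every atom. The boundary-connected ("bulk") variant restricts
#' to voxels 26-connected to the grid boundary through accessible voxels,
#' i.e. reachable by solvent coming from outside.
#'
#' @param structure A \code{protein_structure}.
#' @param probe_radius Probe radius in Angstrom (>= 0).
#' @param spacing Grid spacing in Angstrom (default 0.5).
#' @param margin Padding of the structure bounding box, Angstrom (default:
#'   probe radius + largest vdW radius).
#' @return List with \code{origin}, \code{spacing}, \code{dims},
#'   \code{accessible} (logical 3D array) and \code{bulk} (logical 3D
#'   array, boundary-connected subset).
#' @export
accessibility_mask <- function(structure, probe_radius, spacing = 0.5,
                               margin = NULL) {
  if (!inherits(structure, "protein_structure"))
    stopf("structure must be a protein_structure")
  if (probe_radius < 0) stopf("probe_radius must be >= 0")
  margin <- margin %||% (probe_radius + max(structure$radius))
  g <- grid_geometry(structure, spacing, margin)
  acc <- cpp_access_mask(g$dims, g$origin, spacing, structure$xyz,
                         structure$radius, probe_radius)
  bulk <- cpp_boundary_reach26(acc, g$dims)
  list(origin = g$origin, spacing = spacing, dims = g$dims,
       accessible = array(acc, dim = g$dims),
       bulk = array(bulk, dim = g$dims))
}

#' Detect cavities with a dual-probe grid
#'
#' The solvent-accessible volume is the union of solvent-probe spheres
#' placed at every allowed probe center (a center is allowed when the
#' probe overlaps no atom; interior centers with no path to the outside
#' count too). The bulk volume is the union of bulk-probe spheres at
#' allowed bulk centers that are 26-connected to the grid boundary, i.e.
#' what a 10 A sphere rolling in from outside can sweep. Cavity voxels
#' are in the first volume but not the second. Probe-sphere coverage is
#' computed with an exact Euclidean distance transform of the
#' allowed-center masks. Cavity voxels are clustered by 26-connectivity;
#' clusters below \code{min_voxels} are discarded and survivors labeled
#' 1..n in decreasing volume order.
#'
#' @param structure A \code{protein_structure}.
#' @param probe Solvent probe radius, Angstrom (default 1.4).
#' @param bulk_probe Bulk solvent probe radius, Angstrom (default 10).
#' @param spacing Grid spacing, Angstrom (default 0.5).
#' @param min_voxels Minimum cluster size in voxels (default 96, i.e.
#'   12 A^3 at 0.5 A spacing, about one water molecule).
#' @param max_grid_voxels Memory guard: error if the padded grid would
#'   exceed this many voxels (default 2e8).
#' @return A \code{cavity_grid}: list with \code{origin}, \code{spacing},
#'   \code{dims}, integer \code{label} array (0 = non-cavity) and
#'   \code{cavities}, a list of cavities each holding \code{id},
#'   \code{voxel_count}, \code{volume} (A^3) and \code{voxels} (flat
#'   indices).
#' @export
detect_cavities <- function(structure, probe = 1.4, bulk_probe = 10.0,
                            spacing = 0.5, min_voxels = 96L,
                            max_grid_voxels = 2e8) {
  if (bulk_probe <= probe) stopf("bulk_probe must exceed probe")
  margin <- bulk_probe + max(structure$radius)
  g <- grid_geometry(structure, spacing, margin)
  if (prod(as.numeric(g$dims)) > max_grid_voxels)
    stopf("grid of %d x %d x %d voxels exceeds the memory cap; use a larger spacing",
          g$dims[1], g$dims[2], g$dims[3])
  acc_centers <- cpp_access_mask(g$dims, g$origin, spacing, structure$xyz,
                                 structure$radius, probe)
  bulk_centers <- cpp_access_mask(g$dims, g$origin, spacing, structure$xyz,
                                  structure$radius, bulk_probe)
  bulk_centers <- bulk_centers & cpp_boundary_reach26(bulk_centers, g$dims)
  covered <- cpp_sq_edt(acc_centers, g$dims) <= (probe / spacing)^2 + 1e-9
  bulk_covered <- cpp_sq_edt(bulk_centers, g$dims) <=
    (bulk_probe / spacing)^2 + 1e-9
  cavity_mask <- covered & !bulk_covered
  lab0 <- cpp_label26(cavity_mask, g$dims)
  counts <- tabulate(lab0)
  keep <- which(counts >= min_voxels)
  label <- integer(length(lab0))
  cavities <- list()
  if (length(keep)) {
    # relabel 1..n in decreasing volume; ties by first-encountered label
    keep <- keep[order(-counts[keep], keep)]
    for (new_id in seq_along(keep)) {
      vox <- which(lab0 == keep[new_id])
      label[vox] <- new_id
      cavities[[new_id]] <- list(id = new_id, voxel_count = length(vox),
                                 volume = length(vox) * spacing^3,
                                 voxels = vox)
    }
  }
  structure(list(origin = g$origin, spacing = spacing, dims = g$dims,
                 label = array(label, dim = g$dims), cavities = cavities),
            class = "cavity_grid")
}

#' @export
print.cavity_grid <- function(x, ...) {
  cat(sprintf("cavity_grid: %d x %d x %d voxels at %.2f A, %d cavities\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              length(x$cavities)))
  for (cv in x$cavities)
    cat(sprintf("  cavity %d: %d voxels, %.1f A^3\n", cv$id,
                cv$voxel_count, cv$volume))
  invisible(x)
}

#' Cavity membership of a point
#'
#' A position belongs to a cavity if at least one of the 8 corners of the
#' grid cell enclosing it carries that cavity's label. If corners carry
#' different labels, the smallest id wins.
#'
#' @param position Length-3 coordinate (Angstrom), or an n x 3 matrix.
#' @param grid A \code{cavity_grid}.
#' @return Integer cavity id(s); \code{NA} outside the grid or when no
#'   corner is labeled.
#' @export
neuron_in_cavity <- function(position, grid) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  n <- nrow(position)
  out <- rep(NA_integer_, n)
  rel <- sweep(position, 2, grid$origin) / grid$spacing
  i0 <- floor(rel)
  inside <- rel[, 1] >= 0 & rel[, 2] >= 0 & rel[, 3] >= 0 &
    i0[, 1] <= grid$dims[1] - 2 & i0[, 2] <= grid$dims[2] - 2 &
    i0[, 3] <= grid$dims[3] - 2
  corners <- expand.grid(0:1, 0:1, 0:1)
  for (p in which(inside)) {
    labs <- vapply(seq_len(8), function(cn)
      grid$label[i0[p, 1] + corners[cn, 1] + 1L,
                 i0[p, 2] + corners[cn, 2] + 1L,
                 i0[p, 3] + corners[cn, 3] + 1L], integer(1))
    labs <- labs[labs > 0L]
    if (length(labs)) out[p] <- min(labs)
  }
  out
}

#' Neuron density of a cavity
#'
#' Number of SOM neurons lying inside the cavity divided by the cavity
#' volume; a high density marks a preferentially mapped cavity.
#'
#' @param som A trained \code{som_map}.
#' @param cavity A cavity entry from a \code{cavity_grid}, or a cavity id.
#' @param grid The \code{cavity_grid}.
#' @return Density in neurons per A^3.
#' @export
neuron_density <- function(som, cavity, grid) {
  if (!isTRUE(som$trained)) stopf("som must be trained")
  if (is.numeric(cavity)) cavity <- grid$cavities[[cavity]]
  ids <- neuron_in_cavity(som$codes, grid)
  sum(ids == cavity$id, na.rm = TRUE) / cavity$volume
}

#' Export cavity voxels as PDB pseudo-atoms
#' @param grid A \code{cavity_grid}.
#' @param path Output PDB path; cavity id goes to the residue number and
#'   B-factor columns.
#' @export
write_cavity_pdb <- function(grid, path) {
  vox <- which(grid$label > 0)
  if (length(vox) == 0L) stopf("no cavities to write")
  idx <- arrayInd(vox, grid$dims)
  xyz <- sweep((idx - 1) * grid$spacing, 2, grid$origin, `+`)
  ids <- grid$label[vox]
  n <- length(vox)
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   type = rep("HETATM", n), resno = ids,
                   resid = rep("CAV", n), eleno = seq_len(n),
                   elety = rep("C", n), chain = rep(" ", n),
                   o = rep(1, n), b = as.numeric(ids))
  invisible(path)
}

#' Export the cavity label field as an OpenDX scalar grid
#' @param grid A \code{cavity_grid}.
#' @param path Output .dx path.
#' @export
write_cavity_dx <- function(grid, path) {
  d <- grid$dims
  vals <- as.numeric(aperm(grid$label, c(3, 2, 1))) # DX wants z fastest
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  chunks <- split(vals, (seq_along(vals) - 1L) %/% 3L)
  writeLines(vapply(chunks, function(v)
    paste(format(v, trim = TRUE), collapse = " "), character(1)), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Cavity summary table
#' @param grid A \code{cavity_grid}.
#' @return data.frame with id, voxel_count, volume (A^3).
#' @export
cavity_table <- function(grid) {
  if (length(grid$cavities) == 0L)
    return(data.frame(id = integer(), voxel_count = integer(),
                      volume = numeric()))
  data.frame(id = vapply(grid$cavities, `[[`, integer(1), "id"),
             voxel_count = vapply(grid$cavities, `[[`, integer(1), "voxel_count"),
             volume = vapply(grid$cavities, `[[`, numeric(1), "volume"))
}
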