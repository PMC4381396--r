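# End-to-end orchestration: cavities -> poses -> SOM -> U-matrix ->
# consensual clusters -> optional evaluation / feature enrichment, with a
# machine-readable JSON report embedding the resolved configuration.

#' Build a pipeline configuration
#'
#' All defaults are the protocol's standard settings: 0.5 A grid, 1.4 A
#' solvent and 10 A bulk probes, 96-voxel minimum cavity, 15^3-neuron
#' map target, the two-phase training schedule, a 10-component GMM cap,
#' precision threshold 0.25 with the per-cluster r_CC radius, all pose
#' atoms.
#'
#' @param receptor Path to a receptor PDB (optional; skips the cavity
#'   stage when NULL).
#' @param poses Pose file path(s), or a list of \code{pose_set} objects.
#' @param pose_format One of "sdf", "mol2", "pdbqt".
#' @param scores Optional sidecar score table path.
#' @param reference_ligand Path to a reference ligand file, or a
#'   \code{reference_ligand} (optional; enables the evaluation block).
#' @param spacing,probe,bulk_probe,min_voxels Cavity-grid settings.
#' @param max_poses Lowest-energy poses kept per ligand (default 20).
#' @param som_size Target neuron count (default 3375).
#' @param schedule Training schedule (default \code{default_schedule()}).
#' @param kernel SOM neighborhood kernel ("gaussian" or "cutoff").
#' @param gmm_max_components Cap for the U-value mixture (default 10).
#' @param precision_threshold Success threshold (default 0.25).
#' @param radius_mode "rcc" or a fixed radius in Angstrom (1.6 / 2.0).
#' @param atom_mode "all" or "heavy".
#' @param n_randomizations Z-score resamples (default 1e5).
#' @param seed Integer master seed.
#' @param out_dir Optional output directory for the report files.
#' @return A \code{run_config} list.
#' @export
run_config <- function(receptor = NULL, poses = NULL, pose_format = "sdf",
                       scores = NULL, reference_ligand = NULL,
                       spacing = 0.5, probe = 1.4, bulk_probe = 10.0,
                       min_voxels = 96L, max_poses = 20L,
                       som_size = 3375L, schedule = default_schedule(),
                       kernel = "gaussian", gmm_max_components = 10L,
                       precision_threshold = 0.25, radius_mode = "rcc",
                       atom_mode = "all", n_randomizations = 1e5,
                       seed = 1L, out_dir = NULL) {
  cfg <- list(receptor = receptor, poses = poses,
              pose_format = pose_format, scores = scores,
              reference_ligand = reference_ligand, spacing = spacing,
              probe = probe, bulk_probe = bulk_probe,
              min_voxels = min_voxels, max_poses = max_poses,
              som_size = som_size, schedule = schedule, kernel = kernel,
              gmm_max_components = gmm_max_components,
              precision_threshold = precision_threshold,
              radius_mode = radius_mode, atom_mode = atom_mode,
              n_randomizations = n_randomizations, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match \code{\link{run_config}}
#'   arguments.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full binding-site identification pipeline
#'
#' Stages: cavity detection on the receptor (if given) -> pose ingestion
#' -> SOM training on all pose atom coordinates -> U-matrix + GMM
#' threshold -> consensual cluster extraction and ranking (with r_CC,
#' cavity membership and mean docking score per cluster) -> optional
#' evaluation against the reference ligand. Identical configuration and
#' seed give identical reports.
#'
#' @param config A \code{run_config}.
#' @return A report list (also written as JSON, with neuron PDB and
#'   cavity DX files, when \code{out_dir} is set).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  report <- list(config = config[setdiff(names(config), "out_dir")],
                 package_version = as.character(utils::packageVersion("somsite")))

  grid <- NULL
  if (!is.null(config$receptor)) {
    receptor <- stage("receptor", read_receptor(config$receptor))
    grid <- stage("cavities", detect_cavities(
      receptor, probe = config$probe, bulk_probe = config$bulk_probe,
      spacing = config$spacing, min_voxels = config$min_voxels))
    report$cavities <- cavity_table(grid)
  }

  pose_sets <- stage("poses", {
    if (is.null(config$poses)) stopf("no pose input configured")
    if (is.character(config$poses))
      read_poses(config$poses, format = config$pose_format,
                 max_poses = config$max_poses, scores = config$scores)
    else config$poses
  })
  pts <- stage("poses", pose_coordinates(pose_sets))
  report$n_ligands <- length(pose_sets)
  report$n_points <- nrow(pts)

  som <- stage("som", som_fit(pts, target_size = config$som_size,
                              schedule = config$schedule,
                              seed = config$seed, kernel = config$kernel))
  report$som <- list(dims = som$dims, seed = som$seed)
  qe <- quantization_errors(som, pts)
  report$quantization_error <- as.list(attr(qe, "summary"))

  um <- stage("umatrix", umatrix_threshold(
    compute_umatrix(som), max_components = config$gmm_max_components,
    seed = config$seed))
  report$t_u <- um$t_u
  report$gmm <- um$gmm

  ccs <- stage("clusters", extract_ccs(um, som))
  mean_scores <- neuron_mean_score(som, pts)
  report$ccs <- lapply(ccs, function(cc) {
    cav <- if (!is.null(grid)) {
      ids <- neuron_in_cavity(som$codes[cc$members, , drop = FALSE], grid)
      ids <- ids[!is.na(ids)]
      if (length(ids)) as.integer(names(which.max(table(ids)))) else NA_integer_
    } else NA_integer_
    list(rank = cc$rank, n_neurons = cc$n_neurons, r_cc = cc$r_cc,
         centroid = as.numeric(cc$centroid), mean_u = cc$mean_u,
         cavity_id = cav,
         mean_score = mean(mean_scores[cc$members], na.rm = TRUE))
  })

  if (!is.null(config$reference_ligand)) {
    lig <- stage("evaluation", {
      if (is.character(config$reference_ligand))
        read_reference_ligand(config$reference_ligand)
      else config$reference_ligand
    })
    ev <- stage("evaluation", evaluate_target(
      ccs, som, lig, precision_threshold = config$precision_threshold,
      radius_mode = config$radius_mode, atom_mode = config$atom_mode))
    report$evaluation <- unclass(ev)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    write_neuron_pdb(som, um$values,
                     file.path(config$out_dir, "neurons_umatrix.pdb"))
    if (!is.null(grid) && length(grid$cavities))
      write_cavity_dx(grid, file.path(config$out_dir, "cavities.dx"))
  }
  report$som_object <- som
  report$umatrix_object <- um
  report$ccs_objects <- ccs
  invisible(report)
}
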