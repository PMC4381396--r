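# U-matrix computation, GMM-based thresholds, consensual-cluster
# extraction and evaluation against a reference ligand.
#
# Low U-values mark dense, homogeneous ("high neuron consensus") regions
# of the map; connected sets of low-U neurons are the candidate binding
# sites (consensual clusters, CCs).

#' U-matrix of a trained SOM
#'
#' Per neuron, the mean Euclidean distance (in Angstrom, between neuron
#' coordinates) to its direct lattice neighbors: up to 26, fewer at faces,
#' edges and corners of the non-periodic map.
#'
#' @param som A trained \code{som_map} with every dimension >= 2.
#' @return A \code{som_umatrix}: list with \code{values} (one per neuron,
#'   flat order), and slots \code{t_u} / \code{gmm} filled by
#'   \code{\link{umatrix_threshold}}.
#' @export
compute_umatrix <- function(som) {
  if (!isTRUE(som$trained)) stopf("som must be trained")
  if (any(som$dims < 2L)) stopf("every map dimension must be >= 2")
  dims <- som$dims
  X <- som_array(som$codes[, 1], dims)
  Y <- som_array(som$codes[, 2], dims)
  Z <- som_array(som$codes[, 3], dims)
  K <- dims[3]; J <- dims[2]; I <- dims[1]
  sum_d <- array(0, dim = c(K, J, I))
  n_d <- array(0L, dim = c(K, J, I))
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    # target cells [k,j,i] with neighbor [k+dk, j+dj, i+di] in range
    ks <- max(1, 1 - dk):min(K, K - dk)
    js <- max(1, 1 - dj):min(J, J - dj)
    is <- max(1, 1 - di):min(I, I - di)
    dd <- sqrt((X[ks, js, is, drop = FALSE] - X[ks + dk, js + dj, is + di, drop = FALSE])^2 +
               (Y[ks, js, is, drop = FALSE] - Y[ks + dk, js + dj, is + di, drop = FALSE])^2 +
               (Z[ks, js, is, drop = FALSE] - Z[ks + dk, js + dj, is + di, drop = FALSE])^2)
    sum_d[ks, js, is] <- sum_d[ks, js, is, drop = FALSE] + dd
    n_d[ks, js, is] <- n_d[ks, js, is, drop = FALSE] + 1L
  }
  structure(list(values = as.vector(sum_d / n_d), t_u = NULL, gmm = NULL),
            class = "som_umatrix")
}

#' GMM-based threshold of a value distribution
#'
#' Fits Gaussian mixtures with 1..\code{max_components} components
#' (unequal variances), selects the component count by BIC, takes the
#' component with the largest weight and returns its mean + standard
#' deviation. Used for both the U-value cutoff t_U and the cluster radius
#' r_CC.
#'
#' @param values Numeric vector (>= 10 values unless degenerate).
#' @param max_components Maximum number of mixture components (default 10).
#' @param seed Integer seed (the EM initialization subsamples large
#'   inputs randomly; fixing the seed makes the fit reproducible).
#' @return List with \code{threshold} and \code{gmm} (n_components,
#'   weights, means, variances).
#' @export
fit_gmm_threshold <- function(values, max_components = 10L, seed = 1L) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stopf("values must be finite")
  if (stats::var(values) < 1e-12) {
    # degenerate: effectively a single repeated value
    return(list(threshold = values[1],
                gmm = list(n_components = 1L, weights = 1,
                           means = values[1], variances = 0)))
  }
  if (length(values) < 10L) stopf("need >= 10 values to fit a mixture")
  fit <- fit_mclust(values, seq_len(max_components), seed)
  if (is.null(fit)) fit <- fit_mclust(values, 1L, seed)
  w <- fit$parameters$pro
  mu <- as.numeric(fit$parameters$mean)
  v <- fit$parameters$variance$sigmasq
  if (length(v) == 1L) v <- rep(v, fit$G)
  dom <- which.max(w)
  list(threshold = mu[dom] + sqrt(v[dom]),
       gmm = list(n_components = fit$G, weights = as.numeric(w),
                  means = mu, variances = as.numeric(v)))
}

# Mclust re-evaluates helper calls in the caller's frame, so it must be
# invoked from an environment that can see the mclust namespace. The EM
# initialization subsamples through the RNG for n > 2000, hence the seed.
fit_mclust <- function(values, G, seed = 1L) {
  e <- new.env(parent = asNamespace("mclust"))
  e$.values <- values
  e$.G <- G
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  tryCatch(eval(quote(Mclust(.values, G = .G, modelNames = "V",
                             verbose = FALSE)), e),
           error = function(err) NULL)
}

#' Set the U-value cutoff t_U on a U-matrix
#'
#' Applies \code{\link{fit_gmm_threshold}} to the U-value distribution:
#' t_U = mu + sigma of the BIC-dominant Gaussian component. Neurons with
#' U <= t_U are consensual; higher U-values are barriers between sites.
#'
#' @param umatrix A \code{som_umatrix}.
#' @param max_components Maximum GMM components (default 10).
#' @param seed Seed (see \code{\link{fit_gmm_threshold}}).
#' @return The U-matrix with \code{t_u} and \code{gmm} filled.
#' @export
umatrix_threshold <- function(umatrix, max_components = 10L, seed = 1L) {
  fit <- fit_gmm_threshold(umatrix$values, max_components, seed)
  umatrix$t_u <- fit$threshold
  umatrix$gmm <- fit$gmm
  umatrix
}

#' Extract consensual clusters from a thresholded U-matrix
#'
#' Connected components (26-connectivity in lattice-index space) of the
#' neurons with U <= t_U, sorted by decreasing neuron count (rank 1 =
#' largest); count ties broken by lower mean U-value, then by smallest
#' member flat index.
#'
#' @param umatrix A \code{som_umatrix} with \code{t_u} set.
#' @param som The \code{som_map} the U-matrix came from.
#' @param compute_radius Also compute each cluster's r_CC (default
#'   \code{TRUE}; clusters where no intra-cluster neighbor pair exists get
#'   \code{NA}).
#' @return List of \code{consensual_cluster}: rank, members (flat neuron
#'   indices), n_neurons, centroid, mean_u, r_cc.
#' @export
extract_ccs <- function(umatrix, som, compute_radius = TRUE) {
  if (is.null(umatrix$t_u)) stopf("set t_u first (umatrix_threshold)")
  mask <- umatrix$values <= umatrix$t_u
  if (!any(mask)) return(list())
  dims_arr <- c(som$dims[3], som$dims[2], som$dims[1]) # array order (K,J,I)
  lab <- cpp_label26(mask, dims_arr)
  comp_ids <- setdiff(unique(lab), 0L)
  ccs <- lapply(comp_ids, function(id) {
    members <- which(lab == id)
    list(members = members, n_neurons = length(members),
         mean_u = mean(umatrix$values[members]),
         centroid = colMeans(som$codes[members, , drop = FALSE]))
  })
  ord <- order(-vapply(ccs, `[[`, integer(1), "n_neurons"),
               vapply(ccs, `[[`, numeric(1), "mean_u"),
               vapply(ccs, function(cc) min(cc$members), integer(1)))
  ccs <- ccs[ord]
  for (r in seq_along(ccs)) {
    ccs[[r]]$rank <- r
    ccs[[r]]$r_cc <- if (compute_radius)
      tryCatch(compute_rcc(ccs[[r]], som), error = function(e) NA_real_)
    else NA_real_
    class(ccs[[r]]) <- "consensual_cluster"
  }
  ccs
}

#' @export
print.consensual_cluster <- function(x, ...) {
  cat(sprintf("CC rank %d: %d neurons, r_CC %.3f A, centroid (%.2f, %.2f, %.2f)\n",
              x$rank, x$n_neurons, x$r_cc, x$centroid[1], x$centroid[2],
              x$centroid[3]))
  invisible(x)
}

#' Overlap radius r_CC of a consensual cluster
#'
#' Collects the Euclidean distances between each cluster neuron and its
#' direct axis neighbors (+/-1 along one lattice index) that also belong
#' to the cluster, fits a 2-component Gaussian mixture, and returns
#' mean + sd of the dominant component. On a perfectly regular lattice all
#' distances are equal and that value is returned directly.
#'
#' @param cc A \code{consensual_cluster} with >= 2 neurons.
#' @param som The \code{som_map}.
#' @param seed Seed (see \code{\link{fit_gmm_threshold}}).
#' @return Radius in Angstrom.
#' @export
compute_rcc <- function(cc, som, seed = 1L) {
  if (cc$n_neurons < 2L) stopf("cluster needs >= 2 neurons for a radius")
  d <- intra_cc_neighbor_distances(cc, som)
  if (length(d) == 0L)
    stopf("cluster rank %s has no intra-cluster neighbor pair", cc$rank %||% "?")
  if (stats::var(d) < 1e-12) return(d[1])
  fit <- fit_mclust(d, 2L, seed)
  if (is.null(fit)) return(mean(d) + sd(d))
  w <- fit$parameters$pro
  mu <- as.numeric(fit$parameters$mean)
  v <- fit$parameters$variance$sigmasq
  if (length(v) == 1L) v <- rep(v, fit$G)
  dom <- which.max(w)
  mu[dom] + sqrt(v[dom])
}

intra_cc_neighbor_distances <- function(cc, som) {
  dims <- som$dims
  in_cc <- logical(prod(dims))
  in_cc[cc$members] <- TRUE
  ijk <- som_unflat(cc$members, dims)
  out <- numeric(0)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (o in seq_len(6)) {
    ni <- ijk[, 1] + offsets[o, 1]
    nj <- ijk[, 2] + offsets[o, 2]
    nk <- ijk[, 3] + offsets[o, 3]
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
      nk >= 1 & nk <= dims[3]
    if (!any(ok)) next
    nb <- som_flat(ni[ok], nj[ok], nk[ok], dims)
    sel <- in_cc[nb]
    if (!any(sel)) next
    a <- som$codes[cc$members[ok][sel], , drop = FALSE]
    b <- som$codes[nb[sel], , drop = FALSE]
    out <- c(out, sqrt(rowSums((a - b)^2)))
  }
  out
}

#' Precision of a consensual cluster against a reference ligand
#'
#' Fraction of ligand atoms within \code{radius} of any cluster neuron.
#'
#' @param cc A \code{consensual_cluster}.
#' @param som The \code{som_map}.
#' @param ligand A \code{reference_ligand}.
#' @param radius Overlap radius in Angstrom (default: the cluster's r_CC).
#' @param atom_mode \code{"all"} (default) or \code{"heavy"}.
#' @return Fraction in [0, 1].
#' @export
cc_precision <- function(cc, som, ligand, radius = cc$r_cc,
                         atom_mode = c("all", "heavy")) {
  atom_mode <- match.arg(atom_mode)
  if (!inherits(ligand, "reference_ligand")) stopf("ligand must be a reference_ligand")
  xyz <- ligand$xyz
  if (atom_mode == "heavy") xyz <- xyz[ligand$heavy, , drop = FALSE]
  if (nrow(xyz) == 0L) stopf("ligand has no atoms under atom_mode '%s'", atom_mode)
  if (!is.finite(radius)) stopf("radius is not available for this cluster")
  dmin <- cpp_min_dist(xyz, som$codes[cc$members, , drop = FALSE])
  mean(dmin <= radius)
}

#' Evaluate predicted clusters against a reference ligand
#'
#' Computes per-cluster precision under the chosen radius/atom
#' convention. The hit is the lowest-rank cluster with precision above
#' \code{precision_threshold}; Top1/Top3 success flags record whether the
#' hit is at rank 1 / within ranks 1-3. The stringent occurrence
#' accounting additionally marks the target failed when the ligand
#' overlaps (precision > 0) zero or two-or-more clusters.
#'
#' @param ccs List of \code{consensual_cluster}.
#' @param som The \code{som_map}.
#' @param ligand A \code{reference_ligand}.
#' @param precision_threshold Success threshold on precision (default
#'   0.25; 0.15 is the convention paired with the 2.0 A radius).
#' @param radius_mode \code{"rcc"} (per-cluster r_CC, default) or a fixed
#'   numeric radius in Angstrom (1.6 and 2.0 are the standard
#'   literature settings).
#' @param atom_mode \code{"all"} or \code{"heavy"}.
#' @return A \code{target_evaluation}: precisions by rank, hit rank (or
#'   NA), top1/top3 logical flags, occurrence diagnostics.
#' @export
evaluate_target <- function(ccs, som, ligand, precision_threshold = 0.25,
                            radius_mode = "rcc",
                            atom_mode = c("all", "heavy")) {
  atom_mode <- match.arg(atom_mode)
  prec <- vapply(ccs, function(cc) {
    r <- if (identical(radius_mode, "rcc")) cc$r_cc else as.numeric(radius_mode)
    if (!is.finite(r)) return(NA_real_)
    cc_precision(cc, som, ligand, radius = r, atom_mode = atom_mode)
  }, numeric(1))
  above <- which(!is.na(prec) & prec > precision_threshold)
  hit <- if (length(above)) min(above) else NA_integer_
  n_overlap <- sum(!is.na(prec) & prec > 0)
  structure(list(precisions = prec, hit_cc = hit,
                 top1 = isTRUE(hit == 1L), top3 = isTRUE(hit <= 3L),
                 n_overlapping = n_overlap,
                 occurrence_failed = n_overlap == 0L || n_overlap >= 2L,
                 precision_threshold = precision_threshold,
                 radius_mode = radius_mode, atom_mode = atom_mode),
            class = "target_evaluation")
}

#' Success rates over a set of target evaluations
#'
#' @param evaluations List of \code{target_evaluation}.
#' @return List with \code{top1_sr} and \code{top3_sr} (fractions),
#'   \code{mean_hit_precision} (mean precision of the hit clusters) and
#'   \code{n}.
#' @export
success_rates <- function(evaluations) {
  if (length(evaluations) < 1L) stopf("need at least one evaluation")
  top1 <- vapply(evaluations, `[[`, logical(1), "top1")
  top3 <- vapply(evaluations, `[[`, logical(1), "top3")
  hitp <- vapply(evaluations, function(ev)
    if (is.na(ev$hit_cc)) NA_real_ else ev$precisions[ev$hit_cc], numeric(1))
  list(top1_sr = mean(top1), top3_sr = mean(top3),
       mean_hit_precision = mean(hitp, na.rm = TRUE),
       n = length(evaluations))
}

#' Mean docking score projected on the neurons
#'
#' Per neuron, the mean score of all pose atoms whose BMU is that neuron;
#' the score counterpart of the U-matrix for visual inspection.
#'
#' @param som A trained \code{som_map}.
#' @param points Pose atom coordinates as returned by
#'   \code{\link{pose_coordinates}} (with a \code{score} attribute), or an
#'   n x 3 matrix plus \code{scores}.
#' @param scores Optional per-row scores when \code{points} lacks the
#'   attribute.
#' @return Numeric vector, one mean score per neuron (NA where no atom
#'   maps).
#' @export
neuron_mean_score <- function(som, points, scores = attr(points, "score")) {
  if (is.null(scores)) stopf("no scores supplied")
  b <- som_bmu(som, points)
  out <- rep(NA_real_, nrow(som$codes))
  agg <- tapply(scores, b, mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
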