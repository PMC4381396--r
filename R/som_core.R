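# 3D non-periodic Kohonen map on pose-atom (or feature-center)
# coordinates: PCA-based initialization, two-phase exponential-decay
# training, BMU queries and quantization errors.
#
# Neurons live in the same Cartesian space as the input points (Angstrom);
# the neighborhood kernel acts in map-index space. Flat neuron order: k
# fastest (see utils.R).

#' Principal-component frame of a point cloud
#'
#' PCA of the centered coordinates: orthonormal components V1..V3 with
#' lengths S1 >= S2 >= S3 (square roots of the covariance eigenvalues) and
#' the min/max projections of the points on each component. The frame
#' orients and sizes the initial SOM lattice.
#'
#' @param points n x 3 coordinate matrix (Angstrom).
#' @return A \code{pca_frame}: list with \code{mean}, \code{components}
#'   (3 x 3, columns V1..V3), \code{lengths} (S1..S3, Angstrom),
#'   \code{lo}/\code{hi} projection extrema per component.
#' @export
pca_frame <- function(points) {
  points <- as_xyz_matrix(points, "points")
  if (nrow(unique(points)) < 2L)
    stopf("need at least 2 distinct points to define an orientation")
  pc <- prcomp(points, center = TRUE, scale. = FALSE)
  proj <- pc$x
  structure(list(mean = as.numeric(pc$center),
                 components = unname(pc$rotation),
                 lengths = unname(pc$sdev),
                 lo = apply(proj, 2, min), hi = apply(proj, 2, max)),
            class = "pca_frame")
}

#' Map dimensions proportional to the data extents
#'
#' Chooses integer lattice dimensions (I,J,K) approximately proportional
#' to the PCA lengths S1..S3 with product close to \code{target_size}
#' (default 15^3 = 3375): I = round(c S1) etc. with
#' c = (target_size/(S1 S2 S3))^(1/3). Each dimension is floored at 2;
#' degenerate lengths are floored at S1/100 first.
#'
#' @param S Numeric length-3 vector of PCA lengths (Angstrom).
#' @param target_size Target number of neurons (default 3375).
#' @return Integer vector (I, J, K).
#' @export
map_dims <- function(S, target_size = 3375L) {
  if (length(S) != 3L || any(!is.finite(S)) || any(S < 0))
    stopf("S must be three finite non-negative lengths")
  if (max(S) <= 0) stopf("all PCA lengths are zero")
  S <- pmax(S, max(S) / 100)
  cc <- (target_size / prod(S))^(1 / 3)
  pmax(2L, as.integer(round(cc * S)))
}

#' Initialize a SOM lattice from a PCA frame
#'
#' Neurons form a regular lattice spanning the projection range of the
#' data: neuron (i,j,k) sits at mean + sum_d V_d (lo_d + idx_d (hi_d -
#' lo_d) / N_d) with idx_d in 0..N_d-1.
#'
#' @param frame A \code{pca_frame}.
#' @param dims Integer (I, J, K) lattice dimensions.
#' @return An untrained \code{som_map}: list with \code{dims},
#'   \code{codes} (n x 3 neuron coordinates, flat order k fastest),
#'   \code{trained}, \code{seed}, \code{schedule}.
#' @export
init_som <- function(frame, dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stopf("dims must be 3 positive integers")
  dims <- pmax(dims, 2L)
  idx <- som_unflat(seq_len(prod(dims)), dims)
  step <- (frame$hi - frame$lo) / dims
  loc <- cbind(frame$lo[1] + (idx[, 1] - 1) * step[1],
               frame$lo[2] + (idx[, 2] - 1) * step[2],
               frame$lo[3] + (idx[, 3] - 1) * step[3])
  codes <- sweep(loc %*% t(frame$components), 2, frame$mean, `+`)
  structure(list(dims = dims, codes = codes, trained = FALSE,
                 seed = NA_integer_, schedule = NULL),
            class = "som_map")
}

#' Default two-phase training schedule
#'
#' Phase 1: one cycle with radius decaying 7.5 -> 3.75 and learning rate
#' 1 -> 0.5. Phase 2: ten cycles with radius 3.75 -> 1 and learning rate
#' 0.5 -> 0.1. Within each phase both decay exponentially with
#' lambda = (total phase steps) / 10.
#'
#' @return List of phases, each a list(cycles, r0, rf, alpha0, alphaf).
#' @export
default_schedule <- function() {
  list(list(cycles = 1L, r0 = 7.5, rf = 3.75, alpha0 = 1.0, alphaf = 0.5),
       list(cycles = 10L, r0 = 3.75, rf = 1.0, alpha0 = 0.5, alphaf = 0.1))
}

validate_schedule <- function(schedule) {
  for (ph in schedule) {
    if (!(ph$r0 >= ph$rf && ph$rf > 0)) stopf("schedule needs r0 >= rf > 0")
    if (!(ph$alpha0 >= ph$alphaf && ph$alphaf > 0))
      stopf("schedule needs alpha0 >= alphaf > 0")
    if (ph$cycles < 1L) stopf("each phase needs >= 1 cycle")
  }
  schedule
}

#' Train a SOM on 3D points
#'
#' Each cycle presents every input point once in a seeded random order,
#' updating the map after each presentation: the best-matching unit (BMU)
#' is found and every neuron w moves by alpha_t exp(-d^2 / (2 r_t^2))
#' (x - w), where d is the Euclidean distance in map-index space between
#' the neuron and the BMU. Radius and learning rate decay exponentially
#' within each phase (step counter t runs across the phase's cycles).
#' Identical seed and inputs give bit-identical maps.
#'
#' @param som An initialized \code{som_map}.
#' @param points n x 3 input coordinates (Angstrom).
#' @param schedule Training schedule (default \code{default_schedule()}).
#' @param seed Integer seed for the presentation orders.
#' @param kernel \code{"gaussian"} (default) applies the Gaussian
#'   neighborhood to every neuron; \code{"cutoff"} additionally zeroes the
#'   update beyond the current radius.
#' @return The trained \code{som_map}.
#' @export
som_train <- function(som, points, schedule = default_schedule(),
                      seed = 1L, kernel = c("gaussian", "cutoff")) {
  if (!inherits(som, "som_map")) stopf("som must be a som_map")
  kernel <- match.arg(kernel)
  points <- as_xyz_matrix(points, "points")
  if (nrow(points) < 1L) stopf("need at least one input point")
  schedule <- validate_schedule(schedule)
  n <- nrow(points)
  codes <- som$codes + 0 # force a copy; C++ updates in place
  phase_fun <- if (kernel == "gaussian") cpp_som_phase else cpp_som_phase_cutoff
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (ph in schedule) {
    order0 <- unlist(lapply(seq_len(ph$cycles),
                            function(cy) sample.int(n) - 1L))
    codes <- phase_fun(codes, som$dims[1], som$dims[2], som$dims[3],
                       points, order0, ph$r0, ph$rf, ph$alpha0, ph$alphaf)
  }
  som$codes <- codes
  som$trained <- TRUE
  som$seed <- as.integer(seed)
  som$schedule <- schedule
  som
}

#' Fit a SOM to a point cloud (convenience wrapper)
#'
#' PCA frame, dimensioning, initialization and training in one call.
#'
#' @param points n x 3 coordinates (Angstrom).
#' @param target_size Target neuron count (default 3375 = 15^3).
#' @param schedule Training schedule.
#' @param seed Integer seed.
#' @param kernel Neighborhood kernel, see \code{\link{som_train}}.
#' @return A trained \code{som_map}.
#' @export
som_fit <- function(points, target_size = 3375L,
                    schedule = default_schedule(), seed = 1L,
                    kernel = "gaussian") {
  frame <- pca_frame(points)
  som <- init_som(frame, map_dims(frame$lengths, target_size))
  som_train(som, points, schedule = schedule, seed = seed, kernel = kernel)
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("som_map %d x %d x %d (%d neurons), %s\n", x$dims[1],
              x$dims[2], x$dims[3], nrow(x$codes),
              if (isTRUE(x$trained)) sprintf("trained (seed %d)", x$seed)
              else "untrained"))
  invisible(x)
}

#' Best-matching unit of one or more points
#'
#' The neuron with minimal Euclidean distance to the point; ties are
#' broken by the smallest flat index (k fastest).
#'
#' @param som A \code{som_map}.
#' @param points Length-3 coordinate or n x 3 matrix.
#' @return Integer flat neuron indices (1-based); use
#'   \code{\link{som_neuron_index}} for (i,j,k) triples.
#' @export
som_bmu <- function(som, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  cpp_bmu(som$codes, as_xyz_matrix(points, "points")) + 1L
}

#' Convert flat neuron indices to (i,j,k)
#' @param som A \code{som_map}.
#' @param flat Integer flat indices.
#' @return n x 3 integer matrix of lattice indices.
#' @export
som_neuron_index <- function(som, flat) som_unflat(flat, som$dims)

#' Quantization errors of a trained map
#'
#' Per-point Euclidean distance to the BMU; their mean +/- sd measures the
#' acuity of the map.
#'
#' @param som A trained \code{som_map}.
#' @param points n x 3 coordinates (Angstrom).
#' @return Numeric vector of distances with attribute \code{summary}
#'   (mean, sd).
#' @export
quantization_errors <- function(som, points) {
  if (!isTRUE(som$trained)) stopf("som must be trained")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as_xyz_matrix(points, "points")
  b <- som_bmu(som, points)
  d <- sqrt(rowSums((points - som$codes[b, , drop = FALSE])^2))
  attr(d, "summary") <- c(mean = mean(d), sd = sd(d))
  d
}

#' Serialize a SOM to JSON
#' @param som A \code{som_map}.
#' @param path Output path.
#' @export
write_som_json <- function(som, path) {
  jsonlite::write_json(list(dims = som$dims, trained = som$trained,
                            seed = som$seed, schedule = som$schedule,
                            codes = som$codes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a SOM from JSON written by \code{\link{write_som_json}}
#' @param path JSON path.
#' @return A \code{som_map}.
#' @export
read_som_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(dims = as.integer(x$dims), codes = as.matrix(x$codes),
                 trained = isTRUE(x$trained),
                 seed = as.integer(x$seed %||% NA_integer_),
                 schedule = if (is.data.frame(x$schedule))
                   lapply(seq_len(nrow(x$schedule)), function(i)
                     as.list(x$schedule[i, ])) else x$schedule),
            class = "som_map")
}
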