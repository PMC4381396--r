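# U-matrix, GMM thresholds, consensual clusters and target evaluation.

test_that("U-matrix equals the brute-force neighbor enumeration", {
  set.seed(11)
  for (rep in 1:3) {
    dims <- sample(2:5, 3, replace = TRUE)
    som <- som_from_codes(matrix(rnorm(prod(dims) * 3, sd = 2),
                                 ncol = 3), dims)
    um <- compute_umatrix(som)
    expect_equal(um$values, oracle_umatrix(som), tolerance = 1e-12)
  }
})

test_that("U-matrix handles degenerate and analytic cases", {
  # all neurons identical -> all zeros
  som0 <- som_from_codes(matrix(1, 8, 3), c(2, 2, 2))
  expect_true(all(compute_umatrix(som0)$values == 0))

  # 2x2x2 unit cube: every neuron sees 3 edges, 3 face and 1 space diagonal
  som1 <- som_lattice(c(2, 2, 2), s = 1)
  expect_equal(compute_umatrix(som1)$values,
               rep((3 + 3 * sqrt(2) + sqrt(3)) / 7, 8), tolerance = 1e-12)

  flat <- som_from_codes(matrix(rnorm(12), ncol = 3), c(4, 1, 1))
  expect_error(compute_umatrix(flat), ">= 2")
  untrained <- som_from_codes(matrix(1, 8, 3), c(2, 2, 2), trained = FALSE)
  expect_error(compute_umatrix(untrained), "trained")
})

test_that("the GMM threshold is mean + sd of the dominant component", {
  # degenerate: a single repeated value
  expect_equal(fit_gmm_threshold(rep(3.2, 50))$threshold, 3.2)

  # single Gaussian: threshold ~ mu + sigma
  set.seed(12)
  x <- rnorm(1e4, 5, 1)
  fit <- fit_gmm_threshold(x, seed = 12)
  expect_equal(fit$threshold, mean(x) + sd(x), tolerance = 0.02)

  # bimodal: the dominant low mode sets the threshold
  set.seed(13)
  y <- c(rnorm(9000, 1, 0.1), rnorm(1000, 5, 0.1))
  fy <- fit_gmm_threshold(y, seed = 13)
  expect_equal(fy$threshold, 1.1, tolerance = 0.05)
  expect_lt(fy$threshold, 2)
  expect_gte(fy$gmm$n_components, 2L)

  expect_error(fit_gmm_threshold(c(1, 2)), ">= 10")
})

test_that("the threshold is location-equivariant", {
  set.seed(14)
  x <- c(rnorm(500, 2, 0.3), rnorm(200, 6, 0.5))
  t0 <- fit_gmm_threshold(x, seed = 14)$threshold
  t1 <- fit_gmm_threshold(x + 10, seed = 14)$threshold
  expect_equal(t1, t0 + 10, tolerance = 1e-6)
})

test_that("consensual clusters are connected components of low-U neurons", {
  # constructed map: two low-U blocks (10 and 4 neurons) in a 5x5x5 lattice
  dims <- c(5L, 5L, 5L)
  som <- som_lattice(dims, s = 1)
  u <- rep(10, prod(dims))
  flat <- function(i, j, k) somsite:::som_flat(i, j, k, dims)
  block1 <- c(flat(1, 1, 1:5), flat(1, 2, 1:5))      # 10 neurons
  block2 <- flat(4:5, 5, 5)
  block2 <- c(flat(4, 5, 5), flat(5, 5, 5), flat(4, 4, 5), flat(5, 4, 5))
  u[block1] <- 0.5
  u[block2] <- 0.5
  um <- structure(list(values = u, t_u = 1, gmm = NULL),
                  class = "som_umatrix")
  ccs <- extract_ccs(um, som)
  expect_length(ccs, 2L)
  expect_equal(ccs[[1]]$n_neurons, 10L)
  expect_equal(ccs[[2]]$n_neurons, 4L)
  expect_setequal(ccs[[1]]$members, block1)
  expect_setequal(ccs[[2]]$members, unique(block2))

  # nothing below threshold -> empty list
  um2 <- structure(list(values = u, t_u = 0.1, gmm = NULL),
                   class = "som_umatrix")
  expect_length(extract_ccs(um2, som), 0L)
  um3 <- structure(list(values = u, t_u = NULL, gmm = NULL),
                   class = "som_umatrix")
  expect_error(extract_ccs(um3, som), "t_u")
})

test_that("cluster partitions match the oracle on random threshold masks", {
  set.seed(15)
  dims <- c(5L, 5L, 5L)
  som <- som_lattice(dims, s = 1)
  for (rep in 1:5) {
    u <- runif(prod(dims))
    um <- structure(list(values = u, t_u = 0.4, gmm = NULL),
                    class = "som_umatrix")
    ccs <- extract_ccs(um, som, compute_radius = FALSE)
    mask <- somsite:::som_array(u <= 0.4, dims)
    want <- partition_signature(oracle_label26(mask))
    got <- lapply(ccs, function(cc) sort(cc$members))
    expect_setequal(lapply(want, sort), got)
  }
})

test_that("r_CC reflects the dominant intra-cluster neighbor distance mode", {
  # perfectly regular lattice: all neighbor distances equal the spacing
  dims <- c(4L, 4L, 4L)
  som <- som_lattice(dims, s = 0.7)
  cc <- list(members = seq_len(prod(dims)), n_neurons = prod(dims),
             rank = 1L)
  expect_equal(compute_rcc(cc, som), 0.7, tolerance = 1e-12)

  # bimodal neighbor spacings along a line: dominant mode + its sd
  set.seed(16)
  n <- 400L
  steps <- ifelse(runif(n - 1) < 0.8, rnorm(n - 1, 0.6, 0.05),
                  rnorm(n - 1, 1.5, 0.05))
  codes <- cbind(cumsum(c(0, steps)), 0, 0)
  line <- som_from_codes(codes, c(n, 1, 1))
  ccl <- list(members = seq_len(n), n_neurons = n, rank = 1L)
  r <- compute_rcc(ccl, line)
  expect_equal(r, 0.65, tolerance = 0.05)

  # rotation invariance
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rot <- som_from_codes(codes %*% t(R), c(n, 1, 1))
  expect_equal(compute_rcc(ccl, rot), r, tolerance = 1e-8)

  # no intra-cluster neighbor pair -> error
  iso <- list(members = c(1L, 34L), n_neurons = 2L, rank = 2L)
  expect_error(compute_rcc(iso, som_lattice(c(4, 4, 4))), "neighbor pair")
})

test_that("precision counts ligand atoms within the radius", {
  dims <- c(3L, 3L, 3L)
  som <- som_lattice(dims, s = 1)
  cc <- list(members = seq_len(27L), n_neurons = 27L, rank = 1L,
             r_cc = 1)
  at_neurons <- reference_ligand(som$codes[c(1, 5, 9), ])
  expect_equal(cc_precision(cc, som, at_neurons), 1)
  far <- reference_ligand(som$codes + 100)
  expect_equal(cc_precision(cc, som, far), 0)

  # monotone non-decreasing in the radius
  set.seed(17)
  lig <- reference_ligand(som$codes[1:5, ] +
                            matrix(rnorm(15, sd = 1), ncol = 3))
  radii <- seq(0.1, 3, by = 0.1)
  precs <- vapply(radii, function(r)
    cc_precision(cc, som, lig, radius = r), numeric(1))
  expect_true(all(diff(precs) >= 0))
})

test_that("target evaluation applies the hit and occurrence rules", {
  # three clusters along x at 0, 50, 100; fixed 1.6 A radius
  mk <- function(x0) sweep(som_lattice(c(2, 2, 2), s = 1)$codes, 2,
                           c(x0, 0, 0), `+`)
  som <- som_from_codes(rbind(mk(0), mk(50), mk(100)), c(6, 2, 2))
  ccs <- list(
    list(members = 1:8, n_neurons = 8L, rank = 1L, r_cc = 1,
         centroid = c(1.5, 1.5, 1.5)),
    list(members = 9:16, n_neurons = 8L, rank = 2L, r_cc = 1,
         centroid = c(51.5, 1.5, 1.5)),
    list(members = 17:24, n_neurons = 8L, rank = 3L, r_cc = 1,
         centroid = c(101.5, 1.5, 1.5)))
  # 10 atoms: 1 on CC1, 3 on CC2, 6 in the void -> precisions 0.1/0.3/0.0
  atoms <- rbind(c(1, 1, 1),
                 c(51, 1, 1), c(51, 2, 1), c(52, 1, 1),
                 matrix(rep(c(25, 25, 25), 6), ncol = 3, byrow = TRUE))
  ev <- evaluate_target(ccs, som, reference_ligand(atoms),
                        radius_mode = 1.6)
  expect_equal(ev$precisions, c(0.1, 0.3, 0.0))
  expect_equal(ev$hit_cc, 2L)
  expect_false(ev$top1)
  expect_true(ev$top3)
  expect_equal(ev$n_overlapping, 2L)
  expect_true(ev$occurrence_failed)

  # empty cluster list -> failure with no hit
  ev0 <- evaluate_target(list(), som, reference_ligand(atoms))
  expect_true(is.na(ev0$hit_cc))
  expect_false(ev0$top1)
  expect_true(ev0$occurrence_failed)

  # single overlapped cluster passes the occurrence rule
  ev1 <- evaluate_target(ccs[1], som,
                         reference_ligand(mk(0) + 0.1), radius_mode = 1.6)
  expect_true(ev1$top1)
  expect_false(ev1$occurrence_failed)
})

test_that("success rates aggregate Top1/Top3 flags", {
  mk_ev <- function(top1, top3, prec = 0.5) {
    structure(list(precisions = prec, hit_cc = if (top1) 1L else
      if (top3) 2L else NA_integer_, top1 = top1, top3 = top3),
      class = "target_evaluation")
  }
  all_good <- replicate(5, mk_ev(TRUE, TRUE), simplify = FALSE)
  sr <- success_rates(all_good)
  expect_equal(sr$top1_sr, 1)
  expect_equal(sr$top3_sr, 1)

  evs <- c(replicate(41, mk_ev(TRUE, TRUE), simplify = FALSE),
           replicate(9, mk_ev(FALSE, FALSE), simplify = FALSE))
  expect_equal(success_rates(evs)$top1_sr, 0.82)
  expect_error(success_rates(list()), "at least one")
})

test_that("mean docking score projects onto neurons by BMU", {
  som <- som_lattice(c(2, 2, 2), s = 5)
  pts <- som$codes[c(1, 1, 3), ] + 0.01
  scores <- c(-8, -6, -2)
  ms <- neuron_mean_score(som, pts, scores)
  expect_equal(ms[1], -7)
  expect_equal(ms[3], -2)
  expect_true(all(is.na(ms[c(2, 4:8)])))
})
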