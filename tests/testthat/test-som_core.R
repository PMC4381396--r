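# PCA frame, map dimensioning, initialization and Kohonen training.

test_that("pca_frame recovers orientation, lengths and extrema", {
  # rank-1 data: first component along x, remaining lengths ~ 0
  x <- cbind(seq(-5, 5, length.out = 50), 0, 0)
  fr <- pca_frame(x)
  expect_equal(abs(fr$components[, 1]), c(1, 0, 0), tolerance = 1e-8)
  expect_lt(fr$lengths[2], 1e-8)
  expect_lt(fr$lengths[3], 1e-8)
  expect_equal(fr$lo[1], -fr$hi[1], tolerance = 1e-8)

  # isotropic Gaussian: all three lengths agree within 5%
  set.seed(7)
  g <- matrix(rnorm(3e4), ncol = 3)
  fg <- pca_frame(g)
  expect_lt(diff(range(fg$lengths)) / fg$lengths[1], 0.05)

  # rigid rotation leaves lengths invariant
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fr2 <- pca_frame(g %*% t(R))
  expect_equal(fr2$lengths, fg$lengths, tolerance = 1e-8)

  expect_error(pca_frame(matrix(1, 5, 3)), "distinct")
})

test_that("map_dims rounds c*S with product near the target", {
  expect_equal(map_dims(c(10, 7, 5)), c(21L, 15L, 11L))
  expect_equal(map_dims(c(3, 3, 3)), c(15L, 15L, 15L))
  expect_equal(map_dims(c(42, 42, 42)), c(15L, 15L, 15L))
  # degenerate lengths are floored, dims never below 2
  d <- map_dims(c(10, 0, 0))
  expect_true(all(d >= 2L))
  expect_error(map_dims(c(0, 0, 0)), "zero")
})

test_that("init_som spans the projection range on a regular lattice", {
  fr <- structure(list(mean = c(0, 0, 0), components = diag(3),
                       lengths = c(1, 1, 1), lo = c(0, 0, 0),
                       hi = c(1, 1, 1)), class = "pca_frame")
  som <- init_som(fr, c(2, 2, 2))
  expect_setequal(unique(som$codes[, 1]), c(0, 0.5))
  expect_setequal(unique(som$codes[, 2]), c(0, 0.5))
  # neuron (1,1,1) = mean + sum V_d lo_d
  expect_equal(som$codes[1, ], c(0, 0, 0))
  # no duplicate neurons when ranges are positive
  expect_equal(nrow(unique(som$codes)), 8L)

  fr$mean <- c(10, -5, 2)
  som2 <- init_som(fr, c(3, 3, 3))
  expect_equal(som2$codes[1, ], fr$mean + c(0, 0, 0))
})

test_that("training contracts the map onto a single repeated point", {
  set.seed(1)
  spread <- matrix(rnorm(60, sd = 5), ncol = 3)
  fr <- pca_frame(spread)
  som <- init_som(fr, c(3, 3, 3))
  p <- c(2, -1, 4)
  pts <- matrix(rep(p, 200), ncol = 3, byrow = TRUE)
  trained <- som_train(som, pts, seed = 9)
  expect_true(trained$trained)
  expect_lt(max(sqrt(rowSums(sweep(trained$codes, 2, p)^2))), 1e-3)
})

test_that("training is bit-identical under a fixed seed", {
  set.seed(2)
  pts <- matrix(rnorm(900, sd = 3), ncol = 3)
  fr <- pca_frame(pts)
  som <- init_som(fr, map_dims(fr$lengths, 216L))
  a <- som_train(som, pts, seed = 5)
  b <- som_train(som, pts, seed = 5)
  expect_identical(a$codes, b$codes)
  c <- som_train(som, pts, seed = 6)
  expect_false(identical(a$codes, c$codes))
})

test_that("two separated clusters are resolved into contiguous map regions", {
  set.seed(3)
  cl1 <- matrix(rnorm(1500, sd = 1), ncol = 3) +
    matrix(rep(c(-20, 0, 0), 500), ncol = 3, byrow = TRUE)
  cl2 <- matrix(rnorm(1500, sd = 1), ncol = 3) +
    matrix(rep(c(20, 0, 0), 500), ncol = 3, byrow = TRUE)
  pts <- rbind(cl1, cl2)
  som <- som_fit(pts, target_size = 512L, seed = 4)

  # every neuron ends near the closer cluster center
  d1 <- sqrt(rowSums(sweep(som$codes, 2, c(-20, 0, 0))^2))
  d2 <- sqrt(rowSums(sweep(som$codes, 2, c(20, 0, 0))^2))
  expect_lt(max(pmin(d1, d2)), 25)

  # BMUs agree with a brute-force scan
  q <- pts[sample.int(nrow(pts), 50), ]
  expect_equal(som_bmu(som, q),
               vapply(seq_len(50), function(i) oracle_bmu(som, q[i, ]),
                      integer(1)))

  # >= 90% of each cluster's points map into one 26-connected neuron set
  for (cl in list(cl1, cl2)) {
    b <- som_bmu(som, cl)
    mask <- array(FALSE, c(som$dims[3], som$dims[2], som$dims[1]))
    mask[unique(b)] <- TRUE
    lab <- array(somsite:::cpp_label26(as.vector(mask), dim(mask)),
                 dim(mask))
    counts <- table(lab[b]) # points per component
    expect_gte(max(counts) / length(b), 0.9)
  }
})

test_that("bmu resolves ties to the smallest flat index", {
  codes <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(6, 0, 0))
  som <- som_from_codes(codes, c(4, 1, 1))
  expect_equal(som_bmu(som, c(1, 0, 0)), 1L)  # equidistant to 1 and 2
  expect_equal(som_bmu(som, c(2, 0, 0)), 2L)  # exact hit
})

test_that("quantization error is zero at neuron positions and improves with training", {
  run <- small_pocket_run(seed = 6, n_ligands = 10L, target_size = 216L)
  som <- run$som
  qe0 <- quantization_errors(som, som$codes)
  expect_true(all(qe0 == 0))

  # full two-phase schedule is at least as acute as phase 1 alone
  fr <- pca_frame(run$pts)
  som0 <- init_som(fr, map_dims(fr$lengths, 216L))
  phase1 <- som_train(som0, run$pts, schedule = default_schedule()[1],
                      seed = 6)
  full <- som_train(som0, run$pts, seed = 6)
  m1 <- attr(quantization_errors(phase1, run$pts), "summary")["mean"]
  m2 <- attr(quantization_errors(full, run$pts), "summary")["mean"]
  expect_lte(m2, m1)
})

test_that("a larger map target does not increase the mean quantization error", {
  set.seed(8)
  cl <- rbind(matrix(rnorm(900, sd = 1), ncol = 3),
              sweep(matrix(rnorm(900, sd = 1), ncol = 3), 2,
                    c(15, 0, 0), `+`))
  small <- som_fit(cl, target_size = 216L, seed = 8)
  large <- som_fit(cl, target_size = 1000L, seed = 8)
  expect_lte(attr(quantization_errors(large, cl), "summary")["mean"],
             attr(quantization_errors(small, cl), "summary")["mean"])
})

test_that("trained neurons stay inside the union bounding box of data and lattice", {
  set.seed(9)
  pts <- matrix(rnorm(1200, sd = 4), ncol = 3)
  fr <- pca_frame(pts)
  som0 <- init_som(fr, map_dims(fr$lengths, 343L))
  som <- som_train(som0, pts, seed = 9)
  lo <- pmin(apply(pts, 2, min), apply(som0$codes, 2, min)) - 1e-9
  hi <- pmax(apply(pts, 2, max), apply(som0$codes, 2, max)) + 1e-9
  expect_true(all(sweep(som$codes, 2, lo, `>=`)))
  expect_true(all(sweep(som$codes, 2, hi, `<=`)))
})

test_that("SOM JSON serialization round-trips", {
  run <- small_pocket_run(seed = 10, n_ligands = 5L, target_size = 125L)
  tf <- withr::local_tempfile(fileext = ".json")
  write_som_json(run$som, tf)
  back <- read_som_json(tf)
  expect_equal(back$dims, run$som$dims)
  expect_equal(back$codes, run$som$codes, tolerance = 1e-12)
  expect_true(back$trained)
})
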