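# Fixtures and independent oracles used across the suite. The oracles are
# deliberately naive (triple loops, breadth-first searches, direct
# distance scans) so they share no code path with the implementation.

# Build a som_map directly from neuron coordinates (flat order: k fastest).
som_from_codes <- function(codes, dims, trained = TRUE) {
  structure(list(dims = as.integer(dims), codes = as.matrix(codes),
                 trained = trained, seed = 0L, schedule = NULL),
            class = "som_map")
}

# Regular lattice SOM with spacing s, dims (I,J,K).
som_lattice <- function(dims, s = 1) {
  idx <- expand.grid(k = seq_len(dims[3]), j = seq_len(dims[2]),
                     i = seq_len(dims[1]))
  # flat order k fastest: k varies first, then j, then i
  codes <- cbind(idx$i, idx$j, idx$k) * s
  som_from_codes(codes, dims)
}

# Brute-force U-matrix: triple loop over all neuron pairs' index offsets.
oracle_umatrix <- function(som) {
  dims <- som$dims
  vals <- numeric(prod(dims))
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      f <- ((i - 1) * dims[2] + (j - 1)) * dims[3] + k
      acc <- c()
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
            kk < 1 || kk > dims[3]) next
        g <- ((ii - 1) * dims[2] + (jj - 1)) * dims[3] + kk
        acc <- c(acc, sqrt(sum((som$codes[f, ] - som$codes[g, ])^2)))
      }
      vals[f] <- mean(acc)
    }
  vals
}

# Brute-force BMU: full distance scan, first minimum wins.
oracle_bmu <- function(som, p) {
  d2 <- rowSums(sweep(som$codes, 2, p)^2)
  which(d2 == min(d2))[1]
}

# Breadth-first 26-connected component labeling of a logical 3D array.
oracle_label26 <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      a <- arrayInd(cur, dims)
      for (d1 in -1:1) for (d2 in -1:1) for (d3 in -1:1) {
        b <- a + c(d1, d2, d3)
        if (any(b < 1) || any(b > dims)) next
        q <- b[1] + dims[1] * ((b[2] - 1) + dims[2] * (b[3] - 1))
        if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# Partition signature invariant to label permutation.
partition_signature <- function(lab) {
  unname(split(which(lab != 0), lab[lab != 0]))
}

# Tiny hand-written PDB fixtures.
write_tiny_pdb <- function(path, atoms) {
  # atoms: data.frame with element, x, y, z
  lines <- sprintf(
    "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), atoms$element, seq_len(nrow(atoms)),
    atoms$x, atoms$y, atoms$z, atoms$element)
  writeLines(c(lines, "END"), path)
  path
}

# Small planted-pocket run shared by a few tests (cheap settings).
small_pocket_run <- function(seed = 1L, n_ligands = 20L,
                             target_size = 512L) {
  sim <- sample_poses(planted_pocket_specs(), n_ligands = n_ligands,
                      seed = seed)
  pts <- pose_coordinates(sim$pose_sets)
  som <- som_fit(pts, target_size = target_size, seed = seed)
  um <- umatrix_threshold(compute_umatrix(som), seed = seed)
  list(sim = sim, pts = pts, som = som, um = um,
       ccs = extract_ccs(um, som))
}
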