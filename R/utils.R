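# Internal helpers shared across modules.

# Flat neuron index convention: for map dims (I,J,K), flat = ((i-1)*J +
# (j-1))*K + (k-1) + 1, i.e. k varies fastest. This equals plain R array
# order for an array of dim c(K, J, I), which is what som_array() builds.

som_flat <- function(i, j, k, dims) {
  ((i - 1L) * dims[2] + (j - 1L)) * dims[3] + (k - 1L) + 1L
}

som_unflat <- function(f, dims) {
  f0 <- f - 1L
  k <- f0 %% dims[3]
  j <- (f0 %/% dims[3]) %% dims[2]
  i <- f0 %/% (dims[3] * dims[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

som_array <- function(values, dims) {
  array(values, dim = c(dims[3], dims[2], dims[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

as_xyz_matrix <- function(x, what = "coordinates") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stopf("%s must be an n x 3 matrix", what)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stopf("%s contain non-finite values", what)
  dimnames(x) <- NULL
  x
}

# Deterministic 31-bit polynomial string hash (base 131, modulus 2^31-1).
# All intermediate products stay below 2^53 so double arithmetic is exact.
hash31 <- function(s) {
  m <- 2147483647
  v <- utf8ToInt(s) %% m
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% m
  as.integer(h)
}
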