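# Internal helpers shared across modules.

# Flatten an n x K x 3 shape array to an n x 3K matrix (column order:
# all x, then all y, then all z). Inverse of unflatten_shapes().
flatten_shapes <- function(coords) {
  n <- dim(coords)[1L]
  matrix(coords, nrow = n)
}

unflatten_shapes <- function(mat, K) {
  array(mat, dim = c(nrow(mat), K, 3L))
}

# Reshape one flattened 3K shape vector back to K x 3.
vec_to_shape <- function(v, K) {
  matrix(v, nrow = K, ncol = 3L)
}

shape_to_vec <- function(s) as.vector(s)

# Deterministic 32-bit seed derived from a master seed and a text key, so
# independent random streams (per group, per simulation) can be spawned
# without one stream's length affecting another.
derive_seed <- function(seed, key) {
  u <- utf8ToInt(as.character(key))
  h <- sum(u * ((seq_along(u) - 1L) %% 31L + 1L))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 1009) %% 2147483647)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
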