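#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid; the standard size measure removed by Procrustes scaling.
#'
#' @param shape a `K x 3` coordinate matrix.
#' @return positive scalar (same units as the coordinates).
#' @export
centroid_size <- function(shape) {
  sqrt(sum(scale(shape, scale = FALSE)^2))
}

# Center a configuration at the origin.
.center_shape <- function(shape) {
  sweep(shape, 2L, colMeans(shape))
}

# Optimal proper rotation of b onto a (both centered): the rotation R with
# det(R) = +1 minimizing ||a - bR||_F. Reflections are never allowed —
# anatomical configurations must not be mirrored.
.rotate_onto <- function(b, a) {
  sv <- svd(crossprod(b, a))
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  b %*% R
}

#' Generalized Procrustes superimposition
#'
#' Superimposes all configurations by translating each to the origin,
#' scaling to unit centroid size, and iteratively rotating onto an evolving
#' consensus (the arithmetic mean shape) until the consensus stabilizes.
#' Rotations are restricted to proper rotations (no reflection). After
#' convergence the whole set is rotated to a canonical orientation (the
#' consensus aligned to its principal axes with a fixed sign convention) so
#' that the output is invariant to arbitrary rigid motions and uniform
#' scalings of the input specimens.
#'
#' @param dataset a [landmark_dataset()] with `K >= 4` landmarks and
#'   `n >= 2` specimens.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter maximum number of alignment iterations.
#' @return an object of class `aligned_dataset`: list with `shape_coords`
#'   (`n x K x 3` dimensionless Procrustes coordinates, each configuration
#'   centered with unit centroid size), `centroid_sizes` (mm),
#'   `consensus` (`K x 3` mean shape), `n_iterations`, `converged`,
#'   `source_meta`, `landmark_labels` and `allometry_corrected = FALSE`.
#' @export
gpa_superimpose <- function(dataset, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  coords <- dataset$coordinates
  n <- dim(coords)[1L]; K <- dim(coords)[2L]
  if (n < 2L) stop("GPA requires at least 2 specimens")
  cs <- numeric(n)
  X <- array(NA_real_, dim = dim(coords))
  for (i in seq_len(n)) {
    s <- .center_shape(coords[i, , ])
    cs[i] <- sqrt(sum(s^2))
    if (cs[i] <= 0)
      stop("zero centroid size (all landmarks coincident) for specimen ",
           dataset$meta$specimen_id[i])
    X[i, , ] <- s / cs[i]
  }

  consensus <- X[1L, , ]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) X[i, , ] <- .rotate_onto(X[i, , ], consensus)
    m <- apply(X, c(2L, 3L), mean)
    m <- .center_shape(m)
    m <- m / sqrt(sum(m^2))
    delta <- sqrt(mean((m - consensus)^2))
    consensus <- m
    if (delta < tol) { converged <- TRUE; break }
  }
  for (i in seq_len(n)) X[i, , ] <- .rotate_onto(X[i, , ], consensus)

  # canonical orientation: principal axes of the consensus, largest-|loading|
  # element of each axis positive, proper rotation enforced
  V <- .canonical_axes(consensus)
  for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% V
  consensus <- apply(X, c(2L, 3L), mean)

  dimnames(X) <- dimnames(coords)
  structure(list(shape_coords = X, centroid_sizes = cs,
                 consensus = consensus, n_iterations = iter,
                 converged = converged, source_meta = dataset$meta,
                 landmark_labels = dataset$landmark_labels,
                 allometry_corrected = FALSE),
            class = "aligned_dataset")
}

# Principal-axis rotation with signs fixed on the rotated shape (the
# landmark with the largest |coordinate| on each axis made positive), so
# the orientation is a deterministic function of the shape alone. The
# proper-rotation constraint overrides the sign rule on the minor axis.
.canonical_axes <- function(shape) {
  C <- .center_shape(shape)
  V <- eigen(crossprod(C), symmetric = TRUE)$vectors
  B <- C %*% V
  for (j in 1:3) {
    i <- which.max(abs(B[, j]))
    if (B[i, j] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  V
}

#' @export
print.aligned_dataset <- function(x, ...) {
  d <- dim(x$shape_coords)
  cat("Procrustes-aligned dataset:", d[1L], "specimens x", d[2L],
      "landmarks\n")
  cat("iterations:", x$n_iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("centroid size range:",
      paste(signif(range(x$centroid_sizes), 4), collapse = " - "), "mm\n")
  if (isTRUE(x$allometry_corrected))
    cat("shape coordinates are allometry-corrected residuals\n")
  invisible(x)
}

#' Partial Procrustes distance between two aligned shapes
#'
#' Root summed squared coordinate difference after optimally rotating
#' `shape_b` onto `shape_a` (proper rotation only). Both shapes are assumed
#' to be in the Procrustes alignment frame (centered; unit centroid size for
#' individual specimens, or group means thereof). The distance is symmetric
#' and zero iff the shapes are identical up to rotation.
#'
#' @param shape_a,shape_b `K x 3` matrices with equal `K`.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  shape_a <- as.matrix(shape_a); shape_b <- as.matrix(shape_b)
  if (!all(dim(shape_a) == dim(shape_b)))
    stop("shapes have mismatched dimensions (",
         paste(dim(shape_a), collapse = "x"), " vs ",
         paste(dim(shape_b), collapse = "x"), ")")
  a <- .center_shape(shape_a)
  b <- .rotate_onto(.center_shape(shape_b), a)
  sqrt(sum((a - b)^2))
}
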