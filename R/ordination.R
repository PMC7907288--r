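#' Principal component analysis of aligned shapes
#'
#' Eigendecomposition of the specimen covariance matrix of the flattened
#' Procrustes coordinates (allometry-corrected residuals when correction has
#' been applied). Scores are centered projections; eigenvector signs are
#' fixed so that the largest-magnitude loading of each component is
#' positive, making ordinations reproducible across runs.
#'
#' @param aligned an `aligned_dataset` with `n >= 3` specimens.
#' @return an object of class `shape_pca`: `eigenvectors` (3K x m loading
#'   matrix), `eigenvalues` (non-increasing), `scores` (n x m),
#'   `percent_variance` (sums to 100), `mean_shape` (K x 3), `K`,
#'   `landmark_labels`.
#' @export
pca_fit <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  n <- n_specimens(aligned); K <- n_landmarks(aligned)
  if (n < 3L) stop("PCA requires at least 3 specimens, got ", n)
  X <- flatten_shapes(aligned$shape_coords)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- p$rotation
  sco <- p$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  ev <- p$sdev^2
  rownames(sco) <- aligned$source_meta$specimen_id
  structure(list(eigenvectors = rot, eigenvalues = ev, scores = sco,
                 percent_variance = 100 * ev / sum(ev),
                 mean_shape = vec_to_shape(p$center, K),
                 K = K, landmark_labels = aligned$landmark_labels),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", nrow(x$scores), "specimens,", length(x$eigenvalues),
      "components\n")
  m <- min(5L, length(x$percent_variance))
  cat("percent variance (first ", m, "): ",
      paste(sprintf("%.1f", x$percent_variance[seq_len(m)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reconstruct the shape at a given score along one principal component
#'
#' Returns `mean_shape + score * eigenvector(component)` reshaped to
#' `K x 3` — the coordinate reconstruction used to visualize extreme
#' morphologies along an ordination axis.
#'
#' @param model a `shape_pca`.
#' @param component 1-based component index.
#' @param score position along the component, in score units.
#' @return a `K x 3` shape matrix.
#' @export
extreme_shape <- function(model, component, score) {
  stopifnot(inherits(model, "shape_pca"))
  if (component < 1L || component > ncol(model$eigenvectors))
    stop("component ", component, " out of range 1..",
         ncol(model$eigenvectors))
  s <- vec_to_shape(shape_to_vec(model$mean_shape) +
                      score * model$eigenvectors[, component], model$K)
  rownames(s) <- model$landmark_labels
  colnames(s) <- c("x", "y", "z")
  s
}

#' Convex-hull range-of-variation membership in an ordination plane
#'
#' Builds the convex hull of a reference group's scores in a 2D ordination
#' plane (typically PC1-PC2) and reports which query specimens fall inside
#' it — the geometric reading of "fell within the range of variation" of a
#' reference group. The hull is closed: boundary points count as inside.
#'
#' @param scores_2d `n_query x 2` matrix of query scores.
#' @param reference_scores_2d `n_ref x 2` matrix of reference scores;
#'   at least 3 non-collinear points.
#' @param tol relative tolerance for boundary inclusion.
#' @return list with `fraction` (in `[0, 1]`) and `inside` (logical
#'   per query specimen).
#' @export
hull_membership <- function(scores_2d, reference_scores_2d, tol = 1e-9) {
  q <- as.matrix(scores_2d); r <- as.matrix(reference_scores_2d)
  if (ncol(q) != 2L || ncol(r) != 2L)
    stop("scores must be 2-column matrices (one ordination plane)")
  if (nrow(r) < 3L) stop("need at least 3 reference points")
  h <- grDevices::chull(r)
  poly <- r[h, , drop = FALSE]
  m <- nrow(poly)
  # shoelace area; collinear references give a degenerate hull
  xs <- poly[, 1L]; ys <- poly[, 2L]
  area <- abs(sum(xs * ys[c(2:m, 1L)] - xs[c(2:m, 1L)] * ys)) / 2
  scale2 <- max(apply(r, 2L, function(v) diff(range(v))))^2
  if (m < 3L || area <= tol * max(scale2, .Machine$double.xmin))
    stop("reference points are collinear; convex hull is degenerate")

  eps <- tol * sqrt(scale2)
  inside <- rep(TRUE, nrow(q))
  # chull() returns vertices clockwise; a point is inside iff it is on the
  # clockwise side (cross product <= 0) of every edge, within tolerance
  for (i in seq_len(m)) {
    p1 <- poly[i, ]; p2 <- poly[if (i == m) 1L else i + 1L, ]
    cross <- (p2[1L] - p1[1L]) * (q[, 2L] - p1[2L]) -
             (p2[2L] - p1[2L]) * (q[, 1L] - p1[1L])
    inside <- inside & (cross <= eps)
  }
  list(fraction = mean(inside), inside = unname(inside))
}
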