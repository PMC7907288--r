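#' Permutation test of a group mean-shape difference
#'
#' Tests whether two groups differ in mean shape, using the Procrustes
#' distance between the group mean shapes as the test statistic. The null
#' distribution is generated by randomly permuting the group labels
#' `n_rounds` times over the globally aligned coordinates (labels are
#' exchangeable under the null, so the alignment is not re-run per
#' permutation) and recomputing the statistic. Permuted distances greater
#' than or equal to the observed count as exceedances, so a zero observed
#' distance yields p = 1.
#'
#' @param aligned an `aligned_dataset`.
#' @param labels per-specimen labels with exactly two classes, each with at
#'   least 2 specimens.
#' @param n_rounds number of permutations (default 10000).
#' @param seed RNG seed.
#' @param convention `"add_one"` (default): `p = (1 + b) / (1 + n_rounds)`
#'   where `b` counts exceedances, avoiding zero p-values; `"raw"`:
#'   `p = b / n_rounds`.
#' @return an object of class `perm_test`: `observed_distance`,
#'   `permuted` distances, `p_value`, `n_rounds`, `seed`, `convention`,
#'   `group_labels`.
#' @export
procrustes_perm_test <- function(aligned, labels, n_rounds = 10000L,
                                 seed = 1L,
                                 convention = c("add_one", "raw")) {
  convention <- match.arg(convention)
  stopifnot(inherits(aligned, "aligned_dataset"))
  labels <- as.character(labels)
  if (length(labels) != n_specimens(aligned))
    stop("`labels` must have one value per specimen")
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("labels must have exactly 2 classes, got ", length(lev))
  if (min(table(labels)) < 2L)
    stop("each class needs at least 2 specimens")

  K <- n_landmarks(aligned)
  X <- flatten_shapes(aligned$shape_coords)
  is_a <- labels == lev[1L]
  stat <- function(sel) {
    procrustes_distance(vec_to_shape(colMeans(X[sel, , drop = FALSE]), K),
                        vec_to_shape(colMeans(X[!sel, , drop = FALSE]), K))
  }
  observed <- stat(is_a)
  permuted <- with_seed(derive_seed(seed, "procrustes_perm"), {
    vapply(seq_len(n_rounds), function(i) stat(sample(is_a)), numeric(1))
  })
  b <- sum(permuted >= observed)
  p <- if (convention == "add_one") (1 + b) / (1 + n_rounds)
       else b / n_rounds
  structure(list(observed_distance = observed, permuted = permuted,
                 n_rounds = as.integer(n_rounds), p_value = p,
                 seed = as.integer(seed), convention = convention,
                 group_labels = lev),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Procrustes-distance permutation test: ",
      paste(x$group_labels, collapse = " vs "), "\n", sep = "")
  cat(sprintf("observed distance: %.6g\n", x$observed_distance))
  cat(sprintf("p-value: %.4g  (%d rounds, %s convention)\n",
              x$p_value, x$n_rounds, x$convention))
  invisible(x)
}
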