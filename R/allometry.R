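#' Remove allometric shape variation by regression of shape on age
#'
#' Within each age stratum, fits an ordinary least-squares multivariate
#' regression of every flattened shape coordinate on age and replaces the
#' shape coordinates by the regression residuals re-centered on the group
#' consensus. The residuals are, by construction, uncorrelated with age
#' within each group and retain the group mean shape; they are the input
#' for downstream ordination and distance-based statistics in growing
#' cohorts. Strata are fitted independently.
#'
#' @param aligned an `aligned_dataset` from [gpa_superimpose()] whose
#'   metadata carries a finite `age` for every specimen.
#' @param grouping character vector of per-specimen stratum labels; defaults
#'   to the metadata `age_group` column. Each stratum needs at least 3
#'   specimens and non-constant age.
#' @return a list with `aligned` (the input with `shape_coords` replaced by
#'   residual shapes and `allometry_corrected = TRUE`) and `models` (one
#'   `allometry_model` per stratum: `grouping`, `intercept` and `slope`
#'    3K-vectors, `residual_shapes` array).
#' @export
allometry_correct <- function(aligned, grouping = NULL) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  meta <- aligned$source_meta
  if (is.null(grouping)) grouping <- as.character(meta$age_group)
  n <- n_specimens(aligned); K <- n_landmarks(aligned)
  if (length(grouping) != n) stop("`grouping` must have one label per specimen")
  if (anyNA(grouping)) stop("missing stratum label for specimen(s): ",
                            paste(meta$specimen_id[is.na(grouping)],
                                  collapse = ", "))
  age <- as.numeric(meta$age)
  if (anyNA(age) || any(!is.finite(age)))
    stop("allometric correction needs a finite age for every specimen")

  X <- flatten_shapes(aligned$shape_coords)
  res <- X
  models <- list()
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) < 3L)
      stop("stratum '", g, "' has ", length(idx),
           " specimens; at least 3 are required")
    a <- age[idx]
    if (stats::var(a) < .Machine$double.eps * max(1, mean(a)^2))
      stop("constant age within stratum '", g, "': slope unidentifiable")
    fit <- stats::lm.fit(cbind(1, a), X[idx, , drop = FALSE])
    cons <- colMeans(X[idx, , drop = FALSE])
    res[idx, ] <- fit$residuals +
      matrix(cons, nrow = length(idx), ncol = ncol(X), byrow = TRUE)
    models[[g]] <- structure(
      list(grouping = g, intercept = fit$coefficients[1L, ],
           slope = fit$coefficients[2L, ],
           residual_shapes = unflatten_shapes(
             res[idx, , drop = FALSE], K),
           n = length(idx)),
      class = "allometry_model")
  }
  aligned$shape_coords <- unflatten_shapes(res, K)
  dimnames(aligned$shape_coords) <- list(meta$specimen_id,
                                         aligned$landmark_labels,
                                         c("x", "y", "z"))
  aligned$allometry_corrected <- TRUE
  list(aligned = aligned, models = models)
}

#' @export
print.allometry_model <- function(x, ...) {
  cat("Allometry model for stratum '", x$grouping, "' (n = ", x$n, ")\n",
      sep = "")
  cat("|slope| (shape units per unit age):",
      signif(sqrt(sum(x$slope^2)), 4), "\n")
  invisible(x)
}
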