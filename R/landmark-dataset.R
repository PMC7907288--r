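#' Construct a landmark dataset
#'
#' The pipeline's universal input: an `n x K x 3` array of 3D landmark
#' coordinates (in mm) together with per-specimen metadata. Every specimen
#' must carry the same `K >= 4` landmarks in the same order, and no
#' coordinate may be missing or non-finite.
#'
#' @param coordinates numeric array of dimension `n x K x 3` (specimens x
#'   landmarks x xyz), units mm.
#' @param landmark_labels character vector of `K` landmark names, in the
#'   stored order.
#' @param meta data frame of specimen metadata with one row per specimen.
#'   Must contain `specimen_id` (unique); recognised optional columns are
#'   `cohort` (mouse/human/synthetic), `genotype` (euploid/trisomic/mosaic),
#'   `treatment` (none/low/high/unspecified), `sex` (female/male/unknown),
#'   `age` (non-negative; days for mouse, years for human) and `age_group`.
#'   Missing optional columns are filled with neutral defaults.
#' @param scale_note optional text recording any pixel-to-mm conversion
#'   applied upstream.
#'
#' @return an object of class `landmark_dataset`: a list with elements
#'   `coordinates`, `landmark_labels`, `meta`, `scale_note`.
#' @export
landmark_dataset <- function(coordinates, landmark_labels, meta,
                             scale_note = NULL) {
  if (!is.array(coordinates) || length(dim(coordinates)) != 3L ||
      dim(coordinates)[3L] != 3L)
    stop("`coordinates` must be an n x K x 3 array")
  n <- dim(coordinates)[1L]
  K <- dim(coordinates)[2L]
  if (n < 1L) stop("dataset must contain at least one specimen")
  if (K < 4L)
    stop("at least 4 landmarks are required for 3D shape analysis, got ", K)
  if (length(landmark_labels) != K || anyDuplicated(landmark_labels))
    stop("`landmark_labels` must be ", K, " unique labels")
  if (!is.data.frame(meta) || is.null(meta$specimen_id))
    stop("`meta` must be a data frame with a `specimen_id` column")
  if (nrow(meta) != n)
    stop("metadata has ", nrow(meta), " rows but coordinates have ", n,
         " specimens")
  meta$specimen_id <- as.character(meta$specimen_id)
  if (anyDuplicated(meta$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
               collapse = ", "))
  bad <- which(!apply(is.finite(coordinates), 1L, all))
  if (length(bad))
    stop("non-finite coordinates for specimen(s): ",
         paste(meta$specimen_id[bad], collapse = ", "))

  defaults <- list(cohort = "synthetic", genotype = "euploid",
                   treatment = "none", sex = "unknown", age = NA_real_,
                   age_group = NA_character_)
  for (nm in names(defaults))
    if (is.null(meta[[nm]])) meta[[nm]] <- defaults[[nm]]
  .check_enum(meta$cohort, c("mouse", "human", "synthetic"), "cohort")
  .check_enum(meta$genotype, c("euploid", "trisomic", "mosaic"), "genotype")
  .check_enum(meta$treatment, c("none", "low", "high", "unspecified"),
              "treatment")
  .check_enum(meta$sex, c("female", "male", "unknown"), "sex")
  if (any(!is.na(meta$age) & meta$age < 0))
    stop("negative age for specimen(s): ",
         paste(meta$specimen_id[!is.na(meta$age) & meta$age < 0],
               collapse = ", "))

  dimnames(coordinates) <- list(meta$specimen_id, landmark_labels,
                                c("x", "y", "z"))
  structure(list(coordinates = coordinates,
                 landmark_labels = as.character(landmark_labels),
                 meta = meta, scale_note = scale_note),
            class = "landmark_dataset")
}

.check_enum <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), allowed)
  if (length(bad))
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = "/"), ")")
  invisible(TRUE)
}

#' @export
print.landmark_dataset <- function(x, ...) {
  d <- dim(x$coordinates)
  cat("Landmark dataset:", d[1L], "specimens x", d[2L], "landmarks (3D, mm)\n")
  tab <- table(genotype = x$meta$genotype, treatment = x$meta$treatment)
  print(tab)
  if (!is.null(x$scale_note)) cat("scale:", x$scale_note, "\n")
  invisible(x)
}

#' Number of specimens / landmarks in a dataset
#' @param x a `landmark_dataset` or `aligned_dataset`.
#' @return integer count.
#' @export
n_specimens <- function(x) dim(.coords_of(x))[1L]

#' @rdname n_specimens
#' @export
n_landmarks <- function(x) dim(.coords_of(x))[2L]

# Accept either raw or aligned datasets wherever a coordinate array is needed.
.coords_of <- function(x) {
  if (inherits(x, "landmark_dataset")) return(x$coordinates)
  if (inherits(x, "aligned_dataset")) return(x$shape_coords)
  stop("expected a landmark_dataset or aligned_dataset")
}

.meta_of <- function(x) {
  if (inherits(x, "landmark_dataset")) return(x$meta)
  if (inherits(x, "aligned_dataset")) return(x$source_meta)
  stop("expected a landmark_dataset or aligned_dataset")
}
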