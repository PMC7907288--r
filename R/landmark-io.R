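#' Read landmark coordinates and specimen metadata from delimited text
#'
#' The coordinate file is a long-form delimited table (comma or tab,
#' auto-detected) with columns `specimen_id, landmark, x, y, z`; the metadata
#' file has one row per specimen with at least `specimen_id` and optionally
#' the fields described in [landmark_dataset()]. Landmark order is taken from
#' the first specimen and enforced for all others. If the metadata carries a
#' `scale_mm_per_unit` column (e.g. a pixel-to-mm factor from photogrammetry),
#' each specimen's coordinates are multiplied by its factor so that stored
#' coordinates are always in mm.
#'
#' @param coord_path path to the coordinate table.
#' @param meta_path path to the metadata table.
#' @return a validated [landmark_dataset()].
#' @export
read_landmark_table <- function(coord_path, meta_path) {
  co <- .read_delim(coord_path)
  need <- c("specimen_id", "landmark", "x", "y", "z")
  if (!all(need %in% names(co)))
    stop("coordinate file must have columns ", paste(need, collapse = ", "))
  meta <- .read_delim(meta_path)
  if (is.null(meta$specimen_id)) stop("metadata file lacks `specimen_id`")
  meta$specimen_id <- as.character(meta$specimen_id)
  co$specimen_id <- as.character(co$specimen_id)
  co$landmark <- as.character(co$landmark)
  for (ax in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(co[[ax]]))
    if (anyNA(v)) {
      bad <- unique(co$specimen_id[is.na(v)])
      stop("non-numeric ", ax, " coordinate for specimen(s): ",
           paste(bad, collapse = ", "))
    }
    co[[ax]] <- v
  }

  ids <- unique(co$specimen_id)
  missing_meta <- setdiff(ids, meta$specimen_id)
  if (length(missing_meta))
    stop("specimen(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  labels <- co$landmark[co$specimen_id == ids[1L]]
  if (anyDuplicated(labels))
    stop("duplicate landmark labels for specimen ", ids[1L])
  K <- length(labels)
  n <- length(ids)
  coords <- array(NA_real_, dim = c(n, K, 3L))
  for (i in seq_len(n)) {
    rows <- co[co$specimen_id == ids[i], , drop = FALSE]
    if (nrow(rows) != K || !setequal(rows$landmark, labels) ||
        anyDuplicated(rows$landmark))
      stop("specimen ", ids[i], " has an inconsistent landmark set ",
           "(expected the ", K, " landmarks of specimen ", ids[1L], ")")
    ord <- match(labels, rows$landmark)
    coords[i, , ] <- as.matrix(rows[ord, c("x", "y", "z")])
  }
  meta <- meta[match(ids, meta$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL

  scale_note <- NULL
  if (!is.null(meta$scale_mm_per_unit)) {
    f <- as.numeric(meta$scale_mm_per_unit)
    if (anyNA(f) || any(f <= 0))
      stop("scale_mm_per_unit must be positive for all specimens")
    coords <- coords * array(rep(f, K * 3L), dim = dim(coords))
    scale_note <- "coordinates rescaled to mm via per-specimen scale_mm_per_unit"
    meta$scale_mm_per_unit <- NULL
  }
  landmark_dataset(coords, labels, meta, scale_note = scale_note)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a landmark dataset to delimited text files
#'
#' Writes the long-form coordinate table and the metadata table such that
#' `read_landmark_table()` round-trips the dataset exactly (coordinates at
#' full double precision, all metadata fields preserved).
#'
#' @param dataset a [landmark_dataset()].
#' @param coord_path,meta_path output paths (comma-separated).
#' @return invisibly, `dataset`.
#' @export
write_landmark_table <- function(dataset, coord_path, meta_path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_specimens(dataset); K <- n_landmarks(dataset)
  ids <- dataset$meta$specimen_id
  co <- data.frame(
    specimen_id = rep(ids, each = K),
    landmark = rep(dataset$landmark_labels, times = n),
    x = .fmt_full(as.vector(t(dataset$coordinates[, , 1L]))),
    y = .fmt_full(as.vector(t(dataset$coordinates[, , 2L]))),
    z = .fmt_full(as.vector(t(dataset$coordinates[, , 3L]))),
    stringsAsFactors = FALSE)
  utils::write.table(co, coord_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(dataset$meta, meta_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(dataset)
}

# full round-trip precision for doubles
.fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read landmark configurations from a TPS file (LM3 blocks)
#'
#' Convenience reader for the classic TPS landmark dialect: repeated
#' `LM3=K` blocks of K lines of `x y z`, each optionally followed by an
#' `ID=` line. Landmarks are unlabelled in TPS; labels `L01..LK` are
#' assigned. Metadata is filled with neutral defaults (synthetic cohort).
#'
#' @param path path to the TPS file.
#' @param scale optional scale factor (mm per file unit) applied to all
#'   coordinates.
#' @return a [landmark_dataset()].
#' @export
read_tps <- function(path, scale = 1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM3 blocks found in ", path)
  shapes <- list(); ids <- character(0)
  for (b in seq_along(starts)) {
    s <- starts[b]
    K <- as.integer(sub("^LM3=", "", lines[s], ignore.case = TRUE))
    block <- lines[(s + 1L):(s + K)]
    m <- do.call(rbind, lapply(strsplit(block, "[ \t]+"), as.numeric))
    if (ncol(m) != 3L || anyNA(m))
      stop("malformed LM3 block ", b, " in ", path)
    end <- if (b < length(starts)) starts[b + 1L] - 1L else length(lines)
    idl <- grep("^ID=", lines[(s + K):end], ignore.case = TRUE, value = TRUE)
    ids[b] <- if (length(idl)) sub("^ID=", "", idl[1L], ignore.case = TRUE)
              else sprintf("tps_%03d", b)
    shapes[[b]] <- m * scale
  }
  Ks <- vapply(shapes, nrow, 1L)
  if (length(unique(Ks)) != 1L)
    stop("inconsistent landmark counts across TPS blocks")
  K <- Ks[1L]
  coords <- array(NA_real_, dim = c(length(shapes), K, 3L))
  for (i in seq_along(shapes)) coords[i, , ] <- shapes[[i]]
  landmark_dataset(coords, sprintf("L%02d", seq_len(K)),
                   data.frame(specimen_id = ids, stringsAsFactors = FALSE),
                   scale_note = if (scale != 1)
                     paste0("TPS coordinates x ", scale, " mm/unit"))
}
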