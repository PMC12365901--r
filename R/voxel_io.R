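#' Voxel label maps
#'
#' A label map is a 3-D integer grid in which 0 marks background, 1 marks a
#' predicted IDH-mutant tumor voxel and 2 a predicted IDH-wildtype tumor
#' voxel. Orientation/affine metadata is carried opaquely (for round-trip
#' fidelity) but never interpreted: every downstream quantity is a voxel
#' count, so coordinate conventions are irrelevant by construction.
#'
#' @param labels 3-D integer array with values in \{0, 1, 2\}.
#' @param subject_id,fold_id optional identifiers.
#' @param reference optional NIfTI object whose header (affine, pixdim) is
#'   reused when the map is written back out.
#' @return an object of class `idh_label_map`.
#' @export
label_map <- function(labels, subject_id = NA_character_, fold_id = NA_integer_,
                      reference = NULL) {
  if (length(dim(labels)) != 3L)
    .idh_stop("idh_format_error", "labels must be a 3-D array")
  vals <- unique(as.vector(labels))
  if (any(vals != as.integer(vals)))
    .idh_stop("idh_format_error",
              sprintf("non-integer voxel values present: %s",
                      paste(head(vals[vals != as.integer(vals)], 5), collapse = ", ")))
  bad <- setdiff(as.integer(vals), c(0L, 1L, 2L))
  if (length(bad) > 0L)
    .idh_stop("idh_format_error",
              sprintf("voxel value(s) outside {0,1,2}: %s",
                      paste(sort(bad), collapse = ", ")))
  labels <- array(as.integer(labels), dim = dim(labels))  # drop foreign attributes
  structure(list(labels = labels, subject_id = subject_id,
                 fold_id = as.integer(fold_id), reference = reference),
            class = "idh_label_map")
}

#' @export
print.idh_label_map <- function(x, ...) {
  cat(sprintf("idh_label_map %s [fold %s]: %s grid, %d mutant / %d wildtype voxels\n",
              x$subject_id, x$fold_id,
              paste(dim(x$labels), collapse = "x"),
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' Read a label volume from NIfTI
#'
#' Loads a NIfTI-1 volume and validates the two-class tumor labelling
#' convention (0 background, 1 mutant, 2 wildtype). Any other voxel value is
#' a format error naming the offending values.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id,fold_id optional identifiers attached to the map.
#' @return an [label_map()].
#' @export
read_label_map <- function(path, subject_id = NA_character_, fold_id = NA_integer_) {
  if (!file.exists(path))
    .idh_stop("idh_io_error", sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- array(arr, dim = dim(arr)[1:3])
  label_map(arr, subject_id = subject_id, fold_id = fold_id, reference = img)
}

#' Write a label volume to NIfTI
#'
#' @param map an [label_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "idh_label_map"))
  img <- if (is.null(map$reference)) {
    RNifti::asNifti(map$labels, datatype = "int16")
  } else {
    RNifti::asNifti(map$labels, reference = map$reference, datatype = "int16")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Reduce a label map to whole-tumor per-class voxel counts
#'
#' @param map an [label_map()] or a plain integer array over \{0, 1, 2\}.
#' @return a list with `n_mutant` (label-1 voxels) and `n_wildtype` (label-2
#'   voxels). A map with no tumor voxels at all raises an empty-tumor error:
#'   such subjects carry no signal and are excluded upstream with a logged
#'   reason.
#' @export
whole_tumor_counts <- function(map) {
  labels <- if (inherits(map, "idh_label_map")) map$labels else map
  n1 <- sum(labels == 1L)
  n2 <- sum(labels == 2L)
  if (n1 + n2 == 0L)
    .idh_stop("idh_empty_tumor_error",
              "label map contains no tumor voxels (labels 1 or 2)")
  list(n_mutant = as.integer(n1), n_wildtype = as.integer(n2))
}

#' Read a per-fold voxel counts table
#'
#' The counts CSV is the imaging-free entry point: one row per subject and
#' fold with the per-class tumor voxel counts already tallied.
#'
#' @param path CSV with columns `subject_id`, `fold_id`, `n_mutant`,
#'   `n_wildtype`.
#' @return validated data frame.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path))
    .idh_stop("idh_io_error", sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "fold_id", "n_mutant", "n_wildtype")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    .idh_stop("idh_format_error",
              sprintf("counts table missing column(s): %s",
                      paste(miss, collapse = ", ")))
  if (any(df$n_mutant < 0 | df$n_wildtype < 0))
    .idh_stop("idh_format_error", "negative voxel counts in counts table")
  df
}
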