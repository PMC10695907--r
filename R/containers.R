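#' Grayscale voxel volume
#'
#' A 3D scalar field on an isotropic grid. The array is stored in
#' `(z, y, x)` order: the first index is the slice (acquisition) axis, so
#' `data[z, , ]` is one image slice. Voxel size is a single isotropic edge
#' length in micrometres; anisotropic grids are rejected by design because
#' all downstream morphology assumes isotropy.
#'
#' @param data numeric 3D array, `(z, y, x)` order.
#' @param voxel_edge_um positive isotropic voxel edge length in micrometres.
#' @param dtype_bits sample width the volume is meant to be stored at:
#'   8 or 16 (unsigned integer) or 32 (float). Defaults to 32 for
#'   non-integer data, else the narrowest unsigned type that fits.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_edge_um, dtype_bits = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dims must be >= 1", call. = FALSE)
  check_voxel_edge(voxel_edge_um)
  storage.mode(data) <- "double"
  if (is.null(dtype_bits)) {
    dtype_bits <- if (all(data == round(data)) && all(data >= 0)) {
      if (max(data) <= 255) 8L else if (max(data) <= 65535) 16L else 32L
    } else 32L
  }
  if (!dtype_bits %in% c(8L, 16L, 32L))
    stop("`dtype_bits` must be one of 8, 16, 32", call. = FALSE)
  structure(list(data = data, voxel_edge_um = as.numeric(voxel_edge_um),
                 dtype_bits = as.integer(dtype_bits)),
            class = "voxel_volume")
}

#' Binary specimen mask
#'
#' A boolean field on the same `(z, y, x)` grid as its source volume;
#' `TRUE` marks segmented tissue.
#'
#' @param data logical 3D array (numeric 0/1 accepted).
#' @param voxel_edge_um positive voxel edge length in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_edge_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order", call. = FALSE)
  check_voxel_edge(voxel_edge_um)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask data must be logical or 0/1", call. = FALSE)
    data <- array(data != 0, dim = dim(data))
  }
  if (anyNA(data)) stop("mask data must not contain NA", call. = FALSE)
  structure(list(data = data, voxel_edge_um = as.numeric(voxel_edge_um)),
            class = "binary_mask")
}

#' Labeled component mask
#'
#' Integer field where 0 is background and labels `1..n_labels` identify
#' connected specimens, numbered in decreasing voxel-count order.
#'
#' @param data integer 3D array of labels.
#' @param n_labels number of components present.
#' @param voxel_edge_um positive voxel edge length in micrometres.
#' @return An object of class `labeled_mask`.
#' @export
labeled_mask <- function(data, n_labels, voxel_edge_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  check_voxel_edge(voxel_edge_um)
  storage.mode(data) <- "integer"
  n_labels <- as.integer(n_labels)
  if (n_labels < 0L) stop("`n_labels` must be >= 0", call. = FALSE)
  present <- sort(unique(as.integer(data)))
  present <- present[present != 0L]
  if (length(present) != n_labels || (n_labels > 0L &&
      !identical(present, seq_len(n_labels))))
    stop("labels must be exactly 1..n_labels with no gaps", call. = FALSE)
  structure(list(data = data, n_labels = n_labels,
                 voxel_edge_um = as.numeric(voxel_edge_um)),
            class = "labeled_mask")
}

check_voxel_edge <- function(voxel_edge_um) {
  if (!is.numeric(voxel_edge_um) || length(voxel_edge_um) != 1L ||
      !is.finite(voxel_edge_um) || voxel_edge_um <= 0)
    stop("`voxel_edge_um` must be a single positive number", call. = FALSE)
  invisible(TRUE)
}

#' Foreground voxel count of a mask
#' @param mask a `binary_mask`.
#' @return Integer count of foreground voxels.
#' @export
n_foreground <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d (z,y,x), %g um voxels, %d-bit\n",
              d[1], d[2], d[3], x$voxel_edge_um, x$dtype_bits))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d (z,y,x), %g um voxels, %d foreground\n",
              d[1], d[2], d[3], x$voxel_edge_um, sum(x$data)))
  invisible(x)
}

#' @export
print.labeled_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<labeled_mask> %d x %d x %d (z,y,x), %d components\n",
              d[1], d[2], d[3], x$n_labels))
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks. Defined as 1
#' when both masks are empty.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("masks must share a grid", call. = FALSE)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}
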