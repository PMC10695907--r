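#' Structuring elements
#'
#' A structuring element (kernel) is a small 3D boolean neighbourhood with
#' odd edge lengths and a foreground centre. The default for every
#' morphological step in the integrity analysis is the full 3 x 3 x 3
#' cube (27 foreground voxels).
#'
#' @param shape logical 3D array with odd edge lengths; the centre voxel
#'   must be foreground.
#' @param name short label used in reports.
#' @return An object of class `structuring_element`.
#' @export
structuring_element <- function(shape, name = "custom") {
  if (!is.array(shape) || length(dim(shape)) != 3L)
    stop("`shape` must be a 3D array", call. = FALSE)
  if (any(dim(shape) %% 2L == 0L))
    stop("structuring element edge lengths must be odd", call. = FALSE)
  shape <- array(shape != 0, dim = dim(shape))
  ctr <- (dim(shape) + 1L) %/% 2L
  if (!shape[ctr[1], ctr[2], ctr[3]])
    stop("structuring element centre must be foreground", call. = FALSE)
  structure(list(shape = shape, name = name), class = "structuring_element")
}

#' @rdname structuring_element
#' @param size odd cube edge length (default 3).
#' @export
se_cube <- function(size = 3L) {
  structuring_element(array(TRUE, dim = rep(as.integer(size), 3L)),
                      name = sprintf("cube%d", as.integer(size)))
}

#' @rdname structuring_element
#' @details `se_cross()` is the 6-connected cross (7 foreground voxels),
#'   provided for sensitivity analyses.
#' @export
se_cross <- function() {
  a <- array(FALSE, dim = c(3L, 3L, 3L))
  a[2, 2, 2] <- TRUE
  a[c(1, 3), 2, 2] <- TRUE
  a[2, c(1, 3), 2] <- TRUE
  a[2, 2, c(1, 3)] <- TRUE
  structuring_element(a, name = "cross6")
}

se_radius <- function(se) max((dim(se$shape) - 1L) %/% 2L)

apply_morph <- function(mask, se, fn) {
  out <- fn(as.vector(mask$data), dim(mask$data),
            as.vector(se$shape), dim(se$shape))
  binary_mask(array(out, dim = dim(mask$data)), mask$voxel_edge_um)
}

#' Binary dilation and erosion
#'
#' Elementary 3D morphology with an arbitrary structuring element. Voxels
#' outside the grid are background, so erosion can remove foreground at
#' the grid border; use [pad_mask()] for border-safe composites.
#'
#' @param mask a [binary_mask()].
#' @param se a [structuring_element()] (default: 3 x 3 x 3 cube).
#' @return A [binary_mask()] on the same grid.
#' @export
morph_dilate <- function(mask, se = se_cube()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "structuring_element"))
  apply_morph(mask, se, .dilate_cpp)
}

#' @rdname morph_dilate
#' @export
morph_erode <- function(mask, se = se_cube()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "structuring_element"))
  apply_morph(mask, se, .erode_cpp)
}

#' Morphological closing
#'
#' Dilation followed by erosion; with `iterations = n` the mask is dilated
#' n times and then eroded n times. Closing bridges gaps and fills cracks
#' narrower than the structuring element. Border voxels see background
#' outside the grid.
#'
#' @inheritParams morph_dilate
#' @param iterations number of dilation (then erosion) passes, >= 1.
#' @return A [binary_mask()].
#' @export
morph_close <- function(mask, se = se_cube(), iterations = 1L) {
  iterations <- check_iterations(iterations)
  out <- mask
  for (i in seq_len(iterations)) out <- morph_dilate(out, se)
  for (i in seq_len(iterations)) out <- morph_erode(out, se)
  out
}

#' Morphological opening
#'
#' Erosion followed by dilation; removes protrusions thinner than the
#' structuring element (surface smoothing).
#'
#' @inheritParams morph_close
#' @return A [binary_mask()].
#' @export
morph_open <- function(mask, se = se_cube(), iterations = 1L) {
  iterations <- check_iterations(iterations)
  out <- mask
  for (i in seq_len(iterations)) out <- morph_erode(out, se)
  for (i in seq_len(iterations)) out <- morph_dilate(out, se)
  out
}

check_iterations <- function(iterations) {
  iterations <- as.integer(iterations)
  if (length(iterations) != 1L || is.na(iterations) || iterations < 1L)
    stop("`iterations` must be a single integer >= 1", call. = FALSE)
  iterations
}

#' Fill enclosed holes
#'
#' Background components with no path (under `background_connectivity`) to
#' any grid face become foreground; voids open to the exterior are left
#' alone. The default background connectivity of 6 is the standard dual of
#' 26-connected foreground and stops enclosed voids from "leaking" out
#' diagonally.
#'
#' @param mask a [binary_mask()].
#' @param background_connectivity 6 or 26.
#' @return A [binary_mask()].
#' @export
fill_holes <- function(mask, background_connectivity = 6L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!background_connectivity %in% c(6L, 26L))
    stop("`background_connectivity` must be 6 or 26", call. = FALSE)
  out <- .fill_holes_cpp(as.vector(mask$data), dim(mask$data),
                         as.integer(background_connectivity))
  binary_mask(array(out, dim = dim(mask$data)), mask$voxel_edge_um)
}

#' Pad a mask with background on every face
#'
#' Embeds the mask in a larger background grid, so that subsequent
#' morphology treats the original border like any interior region.
#'
#' @param mask a [binary_mask()].
#' @param pad non-negative number of background voxels added on each face.
#' @return A [binary_mask()] of dims `dim + 2 * pad`.
#' @export
pad_mask <- function(mask, pad = 2L) {
  stopifnot(inherits(mask, "binary_mask"))
  pad <- as.integer(pad)
  if (pad < 0L) stop("`pad` must be >= 0", call. = FALSE)
  if (pad == 0L) return(mask)
  d <- dim(mask$data)
  out <- array(FALSE, dim = d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    mask$data
  binary_mask(out, mask$voxel_edge_um)
}

#' @rdname pad_mask
#' @param dims original dims to crop back to.
#' @export
crop_mask <- function(mask, dims, pad = 2L) {
  stopifnot(inherits(mask, "binary_mask"))
  pad <- as.integer(pad)
  binary_mask(mask$data[pad + seq_len(dims[1]), pad + seq_len(dims[2]),
                        pad + seq_len(dims[3]), drop = FALSE],
              mask$voxel_edge_um)
}
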