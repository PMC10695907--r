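#' Segmentation parameters
#'
#' Controls for fixed-band region growing. The intensity band is derived
#' once from the seed neighbourhood and never updated during growth, so
#' the result is deterministic and independent of visit order. The
#' defaults are deliberately conservative: `tolerance_k = 3.5` covers more
#' than 99.9% of Gaussian-distributed tissue intensities, and the
#' component floor of 27 voxels (one kernel volume) removes speckle.
#'
#' @param tolerance_k half-width of the acceptance band in multiples of
#'   the seed-neighbourhood intensity SD (> 0).
#' @param neighborhood_radius radius r of the (2r+1)^3 cube around the
#'   seed used for the band statistics (>= 1).
#' @param connectivity growth/labeling connectivity: 6, 18 or 26.
#' @param min_component_voxels components smaller than this are dropped
#'   when labeling pipeline output (>= 0).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(tolerance_k = 3.5, neighborhood_radius = 2L,
                                connectivity = 26L,
                                min_component_voxels = 27L) {
  if (!is.numeric(tolerance_k) || tolerance_k <= 0)
    stop("`tolerance_k` must be > 0", call. = FALSE)
  neighborhood_radius <- as.integer(neighborhood_radius)
  if (neighborhood_radius < 1L)
    stop("`neighborhood_radius` must be >= 1", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  min_component_voxels <- as.integer(min_component_voxels)
  if (min_component_voxels < 0L)
    stop("`min_component_voxels` must be >= 0", call. = FALSE)
  structure(list(tolerance_k = tolerance_k,
                 neighborhood_radius = neighborhood_radius,
                 connectivity = as.integer(connectivity),
                 min_component_voxels = min_component_voxels),
            class = "segmentation_params")
}

#' Fixed-band region growing
#'
#' Grows a connected region from a seed voxel. The acceptance band is
#' `mean +/- k * sd` of the intensities in the `(2r+1)^3` cube centred on
#' the seed, computed once before growth; a voxel joins the region when it
#' is connected to it and its intensity lies inside the band. The seed
#' voxel itself is always part of the result. If the neighbourhood SD is
#' zero the band degenerates to exact-value matching.
#'
#' @param volume a [voxel_volume()].
#' @param seed integer vector `c(z, y, x)` of 1-based voxel indices.
#' @param params a [segmentation_params()].
#' @return A [binary_mask()] on the volume's grid.
#' @export
region_grow <- function(volume, seed, params = segmentation_params()) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(params, "segmentation_params"))
  d <- dim(volume$data)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed (z, y, x) must lie inside the volume", call. = FALSE)
  r <- params$neighborhood_radius
  if (any(seed - r < 1L) || any(seed + r > d))
    stop("seed neighbourhood of radius ", r,
         " is truncated by the volume border", call. = FALSE)
  nb <- volume$data[(seed[1] - r):(seed[1] + r),
                    (seed[2] - r):(seed[2] + r),
                    (seed[3] - r):(seed[3] + r)]
  mu <- mean(nb)
  sigma <- sd(as.vector(nb))
  band <- c(mu - params$tolerance_k * sigma, mu + params$tolerance_k * sigma)
  out <- .region_grow_cpp(as.vector(volume$data), d, seed - 1L,
                          band[1], band[2], params$connectivity)
  binary_mask(array(out, dim = d), volume$voxel_edge_um)
}

#' Label connected foreground components
#'
#' Components are maximal connected foreground sets under the chosen
#' connectivity, labeled `1..n_labels` in decreasing voxel-count order;
#' ties are broken by the lexicographically smallest `(min z, min y,
#' min x)` of the component.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_voxels drop components smaller than this before labeling.
#' @return A [labeled_mask()].
#' @export
label_components <- function(mask, connectivity = 26L, min_voxels = 0L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  raw <- .label_components_cpp(as.vector(mask$data), dim(mask$data),
                               as.integer(connectivity))
  sizes <- raw$sizes
  keep <- which(sizes >= as.integer(min_voxels))
  ord <- keep[order(-sizes[keep], raw$min_z[keep], raw$min_y[keep],
                    raw$min_x[keep])]
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(ord)
  lab <- integer(length(raw$labels))
  fg <- raw$labels > 0L
  lab[fg] <- relab[raw$labels[fg]]
  labeled_mask(array(as.integer(lab), dim = dim(mask$data)),
               n_labels = length(ord), voxel_edge_um = mask$voxel_edge_um)
}

#' Extract one labeled specimen as a binary mask
#'
#' @param labeled a [labeled_mask()].
#' @param label component label in `1..n_labels`.
#' @return A [binary_mask()] of exactly that component.
#' @export
extract_specimen <- function(labeled, label) {
  stopifnot(inherits(labeled, "labeled_mask"))
  label <- as.integer(label)
  if (length(label) != 1L || label < 1L || label > labeled$n_labels)
    stop("label out of range 1..", labeled$n_labels, call. = FALSE)
  binary_mask(labeled$data == label, labeled$voxel_edge_um)
}
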