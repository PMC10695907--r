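#' Tissue volume of a mask
#'
#' Voxel count times the voxel volume: `n * edge_um^3 * 1e-9` cubic
#' millimetres (at 2 um isotropic voxels, `n * 8e-9` mm^3).
#'
#' @param mask a [binary_mask()].
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * mask$voxel_edge_um^3 * 1e-9
}

# Morphology on a specimen is run on a background-padded copy of the grid
# so that a specimen touching the crop border is not eroded by the image
# edge, and so that "connected to the border" means the true exterior.
integrity_pad <- function(se, iterations) {
  max(2L, se_radius(se) * as.integer(iterations) + 1L)
}

#' Inner tissue integrity
#'
#' Ratio of the segmented tissue volume to its volume after internal
#' rupture filling: the mask is closed (single iteration, 3 x 3 x 3 cube
#' by default) to fill thin cracks, then enclosed holes are filled. The
#' ratio `n_seg / n_filled_inner` is 1 for a specimen with no internal
#' rupture and decreases as internal void volume grows.
#'
#' @param mask non-empty [binary_mask()].
#' @param se structuring element (default 3 x 3 x 3 cube).
#' @param iterations closing iterations (default 1).
#' @param background_connectivity hole-filling background connectivity.
#' @return List with `n_seg`, `n_closed`, `n_filled_inner`,
#'   `inner_integrity`.
#' @export
inner_integrity <- function(mask, se = se_cube(), iterations = 1L,
                            background_connectivity = 6L) {
  stopifnot(inherits(mask, "binary_mask"))
  n_seg <- sum(mask$data)
  if (n_seg == 0L) stop("inner integrity undefined for an empty mask",
                        call. = FALSE)
  pad <- integrity_pad(se, iterations)
  m <- pad_mask(mask, pad)
  closed <- morph_close(m, se, iterations)
  filled <- fill_holes(closed, background_connectivity)
  list(n_seg = n_seg,
       n_closed = sum(closed$data),
       n_filled_inner = sum(filled$data),
       inner_integrity = n_seg / sum(filled$data))
}

#' Outer surface integrity
#'
#' Ratio of the surface-smoothed volume to the hole-filled volume: the raw
#' mask first has enclosed holes filled (so internal cracks cannot enter
#' the surface measure), then is opened (single iteration, 3 x 3 x 3 cube
#' by default) to remove thin protrusions. `n_smoothed / n_filled_outer`
#' is 1 for a smooth, cleanly cut surface and decreases with surface
#' coarseness.
#'
#' @inheritParams inner_integrity
#' @param iterations opening iterations (default 1).
#' @return List with `n_filled_outer`, `n_smoothed`, `outer_integrity`,
#'   `degenerate` (TRUE when opening removed the whole specimen, in which
#'   case the ratio is reported as 0 with a warning).
#' @export
outer_integrity <- function(mask, se = se_cube(), iterations = 1L,
                            background_connectivity = 6L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (sum(mask$data) == 0L)
    stop("outer integrity undefined for an empty mask", call. = FALSE)
  pad <- integrity_pad(se, iterations)
  m <- pad_mask(mask, pad)
  filled <- fill_holes(m, background_connectivity)
  smoothed <- morph_open(filled, se, iterations)
  n_filled <- sum(filled$data)
  n_smoothed <- sum(smoothed$data)
  degenerate <- n_smoothed == 0L
  if (degenerate)
    warning("opening removed the entire specimen; outer integrity = 0",
            call. = FALSE)
  list(n_filled_outer = n_filled, n_smoothed = n_smoothed,
       outer_integrity = n_smoothed / n_filled, degenerate = degenerate)
}

#' Aggregate observer compression scores
#'
#' Each observer rates forceps compression on the ordinal scale 0 (no
#' increased-density region), 1 (one definitive pinching site), 2 (one or
#' two definitive pinching sites with deformation). The consensus is the
#' median across observers; with an even observer count the lower median
#' is taken so the consensus stays an attainable ordinal value. The
#' reference protocol uses three observers.
#'
#' @param scores integer vector of per-observer scores, each in 0..2.
#' @return The aggregated integer score.
#' @export
aggregate_compression <- function(scores) {
  if (length(scores) < 1L) stop("at least one score is required",
                                call. = FALSE)
  if (anyNA(scores) || !all(scores %in% 0:2))
    stop("scores must all be 0, 1 or 2", call. = FALSE)
  s <- sort(as.integer(scores))
  s[ceiling(length(s) / 2)] # lower median for even n
}

#' Per-specimen structural summary
#'
#' Runs the full structural feature set on one segmented specimen: voxel
#' counts at every morphological stage, tissue volume in mm^3, inner and
#' outer integrity ratios, and (when observer scores are supplied) the
#' aggregated compression score.
#'
#' @param mask non-empty [binary_mask()] of one specimen.
#' @param se structuring element used for closing and opening.
#' @param scores optional per-observer compression scores (0..2).
#' @param id,group optional specimen id and group label carried into the
#'   output row.
#' @param iterations morphology iterations (default 1).
#' @param background_connectivity hole-filling background connectivity.
#' @return One-row `data.frame` with columns `id`, `group`, `n_seg`,
#'   `n_closed`, `n_filled_inner`, `n_filled_outer`, `n_smoothed`,
#'   `volume_mm3`, `inner_integrity`, `outer_integrity`,
#'   `compression_score`.
#' @export
summarize_specimen <- function(mask, se = se_cube(), scores = NULL,
                               id = NA_character_, group = NA_character_,
                               iterations = 1L,
                               background_connectivity = 6L) {
  inner <- inner_integrity(mask, se, iterations, background_connectivity)
  outer <- outer_integrity(mask, se, iterations, background_connectivity)
  data.frame(
    id = as.character(id), group = as.character(group),
    n_seg = inner$n_seg, n_closed = inner$n_closed,
    n_filled_inner = inner$n_filled_inner,
    n_filled_outer = outer$n_filled_outer, n_smoothed = outer$n_smoothed,
    volume_mm3 = compute_volume(mask),
    inner_integrity = inner$inner_integrity,
    outer_integrity = outer$outer_integrity,
    compression_score = if (is.null(scores)) NA_integer_ else
      aggregate_compression(scores),
    stringsAsFactors = FALSE)
}
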