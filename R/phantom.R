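#' @title Synthetic biopsy phantoms
#'
#' @description Biopsy-like grayscale phantoms with analytically known
#' ground truth for every measured feature. A phantom is an ellipsoidal
#' tissue body (bright phase) in a dark background, optionally carrying:
#'
#' * ellipsoidal enclosed *voids* (internal rupture, wider than the
#'   morphology kernel),
#' * planar *thin cracks* of 1-2 voxel thickness (closed by a 3x3x3
#'   closing),
#' * 1-voxel-thick axis-aligned surface *spikes* (outer coarseness,
#'   removed by opening),
#' * spherical *pinch* foci of raised intensity (forceps compression;
#'   they alter the grayscale, not the true tissue extent),
#'
#' plus additive Gaussian noise. All defects are rasterised analytically
#' during generation, so ground-truth voxel counts are exact
#' enumerations, not estimates.
#'
#' @name phantoms
NULL

# Scalar field ((i-c)/a)^2 summed over axes; <= 1 inside the ellipsoid.
ellipsoid_field <- function(dims, center, semi_axes) {
  u <- lapply(1:3, function(k) ((seq_len(dims[k]) - center[k]) /
                                  semi_axes[k])^2)
  outer(outer(u[[1]], u[[2]], "+"), u[[3]], "+")
}

ellipsoid_mask <- function(dims, center, semi_axes) {
  ellipsoid_field(dims, center, semi_axes) <= 1
}

#' Specify a synthetic biopsy phantom
#'
#' Validates the geometric and intensity invariants: the body must keep a
#' background margin of at least 3 voxels to every grid face, voids and
#' pinches must lie strictly inside the body, and the tissue/background
#' contrast must be at least six noise SDs so the phantom is segmentable
#' by construction.
#'
#' @param grid_dims three positive integers `(nz, ny, nx)`.
#' @param body list with `center` (z, y, x) and `semi_axes` (voxels).
#' @param voids list of `list(center, semi_axes)` ellipsoidal cavities.
#' @param thin_cracks list of `list(axis, position, thickness, center,
#'   radius, extent_shrink)` planar slits; `axis` is 1 (z), 2 (y) or 3
#'   (x) and `thickness` 1 or 2. The slit is the slab at `position`
#'   intersected with a sphere of `radius` voxels around `center`
#'   (default: unbounded, i.e. the full cross-section) and clipped to
#'   the body shrunk by `extent_shrink` voxels (default 3) so it stays
#'   enclosed.
#' @param spikes list of `list(axis, sign, u, v, length)` 1-voxel-thick
#'   surface rods; `(u, v)` are the in-plane coordinates on the two axes
#'   other than `axis`, in increasing axis order.
#' @param pinches list of `list(center, radius, boost)` spherical
#'   high-density foci.
#' @param tissue_intensity,background_intensity,noise_sd grayscale model.
#' @param voxel_edge_um isotropic voxel edge length (default 2).
#' @param rng_seed integer seed making the noise (and nothing else)
#'   random.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims, body, voids = list(),
                         thin_cracks = list(), spikes = list(),
                         pinches = list(), tissue_intensity = 200,
                         background_intensity = 50, noise_sd = 5,
                         voxel_edge_um = 2, rng_seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L))
    stop("`grid_dims` must be three positive integers", call. = FALSE)
  check_voxel_edge(voxel_edge_um)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (tissue_intensity - background_intensity < 6 * noise_sd)
    stop("contrast invariant violated: tissue_intensity - ",
         "background_intensity must be >= 6 * noise_sd", call. = FALSE)
  if (!is.list(body) || is.null(body$center) || is.null(body$semi_axes))
    stop("`body` needs `center` and `semi_axes`", call. = FALSE)
  if (any(body$semi_axes <= 0))
    stop("body semi-axes must be positive", call. = FALSE)
  lo <- body$center - body$semi_axes
  hi <- body$center + body$semi_axes
  if (any(lo < 4) || any(hi > grid_dims - 3))
    stop("body must keep a >= 3-voxel background margin on all faces",
         call. = FALSE)
  for (v in voids) {
    if (any(v$semi_axes <= 0)) stop("void semi-axes must be positive",
                                    call. = FALSE)
    # strictly inside: the void's bounding box must fit in the body
    # shrunk by 2 voxels along each axis, so the cavity stays enclosed
    if (any(abs(v$center - body$center) + v$semi_axes >
              body$semi_axes - 2))
      stop("voids must lie strictly inside the body (field: voids)",
           call. = FALSE)
  }
  for (p in pinches) {
    if (p$radius <= 0) stop("pinch radius must be positive", call. = FALSE)
    if (any(abs(p$center - body$center) + p$radius > body$semi_axes - 1))
      stop("pinches must lie strictly inside the body (field: pinches)",
           call. = FALSE)
  }
  for (ck in thin_cracks) {
    if (!ck$axis %in% 1:3) stop("crack axis must be 1, 2 or 3",
                                call. = FALSE)
    if (!ck$thickness %in% 1:2)
      stop("crack thickness must be 1 or 2 voxels (field: thin_cracks)",
           call. = FALSE)
  }
  for (s in spikes) {
    if (!s$axis %in% 1:3 || !s$sign %in% c(-1, 1) || s$length < 1)
      stop("spike needs axis in 1..3, sign +/-1, length >= 1 ",
           "(field: spikes)", call. = FALSE)
  }
  structure(list(grid_dims = grid_dims, body = body, voids = voids,
                 thin_cracks = thin_cracks, spikes = spikes,
                 pinches = pinches, tissue_intensity = tissue_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, voxel_edge_um = voxel_edge_um,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Width-based void taxonomy: a cavity survives a 3x3x3 closing iff its
# minimum width is at least 3 voxels; narrower cavities are "thin".
void_is_wide <- function(v) 2 * min(v$semi_axes) >= 3

#' Generate a phantom volume with ground truth
#'
#' Rasterises the spec into (i) a grayscale [voxel_volume()] (background
#' intensity everywhere, tissue intensity on tissue voxels, pinch boosts,
#' then Gaussian noise seeded by `rng_seed`), (ii) the ground-truth
#' [binary_mask()] of the tissue, and (iii) exact truth counts.
#'
#' `expected_inner_integrity` is `T / (T + V_wide)` with `T` the true
#' tissue count and `V_wide` the enclosed void voxels wider than the
#' kernel; `expected_outer_integrity` is `B / (B + S)` with `B` the solid
#' body count and `S` the spike voxels. Thin cracks are expected to be
#' closed by the kernel and are tallied separately
#' (`true_thin_crack_voxels`); they enter the measured inner denominator,
#' so specs aimed at exact inner-integrity recovery use wide voids only.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume`, `truth_mask`, `truth` (named list of
#'   counts and expected ratios) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dims
  body <- ellipsoid_mask(d, spec$body$center, spec$body$semi_axes)
  n_body <- sum(body)

  void_mask <- array(FALSE, dim = d)
  n_wide <- 0L
  for (v in spec$voids) {
    vm <- ellipsoid_mask(d, v$center, v$semi_axes) & body
    vm <- vm & !void_mask
    if (void_is_wide(v)) n_wide <- n_wide + sum(vm)
    void_mask <- void_mask | vm
  }

  crack_mask <- array(FALSE, dim = d)
  for (ck in spec$thin_cracks) {
    shrink <- ck$extent_shrink %||% 3
    core <- ellipsoid_mask(d, spec$body$center,
                           pmax(spec$body$semi_axes - shrink, 1))
    slab <- array(FALSE, dim = d)
    pos <- ck$position:(ck$position + ck$thickness - 1L)
    pos <- pos[pos >= 1L & pos <= d[ck$axis]]
    if (ck$axis == 1L) slab[pos, , ] <- TRUE
    else if (ck$axis == 2L) slab[, pos, ] <- TRUE
    else slab[, , pos] <- TRUE
    reach <- if (is.null(ck$radius)) core else
      core & ellipsoid_mask(d, ck$center, rep(ck$radius, 3))
    crack_mask <- crack_mask | (slab & reach & !void_mask)
  }

  spike_mask <- array(FALSE, dim = d)
  for (s in spec$spikes) {
    rod <- rasterize_spike(body, s)
    if (is.null(rod))
      stop("spike ray misses the body (field: spikes)", call. = FALSE)
    spike_mask[rod] <- TRUE
  }
  spike_mask <- spike_mask & !body

  tissue <- (body & !void_mask & !crack_mask) | spike_mask
  n_tissue <- sum(tissue)
  n_spike <- sum(spike_mask)
  n_crack <- sum(crack_mask)

  gray <- array(spec$background_intensity, dim = d)
  gray[tissue] <- spec$tissue_intensity
  for (p in spec$pinches) {
    pm <- ellipsoid_mask(d, p$center, rep(p$radius, 3)) & tissue
    gray[pm] <- gray[pm] + p$boost
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$rng_seed)
    gray <- gray + array(rnorm(prod(d), 0, spec$noise_sd), dim = d)
  }

  truth <- list(
    true_tissue_voxels = n_tissue,
    true_enclosed_void_voxels = n_wide,
    true_thin_crack_voxels = n_crack,
    true_spike_voxels = n_spike,
    body_solid_voxels = n_body,
    expected_inner_integrity = n_tissue / (n_tissue + n_wide),
    expected_outer_integrity = n_body / (n_body + n_spike),
    expected_outer_integrity_lower_bound =
      n_body / (n_body + n_spike) - 0.005,
    true_volume_mm3 = n_tissue * spec$voxel_edge_um^3 * 1e-9)

  list(volume = voxel_volume(gray, spec$voxel_edge_um, dtype_bits = 32L),
       truth_mask = binary_mask(tissue, spec$voxel_edge_um),
       truth = truth, spec = spec)
}

# Linear indices of a 1-voxel rod grown outward from the body surface
# along +/- one axis at in-plane position (u, v); NULL if the ray misses.
rasterize_spike <- function(body, s) {
  d <- dim(body)
  others <- setdiff(1:3, s$axis)
  line <- switch(s$axis,
                 body[, s$u, s$v], body[s$u, , s$v], body[s$u, s$v, ])
  hits <- which(line)
  if (length(hits) == 0L) return(NULL)
  anchor <- if (s$sign > 0) max(hits) else min(hits)
  pos <- anchor + s$sign * seq_len(s$length)
  pos <- pos[pos >= 1L & pos <= d[s$axis]]
  if (length(pos) < s$length) return(NULL) # rod clipped by the grid
  coord <- matrix(0L, nrow = length(pos), ncol = 3L)
  coord[, s$axis] <- pos
  coord[, others[1]] <- s$u
  coord[, others[2]] <- s$v
  coord[, 1] + (coord[, 2] - 1L) * d[1] + (coord[, 3] - 1L) * d[1] * d[2]
}

#' Seed voxel for segmenting a phantom
#'
#' Deterministically picks a voxel that is guaranteed to lie in clean
#' tissue: candidate points stepping outward from the body centre along
#' the principal axes are screened analytically against the spec's
#' voids, cracks and pinch foci (with a safety margin larger than the
#' seed-statistics neighbourhood), and the first clean candidate wins.
#'
#' @param spec a [phantom_spec()].
#' @param margin clearance (voxels) demanded from every defect and from
#'   the body surface; keep it at least the region-growing
#'   `neighborhood_radius`.
#' @return Integer `(z, y, x)` seed.
#' @export
phantom_seed <- function(spec, margin = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  bc <- spec$body$center
  bs <- spec$body$semi_axes
  clean <- function(pt) {
    # strictly interior to the body, margin-shrunk
    if (sum(((pt - bc) / pmax(bs - margin, 1e-9))^2) > 1) return(FALSE)
    for (v in spec$voids)
      if (sum(((pt - v$center) / (v$semi_axes + margin))^2) <= 1)
        return(FALSE)
    for (p in spec$pinches)
      if (sqrt(sum((pt - p$center)^2)) <= p$radius + margin) return(FALSE)
    for (ck in spec$thin_cracks)
      if (abs(pt[ck$axis] - (ck$position + (ck$thickness - 1) / 2)) <=
            margin + 1) return(FALSE)
    TRUE
  }
  fr <- c(0, -0.2, 0.2, -0.4, 0.4, -0.6, 0.6, -0.8, 0.8)
  cand <- expand.grid(tz = fr, ty = fr, tx = fr)
  cand <- cand[order(cand$tz^2 + cand$ty^2 + cand$tx^2), ]
  for (i in seq_len(nrow(cand))) {
    pt <- round(bc + as.numeric(cand[i, ]) * bs)
    if (clean(pt)) return(as.integer(pt))
  }
  stop("no clean tissue seed found; phantom defects leave no clear ",
       "interior", call. = FALSE)
}
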