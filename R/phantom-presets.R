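#' Phantom spec with calibrated defect fractions
#'
#' Builds a randomised [phantom_spec()] whose defect load hits designed
#' fractions: the enclosed-void fraction `f = V / B` and the spike
#' fraction `s = S / (B + S)`, where `B` is the solid body voxel count,
#' `V` the enclosed void voxels and `S` the spike voxels. Void sizes are
#' found by bisection on a global scale factor of the candidate cavity
#' ellipsoids, so the achieved fraction matches the design to within a
#' few voxels; spike voxel totals are met exactly by adjusting rod
#' lengths. All placement randomness is drawn from `seed`.
#'
#' @param seed integer; drives placements and, offset, the noise.
#' @param body_semi_axes body ellipsoid semi-axes (z, y, x), voxels.
#' @param void_fraction designed enclosed-void fraction of the body
#'   (0 disables voids); all voids are wider than the 3x3x3 kernel.
#' @param n_voids number of cavities (default: scaled to the target).
#' @param spike_fraction designed spike fraction (0 disables spikes).
#' @param spike_length nominal rod length in voxels.
#' @param n_cracks number of thin planar cracks (thickness
#'   `crack_thickness`).
#' @param crack_thickness 1 or 2 voxels.
#' @param pinch_severity 0, 1 or 2; number of high-density foci.
#' @param noise_sd,tissue_intensity,background_intensity grayscale model.
#' @param voxel_edge_um voxel edge length (default 2).
#' @return A [phantom_spec()].
#' @export
calibrated_phantom_spec <- function(seed, body_semi_axes = c(24, 16, 16),
                                    void_fraction = 0, n_voids = NULL,
                                    spike_fraction = 0, spike_length = 7L,
                                    n_cracks = 0L, crack_thickness = 1L,
                                    pinch_severity = 0L, noise_sd = 5,
                                    tissue_intensity = 200,
                                    background_intensity = 50,
                                    voxel_edge_um = 2) {
  stopifnot(void_fraction >= 0, void_fraction < 0.5,
            spike_fraction >= 0, spike_fraction < 0.2)
  set.seed(as.integer(seed))
  margin <- 4L + if (spike_fraction > 0) as.integer(spike_length) + 2L else 0L
  semi <- body_semi_axes
  dims <- as.integer(ceiling(2 * (semi + margin)) + 1)
  center <- (dims + 1) / 2
  body <- ellipsoid_mask(dims, center, semi)
  n_body <- sum(body)

  voids <- list()
  if (void_fraction > 0) {
    target <- round(void_fraction * n_body)
    if (target >= 20) { # below ~20 voxels no kernel-surviving cavity fits
      if (is.null(n_voids))
        n_voids <- max(1L, min(3L, floor(target / 400) + 1L))
      voids <- calibrate_voids(dims, center, semi, n_voids, target)
    }
  }

  cracks <- list()
  if (n_cracks > 0) {
    # crack reach scales with the body so defect load is size-relative
    r_scale <- mean(semi[2:3]) / 16
    for (i in seq_len(n_cracks)) {
      ax <- sample(1:3, 1)
      ck_c <- center + runif(3, -0.35, 0.35) * semi
      ck_c[ax] <- center[ax] + runif(1, -0.3, 0.3) * semi[ax]
      cracks[[i]] <- list(axis = ax,
                          position = as.integer(round(ck_c[ax])),
                          thickness = as.integer(crack_thickness),
                          center = ck_c,
                          radius = runif(1, 4, 7) * r_scale,
                          extent_shrink = 3)
    }
  }

  spikes <- list()
  if (spike_fraction > 0) {
    s_target <- round(spike_fraction / (1 - spike_fraction) * n_body)
    if (s_target >= 3) # below that no meaningful rod can be placed
      spikes <- place_spikes(body, dims, center, semi, s_target,
                             as.integer(spike_length))
  }

  pinches <- list()
  if (pinch_severity > 0) {
    for (i in seq_len(as.integer(pinch_severity))) {
      off <- runif(3, -0.5, 0.5) * pmax(semi - 6, 0)
      pinches[[i]] <- list(center = center + off,
                           radius = 3 * mean(semi[2:3]) / 16, boost = 15)
    }
  }

  phantom_spec(grid_dims = dims,
               body = list(center = center, semi_axes = semi),
               voids = voids, thin_cracks = cracks, spikes = spikes,
               pinches = pinches, tissue_intensity = tissue_intensity,
               background_intensity = background_intensity,
               noise_sd = noise_sd, voxel_edge_um = voxel_edge_um,
               rng_seed = as.integer(seed) + 1000003L)
}

# Candidate cavities spread along the body's long axis; bisection on a
# shared scale factor matches the total rasterised void count to
# `target`. Each cavity keeps a 2-voxel enclosure margin and a minimum
# semi-axis of 1.6 voxels (width >= 3, so it survives the kernel).
calibrate_voids <- function(dims, center, semi, n_voids, target) {
  min_semi <- 1.6
  frac <- if (n_voids == 1) 0 else seq(-0.4, 0.4, length.out = n_voids)
  cand <- lapply(seq_len(n_voids), function(j) {
    off <- c(frac[j] * semi[1], runif(1, -0.25, 0.25) * semi[2],
             runif(1, -0.25, 0.25) * semi[3])
    list(center = center + off, rel = runif(3, 0.8, 1.25))
  })
  count_at <- function(s) {
    acc <- array(FALSE, dim = dims)
    for (v in cand) {
      sa <- pmax(s * v$rel, min_semi)
      acc <- acc | ellipsoid_mask(dims, v$center, sa)
    }
    sum(acc)
  }
  s_max <- min(vapply(cand, function(v)
    min((semi - 2 - abs(v$center - center)) / v$rel), numeric(1)))
  if (s_max < min_semi)
    stop("void target does not fit inside the body", call. = FALSE)
  if (count_at(s_max) < target)
    stop("designed void fraction too large for this body geometry",
         call. = FALSE)
  lo <- min_semi; hi <- s_max
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (count_at(mid) < target) lo <- mid else hi <- mid
  }
  s_star <- if (abs(count_at(lo) - target) < abs(count_at(hi) - target))
    lo else hi
  lapply(cand, function(v)
    list(center = v$center, semi_axes = pmax(s_star * v$rel, min_semi)))
}

# Random surface rods along +/- each axis; same-ray anchors keep a
# Chebyshev spacing of >= 3 so no pair of rods forms a kernel-surviving
# slab. Rod lengths are nudged by +/-1 so the total hits `s_target`.
place_spikes <- function(body, dims, center, semi, s_target, spike_length) {
  n_sp <- max(1L, round(s_target / spike_length))
  lens <- rep(spike_length, n_sp)
  extra <- s_target - n_sp * spike_length
  if (extra != 0) {
    k <- min(abs(extra), n_sp)
    lens[seq_len(k)] <- lens[seq_len(k)] + sign(extra)
    rem <- extra - sign(extra) * k
    lens[1] <- lens[1] + rem # any residual lands on the first rod
  }
  spikes <- list()
  anchors <- list()
  tries <- 0L
  while (length(spikes) < n_sp && tries < 5000L) {
    tries <- tries + 1L
    ax <- sample(1:3, 1)
    sgn <- sample(c(-1L, 1L), 1)
    others <- setdiff(1:3, ax)
    u <- as.integer(round(center[others[1]] +
                            runif(1, -0.7, 0.7) * semi[others[1]]))
    v <- as.integer(round(center[others[2]] +
                            runif(1, -0.7, 0.7) * semi[others[2]]))
    key_ok <- TRUE
    for (a in anchors)
      if (a$axis == ax && a$sign == sgn &&
          max(abs(a$u - u), abs(a$v - v)) < 3L) { key_ok <- FALSE; break }
    if (!key_ok) next
    s <- list(axis = ax, sign = sgn, u = u, v = v,
              length = lens[length(spikes) + 1L])
    if (is.null(rasterize_spike(body, s))) next
    spikes[[length(spikes) + 1L]] <- s
    anchors[[length(anchors) + 1L]] <- s
  }
  if (length(spikes) < n_sp)
    stop("could not place the designed number of spikes", call. = FALSE)
  spikes
}

preset_table <- function() {
  list(
    `CN-like` = list(group = "CN", body_z = c(24, 2), body_r = c(16, 1.2),
                     void_rng = c(0.001, 0.008), spike_rng = c(0, 0.004),
                     crack_p = 0.3, severity_p = c(0.60, 0.35, 0.05),
                     stratum = 0L),
    `B1-like` = list(group = "B1", body_z = c(31, 2.5), body_r = c(19, 1.8),
                     void_rng = c(0.001, 0.008), spike_rng = c(0, 0.004),
                     crack_p = 0.3, severity_p = c(0.60, 0.35, 0.05),
                     stratum = 0L),
    `B2-like` = list(group = "B2", body_z = c(24, 3), body_r = c(16, 2),
                     void_rng = c(0.025, 0.090), spike_rng = c(0.010, 0.022),
                     crack_p = 0.8, severity_p = c(0.05, 0.35, 0.60),
                     stratum = 1L))
}

#' Seed stratum of a cohort preset
#'
#' Presets that share a defect distribution (the control and the
#' B1-like preset) also share a seed stratum: cohorts generated from the
#' same base seed then draw their defect loads from common random
#' numbers, so the designed null contrast between them is null by
#' construction rather than only in distribution. Presets with a
#' distinct defect distribution get their own stratum.
#'
#' @param preset preset name as in [generate_group_cohort()].
#' @return Integer seed offset (multiples of 1000 of the base seed).
#' @export
preset_seed_stratum <- function(preset) {
  presets <- preset_table()
  if (!preset %in% names(presets))
    stop("unknown preset: ", preset, call. = FALSE)
  presets[[preset]]$stratum * 1000L
}

#' Generate a cohort of group-preset phantoms
#'
#' Draws `n_specimens` phantoms from one of three presets designed to
#' mirror the study's group contrasts: `"CN-like"` (control: few small
#' defects), `"B1-like"` (same defect distribution as control but a
#' larger body), and `"B2-like"` (more and larger voids, more surface
#' spikes, higher compression severity). Per-specimen seeds are
#' `base_seed + index`, so cohorts are reproducible element-wise. Each
#' entry also carries three simulated observer compression scores drawn
#' around the specimen's true pinch severity, and a replicate `set_id`
#' cycling 1..3 (mimicking collection in three sets).
#'
#' @param preset `"CN-like"`, `"B1-like"` or `"B2-like"`.
#' @param n_specimens number of phantoms (>= 1).
#' @param base_seed integer; specimen i uses seed `base_seed + i`.
#' @return List of entries: `id`, `group`, `set_id`, `seed`, `spec`,
#'   `volume`, `truth_mask`, `truth`, `scores`.
#' @export
generate_group_cohort <- function(preset, n_specimens, base_seed) {
  presets <- preset_table()
  if (!preset %in% names(presets))
    stop("unknown preset: ", preset, call. = FALSE)
  if (n_specimens < 1L) stop("`n_specimens` must be >= 1", call. = FALSE)
  p <- presets[[preset]]
  if (base_seed < 0 || base_seed + n_specimens > 1e9)
    stop("`base_seed` must lie in [0, 1e9) so derived seeds stay within ",
         "integer range", call. = FALSE)
  lapply(seq_len(n_specimens), function(i) {
    seed <- as.integer(base_seed) + i
    set.seed(seed)
    az <- max(rnorm(1, p$body_z[1], p$body_z[2]), 18)
    ar <- pmax(rnorm(2, p$body_r[1], p$body_r[2]), 12)
    f <- runif(1, p$void_rng[1], p$void_rng[2])
    s <- runif(1, p$spike_rng[1], p$spike_rng[2])
    ncr <- stats::rbinom(1, 2, p$crack_p)
    sev <- sample(0:2, 1, prob = p$severity_p)
    scores <- vapply(1:3, function(o) {
      u <- runif(1)
      shift <- if (u < 0.125) -1L else if (u < 0.25) 1L else 0L
      min(2L, max(0L, sev + shift))
    }, integer(1))
    spec <- calibrated_phantom_spec(
      seed = seed * 2L + 1L, body_semi_axes = c(az, ar[1], ar[2]),
      void_fraction = f, spike_fraction = if (s < 0.0015) 0 else s,
      n_cracks = ncr, pinch_severity = sev)
    ph <- generate_phantom(spec)
    list(id = sprintf("%s_%02d", p$group, i), group = p$group,
         set_id = ((i - 1L) %% 3L) + 1L, seed = seed, spec = spec,
         volume = ph$volume, truth_mask = ph$truth_mask, truth = ph$truth,
         scores = scores)
  })
}
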