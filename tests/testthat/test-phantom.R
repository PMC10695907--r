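test_that("phantom generation is deterministic given its seed", {
  spec <- calibrated_phantom_spec(seed = 9, void_fraction = 0.03,
                                  spike_fraction = 0.01, n_cracks = 1,
                                  pinch_severity = 1)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$truth_mask$data, p2$truth_mask$data)
  expect_identical(p1$truth, p2$truth)
})

test_that("a defect-free noiseless phantom measures as pristine", {
  spec <- calibrated_phantom_spec(seed = 2, noise_sd = 0)
  ph <- generate_phantom(spec)
  m <- region_grow(ph$volume, phantom_seed(spec))
  expect_identical(m$data, ph$truth_mask$data)
  s <- summarize_specimen(m)
  expect_identical(s$inner_integrity, 1)
  # a voxelised ellipsoid is not perfectly open under the cubic kernel;
  # the curvature loss is a handful of voxels out of tens of thousands
  expect_gte(s$outer_integrity, 0.999)
  expect_identical(s$volume_mm3, ph$truth$true_volume_mm3)
})

test_that("truth counts are exact enumerations of the rasterised masks", {
  spec <- calibrated_phantom_spec(seed = 3, void_fraction = 0.05,
                                  spike_fraction = 0.015, n_cracks = 2)
  ph <- generate_phantom(spec)
  expect_identical(ph$truth$true_tissue_voxels, sum(ph$truth_mask$data))
  expect_identical(
    ph$truth$expected_inner_integrity,
    ph$truth$true_tissue_voxels /
      (ph$truth$true_tissue_voxels + ph$truth$true_enclosed_void_voxels))
  expect_identical(
    ph$truth$true_volume_mm3,
    ph$truth$true_tissue_voxels * spec$voxel_edge_um^3 * 1e-9)
})

test_that("void calibration hits the designed fraction closely", {
  for (f in c(0.01, 0.05, 0.10)) {
    spec <- calibrated_phantom_spec(seed = 17, void_fraction = f)
    ph <- generate_phantom(spec)
    achieved <- ph$truth$true_enclosed_void_voxels /
      ph$truth$body_solid_voxels
    expect_lt(abs(achieved - f), 0.002)
  }
})

test_that("ground-truth recovery: wide voids, no surface defects", {
  spec <- calibrated_phantom_spec(seed = 21, void_fraction = 0.06)
  ph <- generate_phantom(spec)
  s <- summarize_specimen(ph$truth_mask)
  # the measured inner ratio equals the designed one exactly on the
  # ground-truth mask, because every void survives closing and is filled
  expect_identical(s$inner_integrity, ph$truth$expected_inner_integrity)
  expect_gte(s$outer_integrity, 0.98)
})

test_that("spec invariants reject impossible phantoms", {
  expect_error(
    phantom_spec(c(20, 20, 20),
                 body = list(center = c(10, 10, 10),
                             semi_axes = c(9, 6, 6))),
    "margin")
  expect_error(
    phantom_spec(c(30, 30, 30),
                 body = list(center = c(15, 15, 15),
                             semi_axes = c(8, 8, 8)),
                 tissue_intensity = 70, background_intensity = 50,
                 noise_sd = 5),
    "contrast")
  expect_error(
    phantom_spec(c(30, 30, 30),
                 body = list(center = c(15, 15, 15),
                             semi_axes = c(8, 8, 8)),
                 voids = list(list(center = c(15, 15, 21),
                                   semi_axes = c(3, 3, 3)))),
    "voids")
  expect_error(
    phantom_spec(c(30, 30, 30),
                 body = list(center = c(15, 15, 15),
                             semi_axes = c(8, 8, 8)),
                 thin_cracks = list(list(axis = 1, position = 15,
                                         thickness = 4))),
    "thin_cracks")
})

test_that("more void volume strictly lowers measured inner integrity", {
  inner <- vapply(c(0.01, 0.03, 0.06, 0.10), function(f) {
    spec <- calibrated_phantom_spec(seed = 31, void_fraction = f)
    ph <- generate_phantom(spec)
    m <- region_grow(ph$volume, phantom_seed(spec))
    summarize_specimen(m)$inner_integrity
  }, numeric(1))
  expect_true(all(diff(inner) < 0))
})

test_that("more spikes strictly lower measured outer integrity", {
  outer <- vapply(c(0.004, 0.01, 0.02), function(s) {
    spec <- calibrated_phantom_spec(seed = 33, spike_fraction = s)
    ph <- generate_phantom(spec)
    m <- region_grow(ph$volume, phantom_seed(spec))
    summarize_specimen(m)$outer_integrity
  }, numeric(1))
  expect_true(all(diff(outer) < 0))
})

test_that("cohort presets separate the groups as designed", {
  cn <- generate_group_cohort("CN-like", 6, 500)
  b2 <- generate_group_cohort("B2-like", 6, 600)
  m_cn <- vapply(cn, function(e) {
    m <- region_grow(e$volume, phantom_seed(e$spec))
    summarize_specimen(m)$inner_integrity
  }, numeric(1))
  m_b2 <- vapply(b2, function(e) {
    m <- region_grow(e$volume, phantom_seed(e$spec))
    summarize_specimen(m)$inner_integrity
  }, numeric(1))
  expect_true(all(m_cn >= 0.97))
  expect_lt(max(m_b2), min(m_cn))
  expect_error(generate_group_cohort("X-like", 3, 1), "unknown preset")
})
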