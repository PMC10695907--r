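cube21 <- function() {
  binary_mask(solid_cuboid(c(31, 31, 31), c(21, 21, 21)), 2)
}

test_that("a defect-free solid yields unit ratios and exact volume", {
  m <- cube21()
  s <- summarize_specimen(m)
  expect_equal(s$n_seg, 9261)
  expect_identical(s$inner_integrity, 1)
  expect_identical(s$outer_integrity, 1)
  expect_identical(s$volume_mm3, 9261 * 8e-9)
})

test_that("volume is count times voxel volume", {
  m <- binary_mask(solid_cuboid(c(102, 102, 102), c(100, 100, 100)), 2)
  expect_identical(compute_volume(m), 0.008)
  e <- binary_mask(array(FALSE, dim = c(3, 3, 3)), 2)
  expect_identical(compute_volume(e), 0)
  m3 <- binary_mask(solid_cuboid(c(6, 6, 6), c(2, 2, 2)), 3.5)
  expect_equal(compute_volume(m3), 8 * 3.5^3 * 1e-9)
})

test_that("a wide internal cavity survives closing and drives inner integrity", {
  a <- solid_cuboid(c(31, 31, 31), c(21, 21, 21))
  a[14:18, 14:18, 14:18] <- FALSE       # centred 5^3 cavity
  inn <- inner_integrity(binary_mask(a, 2))
  expect_equal(inn$n_seg, 9136)
  expect_equal(inn$n_closed, 9136)      # oracle-confirmed: cavity intact
  expect_identical(oracle_close(a, se_cube()$shape), a)
  expect_equal(inn$n_filled_inner, 9261)
  expect_equal(inn$inner_integrity, 9136 / 9261)
})

test_that("a single-voxel void is already repaired by closing", {
  a <- solid_cuboid(c(31, 31, 31), c(21, 21, 21))
  a[16, 16, 16] <- FALSE
  inn <- inner_integrity(binary_mask(a, 2))
  expect_equal(inn$n_closed, 9261)
  expect_true(oracle_close(a, se_cube()$shape)[16, 16, 16])
  expect_equal(inn$inner_integrity, 9260 / 9261)
})

test_that("surface spikes drive outer integrity; the body is preserved", {
  a <- solid_cuboid(c(35, 35, 35), c(21, 21, 21))
  x_max <- max(which(a, arr.ind = TRUE)[, 3])
  a2 <- a
  a2[18, 18, (x_max + 1):(x_max + 6)] <- TRUE  # 6-voxel rod
  out <- outer_integrity(binary_mask(a2, 2))
  expect_equal(out$n_filled_outer, 9267)
  expect_equal(out$n_smoothed, 9261)
  expect_identical(oracle_open(a2, se_cube()$shape), a)
  expect_equal(out$outer_integrity, 9261 / 9267)
  expect_false(out$degenerate)
})

test_that("a discrete sphere opens nearly cleanly", {
  s <- bioptiq:::ellipsoid_mask(c(21, 21, 21), c(11, 11, 11), c(8, 8, 8))
  out <- outer_integrity(binary_mask(s, 2))
  expect_lt(out$outer_integrity, 1)
  expect_gte(out$outer_integrity, 0.95)
})

test_that("degenerate opening reports zero with a warning flag", {
  a <- array(FALSE, dim = c(7, 7, 7)); a[4, 4, 3:5] <- TRUE
  expect_warning(out <- outer_integrity(binary_mask(a, 2)), "removed")
  expect_equal(out$outer_integrity, 0)
  expect_true(out$degenerate)
})

test_that("empty masks are rejected by the integrity measures", {
  e <- binary_mask(array(FALSE, dim = c(5, 5, 5)), 2)
  expect_error(inner_integrity(e), "empty")
  expect_error(outer_integrity(e), "empty")
})

test_that("compression scores aggregate to the (lower) median", {
  expect_identical(aggregate_compression(c(0, 1, 1)), 1L)
  expect_identical(aggregate_compression(c(2, 2, 0)), 2L)
  expect_identical(aggregate_compression(c(1, 2)), 1L)
  expect_identical(aggregate_compression(c(2)), 2L)
  expect_error(aggregate_compression(integer(0)), "at least one")
  expect_error(aggregate_compression(c(0, 3)), "0, 1 or 2")
})

test_that("the specimen summary composes the individual measures", {
  a <- solid_cuboid(c(35, 35, 35), c(21, 21, 21))
  a[14:18, 14:18, 14:18] <- FALSE
  x_max <- max(which(a, arr.ind = TRUE)[, 3])
  a[18, 20, (x_max + 1):(x_max + 6)] <- TRUE
  s <- summarize_specimen(binary_mask(a, 2), scores = c(1, 1, 2),
                          id = "sp1", group = "B1")
  expect_equal(s$inner_integrity, s$n_seg / s$n_filled_inner)
  expect_equal(s$outer_integrity, s$n_smoothed / s$n_filled_outer)
  expect_gte(s$n_closed, s$n_seg)
  expect_gte(s$n_filled_inner, s$n_closed)
  expect_lte(s$n_smoothed, s$n_filled_outer)
  expect_identical(s$compression_score, 1L)
  expect_identical(s$volume_mm3, s$n_seg * 8e-9)
  expect_identical(s$id, "sp1")
})

test_that("integrity ratios stay in (0, 1] on random generator specimens", {
  set.seed(2024)
  draws <- data.frame(f = runif(5, 0, 0.08), s = runif(5, 0.005, 0.02))
  for (seed in 1:5) {
    spec <- calibrated_phantom_spec(seed = seed,
                                    void_fraction = draws$f[seed],
                                    spike_fraction = draws$s[seed])
    ph <- generate_phantom(spec)
    s <- summarize_specimen(ph$truth_mask)
    expect_true(s$inner_integrity > 0 && s$inner_integrity <= 1)
    expect_true(s$outer_integrity > 0 && s$outer_integrity <= 1)
  }
})
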