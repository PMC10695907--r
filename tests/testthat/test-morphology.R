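mk <- function(a) binary_mask(a, 2)

test_that("closing and opening leave a solid interior cuboid unchanged", {
  cube <- mk(solid_cuboid(c(15, 15, 15), c(9, 9, 9)))
  expect_identical(morph_close(cube)$data, cube$data)
  expect_identical(morph_open(cube)$data, cube$data)
})

test_that("closing bridges a 1-voxel gap between nearby points", {
  a <- array(FALSE, dim = c(9, 9, 9))
  a[5, 5, 4] <- a[5, 5, 6] <- TRUE
  closed <- morph_close(mk(a))
  expect_true(closed$data[5, 5, 5])
  expect_identical(closed$data, oracle_close(a, se_cube()$shape))
})

test_that("opening removes thin protrusions and isolated voxels", {
  a <- solid_cuboid(c(21, 21, 21), c(9, 9, 9))
  spike <- which(a, arr.ind = TRUE)
  x_max <- max(spike[, 3])
  a2 <- a
  a2[11, 11, (x_max + 1):(x_max + 4)] <- TRUE   # 4-voxel rod on a face
  opened <- morph_open(mk(a2))
  expect_identical(opened$data, a)
  expect_equal(sum(a2) - sum(opened$data), 4)

  single <- array(FALSE, dim = c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(sum(morph_open(mk(single))$data), 0)
})

test_that("empty masks are fixed points of closing and opening", {
  e <- mk(array(FALSE, dim = c(6, 6, 6)))
  expect_identical(morph_close(e)$data, e$data)
  expect_identical(morph_open(e)$data, e$data)
})

test_that("hole filling restores enclosed voids but not open channels", {
  a <- solid_cuboid(c(9, 9, 9), c(5, 5, 5))
  a[5, 5, 5] <- FALSE                 # single enclosed void
  expect_equal(sum(a), 124)
  filled <- fill_holes(mk(a))
  expect_equal(sum(filled$data), 125)
  expect_true(filled$data[5, 5, 5])

  # 1-voxel channel from the cavity to the exterior: not filled
  b <- solid_cuboid(c(9, 9, 9), c(5, 5, 5), offset = c(2L, 2L, 2L))
  b[5, 5, 5] <- FALSE
  b[5, 5, 6:9] <- FALSE               # channel along +x to the border
  expect_identical(fill_holes(mk(b))$data, b)
})

test_that("kernels match the brute-force oracle on random masks", {
  set.seed(301)
  ses <- list(cube = se_cube(), cross = se_cross())
  for (i in 1:12) {
    a <- random_mask_arr(c(12, 12, 12), p = runif(1, 0.2, 0.7))
    se <- ses[[(i %% 2) + 1]]
    expect_identical(morph_dilate(mk(a), se)$data, oracle_dilate(a, se$shape))
    expect_identical(morph_erode(mk(a), se)$data, oracle_erode(a, se$shape))
    expect_identical(fill_holes(mk(a), 6L)$data, oracle_fill(a, 6))
    expect_identical(fill_holes(mk(a), 26L)$data, oracle_fill(a, 26))
  }
})

test_that("closing/filling are extensive, opening anti-extensive, all idempotent", {
  # interior masks (3-voxel clear border), as in the integrity pipeline,
  # where the classical lattice properties hold exactly
  set.seed(302)
  for (i in 1:200) {
    a <- array(FALSE, dim = c(16, 16, 16))
    a[4:13, 4:13, 4:13] <- random_mask_arr(c(10, 10, 10),
                                           p = runif(1, 0.1, 0.9))
    m <- mk(a)
    cl <- morph_close(m); op <- morph_open(m); fi <- fill_holes(m)
    expect_true(all(cl$data[a]))          # closing never removes
    expect_true(all(fi$data[a]))          # filling never removes
    expect_true(!any(op$data[!a]))        # opening never adds
    if (i <= 40) {                        # idempotence spot-checked
      expect_identical(morph_close(cl)$data, cl$data)
      expect_identical(morph_open(op)$data, op$data)
      expect_identical(fill_holes(fi)$data, fi$data)
    }
  }
})

test_that("multi-iteration closing dilates n times before eroding n times", {
  set.seed(303)
  a <- random_mask_arr(c(10, 10, 10), p = 0.3)
  se <- se_cube()$shape
  want <- oracle_erode(oracle_erode(oracle_dilate(oracle_dilate(a, se), se),
                                    se), se)
  expect_identical(morph_close(mk(a), iterations = 2L)$data, want)
  expect_error(morph_close(mk(a), iterations = 0), "iterations")
})

test_that("padding shields border-touching objects from closing erosion", {
  a <- array(TRUE, dim = c(4, 4, 4))    # fills the whole grid
  shrunk <- morph_close(mk(a))          # border erosion bites
  expect_lt(sum(shrunk$data), sum(a))
  padded <- crop_mask(morph_close(pad_mask(mk(a), 2)), dim(a), 2)
  expect_identical(padded$data, a)
})
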