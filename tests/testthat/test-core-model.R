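# Geometry containers, trilinear sampling and landmark IO.

test_that("scalar_grid enforces its invariants", {
  expect_error(scalar_grid(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(scalar_grid(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(scalar_grid(1:7, size = c(2, 2, 2)), "prod")
  g <- scalar_grid(array(1:8, c(2, 2, 2)), unit_tag = "HU")
  expect_identical(g$size, c(2L, 2L, 2L))
  expect_identical(g$unit_tag, "HU")
})

test_that("resample is exact on its own geometry and on constants", {
  g <- scalar_grid(array(rnorm(5^3), c(5, 5, 5)), origin = c(-3, 1, 2),
                   spacing = c(1.5, 2, 2.5))
  expect_identical(resample(g, geometry_of(g))$values, g$values)
  const <- scalar_grid(array(7, c(6, 6, 6)), spacing = c(2, 2, 2))
  tg <- grid_geometry(c(1, 1, 1), c(1.3, 1.1, 0.7), c(5, 5, 5))
  expect_true(all(abs(resample(const, tg)$values - 7) < 1e-12))
  expect_error(resample(const, tg, fill = NaN), "finite")
})

test_that("trilinear interpolation matches the closed form on a ramp", {
  r <- ramp_grid(n = 6, spacing = 2)
  # midway between voxel centers at x = 2 and x = 4
  expect_equal(interp_trilinear(r$values, r, matrix(c(3, 4, 4), 1)), 3)
  # general point: f(x) = x everywhere inside
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 10), runif(50, 0, 10))
  expect_equal(interp_trilinear(r$values, r, pts), pts[, 1], tolerance = 1e-12)
})

test_that("resampled values never overshoot the source range", {
  set.seed(7)
  g <- scalar_grid(array(rnorm(6^3), c(6, 6, 6)))
  tg <- grid_geometry(c(-1, -1, -1), c(0.83, 1.21, 0.64), c(9, 9, 9))
  out <- resample(g, tg, fill = 0)
  expect_gte(min(out$values), min(min(g$values), 0))
  expect_lte(max(out$values), max(max(g$values), 0))
})

test_that("sample_vector interpolates componentwise and is zero outside", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5))
  zf <- zero_field(g)
  expect_identical(sample_vector(zf, c(2, 2, 2)), matrix(0, 1, 3))
  cf <- vector_field(array(1, g$size), array(2, g$size), array(3, g$size))
  expect_equal(sample_vector(cf, c(2.2, 1.7, 3.1)), matrix(c(1, 2, 3), 1))
  expect_equal(sample_vector(cf, c(50, 0, 0)), matrix(0, 1, 3))
  # linear field d_x = 0.1 * x sampled at x = 5
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(8, 8, 8))
  pts <- voxel_centers(g)
  lf <- vector_field(array(0.1 * pts[, 1], g$size), array(0, g$size),
                     array(0, g$size))
  expect_equal(sample_vector(lf, c(5, 2, 2))[1, 1], 0.5 * 1 / 1 * 1)
  expect_equal(sample_vector(lf, c(3.5, 2, 2))[1, 1], 0.35)
})

test_that("sample_vector agrees with direct per-voxel lookup at centers", {
  set.seed(11)
  g <- grid_geometry(c(-4, 2, 0), c(2, 1.5, 2.5), c(4, 4, 4))
  f <- vector_field(array(rnorm(64), g$size), array(rnorm(64), g$size),
                    array(rnorm(64), g$size), g$origin, g$spacing)
  pts <- voxel_centers(g)
  got <- sample_vector(f, pts)
  expect_equal(got[, 1], as.vector(f$dx), tolerance = 1e-12)
  expect_equal(got[, 2], as.vector(f$dy), tolerance = 1e-12)
  expect_equal(got[, 3], as.vector(f$dz), tolerance = 1e-12)
})

test_that("landmark files convert voxel indices to world mm", {
  fa <- withr::local_tempfile(fileext = ".txt")
  fb <- withr::local_tempfile(fileext = ".txt")
  geom <- grid_geometry(c(0, 0, 0), c(1, 1, 2.5), c(20, 20, 20))

  writeLines(c("10 10 10"), fa); writeLines(c("10 10 10"), fb)
  lm <- read_landmarks(fa, fb, geom)
  expect_equal(lm$n, 1)
  expect_equal(unname(lm$points_fixed - lm$points_moving), matrix(0, 1, 3))

  # hand computation: indices (0,0,0) vs (0,0,4) with 1-based convention
  writeLines("0 0 0", fa); writeLines("0 0 4", fb)
  lm <- read_landmarks(fa, fb, geom, index_base = 0)
  expect_equal(sqrt(sum((lm$points_fixed - lm$points_moving)^2)), 10)
  # 1-based default shifts both by one voxel, distance unchanged
  writeLines("1 1 1", fa); writeLines("1 1 5", fb)
  lm1 <- read_landmarks(fa, fb, geom, index_base = 1)
  expect_equal(sqrt(sum((lm1$points_fixed - lm1$points_moving)^2)), 10)
  expect_equal(unname(lm1$points_fixed[1, ]), c(0, 0, 0))

  writeLines(c("1 1 1", "2 2 2", "3 3 3"), fa); writeLines(c("1 1 1", "2 2 2"), fb)
  expect_error(read_landmarks(fa, fb, geom), "3.*2")
  writeLines(c("1 1 1", "2 x 2"), fa); writeLines(c("1 1 1", "2 2 2"), fb)
  expect_error(read_landmarks(fa, fb, geom), "line 2")
})

test_that("landmark round trip through files preserves voxel positions", {
  geom <- grid_geometry(c(-10, -10, -10), c(2, 2, 2), c(16, 16, 16))
  pts <- voxel_centers(geom)[c(5, 100, 200), ]
  f <- withr::local_tempfile(fileext = ".txt")
  write_landmarks(pts, f, geom)
  lm <- read_landmarks(f, f, geom)
  expect_equal(unname(lm$points_fixed), unname(pts))
})

test_that("volume IO round-trips values and geometry", {
  g <- scalar_grid(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                   origin = c(-10, 5, 2.5), spacing = c(2, 2.5, 3),
                   unit_tag = "HU")
  for (ext in c(".mha", ".mhd", ".nii")) {
    f <- withr::local_tempfile(fileext = ext)
    write_volume(g, f)
    r <- read_volume(f, unit_tag = "HU")
    expect_equal(r$origin, g$origin, tolerance = 1e-12, info = ext)
    expect_equal(r$spacing, g$spacing, tolerance = 1e-12, info = ext)
    expect_equal(r$values, g$values, tolerance = 1e-12, info = ext)
  }
  # MetaImage geometry is bit-exact
  f <- withr::local_tempfile(fileext = ".mha")
  write_volume(g, f)
  r <- read_volume(f)
  expect_identical(r$origin, g$origin)
  expect_identical(r$spacing, g$spacing)
})

test_that("vector fields round-trip as 3-channel MetaImage", {
  g <- grid_geometry(c(0, -2, 1), c(1.5, 2, 2.5), c(4, 4, 4))
  f <- vector_field(array(rnorm(64), g$size), array(rnorm(64), g$size),
                    array(rnorm(64), g$size), g$origin, g$spacing,
                    domain = "ct", codomain = "cbct")
  p <- withr::local_tempfile(fileext = ".mha")
  write_field(f, p)
  r <- read_field(p, "ct", "cbct")
  expect_identical(r$dx, f$dx)
  expect_identical(r$dy, f$dy)
  expect_identical(r$dz, f$dz)
  expect_identical(r$origin, f$origin)
})

test_that("fov_region tests points correctly for cylinders and boxes", {
  cyl <- fov_region("cylinder", center = c(0, 0, 0), diameter = 10)
  expect_true(fov_contains(cyl, c(4.9, 0, 100)))
  expect_false(fov_contains(cyl, c(5.1, 0, 0)))
  box <- fov_region("box", center = c(0, 0, 0), extents = c(10, 10, 10))
  expect_true(all(fov_contains(box, rbind(c(5, 5, 5), c(-5, 0, 0)))))
  expect_false(fov_contains(box, c(0, 0, 5.01)))
  expect_error(fov_region("cylinder", diameter = -1), "diameter")
})
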