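# Stand-in dose engine and the warping/accumulation chain.

water_slab <- function() {
  scalar_grid(array(0, c(24, 24, 40)), origin = c(-34.5, -34.5, -58.5),
              spacing = c(3, 3, 3), unit_tag = "HU")
}

test_that("depth dose in water is exponential with slope -mu", {
  slab <- water_slab()
  bm <- beam_spec(isocenter = c(0, 0, 0), direction = c(0, 0, 1),
                  field_size = c(50, 50), sad = 1000, mu = 0.005)
  D <- compute_dose(slab, bm)
  z <- -58.5 + (0:39) * 3
  prof <- D$values[12, 12, ]
  d <- 1000 + z                       # source sits at z = -1000
  y <- log(prof * (d / 1000)^2)       # divide out the inverse square
  fit <- lm(y ~ z)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_equal(unname(coef(fit)[2]), -0.005, tolerance = 0.02)
})

test_that("beam edge cases behave as specified", {
  slab <- water_slab()
  bm0 <- beam_spec(weight = 0)
  D <- compute_dose(slab, list(bm0))
  expect_true(all(D$values == 0))
  expect_error(compute_dose(slab, list()), "at least one beam")
  inside <- beam_spec(isocenter = c(0, 0, 0), direction = c(0, 0, 1), sad = 10)
  expect_error(compute_dose(slab, inside), "inside")
  expect_error(beam_spec(direction = c(0, 0, 0)), "non-zero")
  expect_error(beam_spec(weight = -1), ">= 0")
})

test_that("parallel-opposed beams give a symmetric dose", {
  slab <- water_slab()
  beams <- list(beam_spec(isocenter = c(0, 0, -1.5), direction = c(0, 0, 1)),
                beam_spec(isocenter = c(0, 0, -1.5), direction = c(0, 0, -1)))
  D <- compute_dose(slab, beams)
  prof <- D$values[12, 12, ]
  # mirror about the midplane between voxels 20 and 21
  expect_equal(prof, rev(prof), tolerance = 0.01 * max(prof))
})

test_that("warp_dose is exact for identity and preserves translated maxima", {
  ph <- get_phantom32()
  g <- geometry_of(ph$ct4d$phases[[1]])
  bm <- default_phantom_beams(coarse_spec())
  D <- compute_dose(ph$ct4d$phases[[1]], bm)
  expect_identical(warp_dose(D, NULL)$values, D$values)

  z <- array(0, g$size)
  tr <- vector_field(z, z, array(7.5, g$size), g$origin, g$spacing)
  W <- warp_dose(D, tr)
  expect_equal(max(W$values), max(D$values), tolerance = 0.01 * max(D$values))
  expect_gte(min(W$values), 0)

  # warp by a smooth field and then its inverse recovers the dose
  ph48 <- get_phantom48()
  D48 <- compute_dose(ph48$ct4d$phases[[1]],
                      default_phantom_beams(phantom_spec(size = c(48, 48, 48),
                                                         spacing = c(3, 3, 3))))
  f <- ph48$dvf_to_ref[[6]]
  b <- invert_dvf(f, geometry_of(f), tol_mm = 0.05)
  back <- warp_dose(warp_dose(D48, f), b)
  core <- ph48$rois$gtv$grid$values > 0.5
  expect_lt(mean(abs(back$values - D48$values)[core]), 0.1 * max(D48$values))
})

test_that("integral dose is preserved under interior rigid translation", {
  ph <- get_phantom32()
  bm <- default_phantom_beams(coarse_spec())
  D <- compute_dose(ph$ct4d$phases[[1]], bm)
  g <- geometry_of(D)
  z <- array(0, g$size)
  tr <- vector_field(z, z, array(10, g$size), g$origin, g$spacing)
  W <- warp_dose(D, tr)
  expect_lt(abs(integral_dose(W) - integral_dose(D)) / integral_dose(D), 0.02)
})

test_that("accumulate_4d is a weighted warped sum with unit-weight guard", {
  ph <- get_phantom32()
  bm <- default_phantom_beams(coarse_spec())
  D <- compute_dose(ph$ct4d$phases[[1]], bm)
  same <- replicate(10, D, simplify = FALSE)
  acc <- accumulate_4d(same, NULL)
  expect_equal(acc$values, D$values, tolerance = 1e-12)

  zero <- dose_grid(scalar_grid(array(0, D$size), D$origin, D$spacing,
                                unit_tag = "Gy"))
  one_hot <- c(list(D), replicate(9, zero, simplify = FALSE))
  acc1 <- accumulate_4d(one_hot, NULL)
  expect_equal(acc1$values, D$values / 10, tolerance = 1e-12)

  expect_error(accumulate_4d(same, NULL, weights = rep(0.2, 10)), "sum to 1")
  # linearity in each phase dose
  acc2 <- accumulate_4d(lapply(same, function(d) {
    d$values <- d$values * 2; d
  }), NULL)
  expect_equal(acc2$values, 2 * acc$values, tolerance = 1e-12)
})

test_that("motion-compensated accumulation outperforms the extreme phase", {
  ph <- get_phantom32()
  # each phase dose conforms to that phase's anatomy (tight aperture on the
  # instantaneous tumor). Evaluating a displaced phase directly on the
  # reference GTV, with no warping, then under-covers it; warping every
  # phase dose back before summing recovers the coverage
  doses <- lapply(1:10, function(p) {
    s <- (1 - cos(2 * pi * (p - 1) / 10)) / 2
    iso <- c(32, 0, -10 + 8 * s)
    compute_dose(ph$ct4d$phases[[p]],
                 list(beam_spec(isocenter = iso, direction = c(0, 1, 0),
                                field_size = c(26, 26)),
                      beam_spec(isocenter = iso, direction = c(1, 0, 0),
                                field_size = c(26, 26))))
  })
  acc <- accumulate_4d(doses, ph$dvf_to_ref)
  d99_acc <- dvh_metrics(acc, ph$rois$gtv)$value[1]
  d99_extremes <- vapply(c(5, 6, 7), function(p)
    dvh_metrics(doses[[p]], ph$rois$gtv)$value[1], 0)
  expect_gte(d99_acc, max(d99_extremes))
})

test_that("course accumulation sums through the replan chain", {
  ph <- get_phantom32()
  bm <- default_phantom_beams(coarse_spec())
  D <- compute_dose(ph$ct4d$phases[[1]], bm)
  g <- geometry_of(D)

  acc <- accumulate_course(replicate(4, D, simplify = FALSE))
  expect_equal(acc$values, 4 * D$values, tolerance = 1e-12)
  expect_identical(acc$provenance, "cumulative")

  one <- accumulate_course(list(D))
  expect_equal(one$values, D$values, tolerance = 1e-12)

  # two-plan chain with translation links: net shift composes
  z <- array(0, g$size)
  t1 <- vector_field(z, z, array(5, g$size), g$origin, g$spacing)
  chain <- plan_chain(c("pre", "replan"),
                      as.Date(c("2018-10-01", "2018-10-05")),
                      list(NULL, t1))
  acc2 <- accumulate_course(list(D, D),
                            dates = as.Date(c("2018-10-02", "2018-10-06")),
                            chain = chain)
  # fraction 1 passes through unwarped; fraction 2 is pulled by +5 mm
  manual <- D$values + warp_dose(D, t1)$values
  expect_equal(acc2$values, manual, tolerance = 1e-12)

  expect_error(accumulate_course(list(D), dates = as.Date("2018-09-01"),
                                 chain = chain), "predates")
})

test_that("three-plan translation chains compose like a single map", {
  g <- grid_geometry(c(-30, -30, -30), c(4, 4, 4), c(16, 16, 16))
  set.seed(2)
  vals <- gauss_smooth(array(runif(16^3), g$size), 8, g$spacing)
  D <- dose_grid(scalar_grid(vals, g$origin, g$spacing, unit_tag = "Gy"))
  z <- array(0, g$size)
  t1 <- vector_field(array(3, g$size), z, z, g$origin, g$spacing)
  t2 <- vector_field(z, z, array(-4, g$size), g$origin, g$spacing)
  chain <- plan_chain(c("a", "b", "c"),
                      as.Date(c("2018-01-01", "2018-02-01", "2018-03-01")),
                      list(NULL, t1, t2))
  acc <- accumulate_course(list(D), dates = as.Date("2018-03-02"),
                           chain = chain)
  # composition oracle: single warp by the composed map x -> x + t2 + t1
  comp <- vector_field(array(3, g$size), z, array(-4, g$size),
                       g$origin, g$spacing)
  direct <- warp_dose(D, comp)
  core <- as.vector(slice.index(vals, 1) %in% 4:13 &
                    slice.index(vals, 3) %in% 4:13)
  expect_equal(acc$values[array(core, g$size)], direct$values[array(core, g$size)],
               tolerance = 0.05 * max(vals))
})
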