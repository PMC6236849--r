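# TRE, contour agreement and DVH metrics.

test_that("TRE without a field is the raw pair distance", {
  p <- matrix(rnorm(30), 10, 3)
  lm <- landmark_set(p, p)
  r <- compute_tre(lm)
  expect_equal(r$mean_mm, 0)
  expect_equal(r$n, 10)

  q <- p; q[, 3] <- q[, 3] + 4
  r2 <- compute_tre(landmark_set(p, q))
  expect_equal(r2$mean_mm, 4)
  expect_equal(r2$sd_mm, 0)
})

test_that("pooled TRE over several sets matches a brute-force oracle", {
  set.seed(31)
  sets <- lapply(c(5, 9, 17), function(n) {
    a <- matrix(rnorm(3 * n, sd = 20), n, 3)
    landmark_set(a, a + matrix(rnorm(3 * n, sd = 3), n, 3))
  })
  r <- compute_tre(sets)
  all_err <- unlist(lapply(sets, function(s)
    sapply(seq_len(s$n), function(i)
      sqrt(sum((s$points_fixed[i, ] - s$points_moving[i, ])^2)))))
  expect_equal(r$mean_mm, mean(all_err))
  expect_equal(r$sd_mm, sd(all_err))
  expect_equal(r$n, 31)
  expect_equal(nrow(r$per_set), 3)
  expect_equal(r$per_set$mean_mm[2],
               mean(all_err[6:14]))
})

test_that("the exact generating field drives phantom TRE below half a voxel", {
  ph <- get_phantom32()
  r <- compute_tre(ph$landmarks[2:10], ph$dvf_to_ref[[2]])
  # one field for all sets is wrong on purpose; per-phase use:
  for (p in c(3, 6, 9)) {
    r <- compute_tre(ph$landmarks[[p]], ph$dvf_to_ref[[p]])
    expect_lt(r$mean_mm, 0.5 * 5)
  }
})

test_that("contour metrics match brute-force counts and flag strictly", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(20, 20, 20))
  cube <- function(x0) {
    m <- array(0, g$size)
    m[x0:(x0 + 9), 1:10, 1:10] <- 1
    roi_mask(scalar_grid(m, g$origin, g$spacing, unit_tag = "binary"),
             "cube", "target")
  }
  a <- cube(1)
  expect_error(contour_metrics(
    roi_mask(scalar_grid(array(0, g$size), unit_tag = "binary"), "e", "OAR",
             allow_empty = TRUE),
    roi_mask(scalar_grid(array(0, g$size), unit_tag = "binary"), "e", "OAR",
             allow_empty = TRUE)), "empty")

  same <- contour_metrics(a, a)
  expect_equal(same$dice, 1)
  expect_equal(same$msd_mm, 0)
  expect_false(same$volume_flag || same$com_flag)

  b <- cube(6)   # overlap half the volume
  half <- contour_metrics(a, b)
  expect_equal(half$dice, 2 * 500 / 2000)  # exhaustive count: 500 shared
  expect_equal(half$com_shift_mm, 5)
  expect_true(half$com_flag)               # 5 mm > 3 mm
  expect_equal(half$volume_change, 0)
  expect_false(half$volume_flag)

  # DICE and MSD are symmetric
  rev <- contour_metrics(b, a)
  expect_equal(rev$dice, half$dice)
  expect_equal(rev$msd_mm, half$msd_mm)
})

test_that("volume and COM flags trip strictly above threshold", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(30, 30, 12))
  mk <- function(nx) {
    m <- array(0, g$size); m[1:nx, 1:10, 1:10] <- 1
    roi_mask(scalar_grid(m, g$origin, g$spacing, unit_tag = "binary"),
             "r", "target")
  }
  a <- mk(20)                       # 2000 voxels
  expect_false(contour_metrics(a, mk(21))$volume_flag)  # +5%
  expect_false(contour_metrics(a, mk(22))$volume_flag)  # +10% exactly: not >
  expect_true(contour_metrics(a, mk(23))$volume_flag)   # +15%
  # fractional volumes via voxel counts: 9% and 10.1%
  g2 <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(1200, 3, 3))
  row <- function(n) {
    m <- array(0, g2$size); m[seq_len(n), 1, 1] <- 1
    roi_mask(scalar_grid(m, g2$origin, g2$spacing, unit_tag = "binary"),
             "row", "target")
  }
  expect_false(contour_metrics(row(1000), row(1090))$volume_flag)  # +9%
  expect_true(contour_metrics(row(1000), row(1101))$volume_flag)   # +10.1%

  # COM boundary: masks displaced by 2.9 vs 3.1 mm along x on a finer grid
  g3 <- grid_geometry(c(0, 0, 0), c(0.1, 1, 1), c(400, 12, 12))
  blk <- function(i0) {
    m <- array(0, g3$size); m[i0:(i0 + 99), 1:10, 1:10] <- 1
    roi_mask(scalar_grid(m, g3$origin, g3$spacing, unit_tag = "binary"),
             "b", "target")
  }
  expect_false(contour_metrics(blk(1), blk(30))$com_flag)  # 2.9 mm
  expect_true(contour_metrics(blk(1), blk(32))$com_flag)   # 3.1 mm
})

test_that("DVH metrics reproduce closed forms and respect ordering", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(10, 10, 10))
  roi <- roi_mask(scalar_grid(array(1, g$size), g$origin, g$spacing,
                              unit_tag = "binary"), "all", "target")
  uni <- dose_grid(scalar_grid(array(50, g$size), g$origin, g$spacing,
                               unit_tag = "Gy"))
  m <- dvh_metrics(uni, roi, v_levels_gy = 20)
  vals <- setNames(m$value, m$metric)
  expect_equal(unname(vals[c("D99", "D95", "D90", "max", "mean")]),
               rep(50, 5))
  expect_equal(unname(vals["V20"]), 100)

  # SI ramp 0 -> 100 Gy: D90 = 10 Gy, V20 = 80%
  pts <- voxel_centers(g)
  ramp <- dose_grid(scalar_grid(array(pts[, 3] / 18 * 100, g$size),
                                g$origin, g$spacing, unit_tag = "Gy"))
  mr <- dvh_metrics(ramp, roi, v_levels_gy = 20)
  vr <- setNames(mr$value, mr$metric)
  expect_equal(unname(vr["D90"]), 10, tolerance = 100 / 9 / 2)  # one voxel
  expect_equal(unname(vr["V20"]), 80, tolerance = 10)
  expect_lte(vr["D99"], vr["D95"])
  expect_lte(vr["D95"], vr["D90"])

  # percent-of-plan formula
  plan <- dose_grid(scalar_grid(array(100, g$size), g$origin, g$spacing,
                                unit_tag = "Gy"))
  tx <- dose_grid(scalar_grid(array(96.5, g$size), g$origin, g$spacing,
                              unit_tag = "Gy"))
  mp <- dvh_metrics(tx, roi, plan_dose = plan)
  expect_equal(mp$percent[mp$metric == "D99"], 96.5)
  expect_equal(mp$delta_percent[mp$metric == "D99"], -3.5)

  expect_error(dvh_metrics(uni, roi_mask(
    scalar_grid(array(0, g$size), g$origin, g$spacing, unit_tag = "binary"),
    "none", "OAR", allow_empty = TRUE)), "empty")
})

test_that("D_q agrees exactly with the full-sort oracle on random grids", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(3:12, 3, replace = TRUE)
    g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), n)
    d <- dose_grid(scalar_grid(array(rexp(prod(n), 1 / 30), n),
                               g$origin, g$spacing, unit_tag = "Gy"))
    m <- array(as.double(runif(prod(n)) < 0.6), n)
    if (sum(m) < 2) next
    roi <- roi_mask(scalar_grid(m, g$origin, g$spacing, unit_tag = "binary"),
                    "rand", "target")
    got <- dvh_metrics(d, roi, d_levels = c(99, 95, 90, 50),
                       v_levels_gy = c(10, 30))
    vals <- setNames(got$value, got$metric)
    sel <- d$values[m > 0.5]
    for (q in c(99, 95, 90, 50))
      expect_equal(unname(vals[paste0("D", q)]), oracle_dq(sel, q),
                   tolerance = 1e-12)
    for (x in c(10, 30))
      expect_equal(unname(vals[paste0("V", x)]), 100 * mean(sel >= x))
    expect_equal(unname(vals["max"]), max(sel))
  }
})

test_that("course reports collapse to zero deltas for a plan-identical fraction", {
  ph <- get_phantom32()
  bm <- default_phantom_beams(coarse_spec())
  D <- compute_dose(ph$ct4d$phases[[1]], bm)
  rep1 <- course_report(D, list(D), NULL, rois = list(gtv = ph$rois$gtv))
  cum <- dplyr::filter(rep1, fraction == "cumulative", plan > 0)
  expect_true(all(abs(cum$delta_percent) < 1e-9))
  empty <- course_report(D, list(D), NULL, rois = list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("fraction", "roi", "metric", "value") %in% names(empty)))
})
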