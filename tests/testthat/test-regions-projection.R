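test_that("region construction normalises and validates", {
  r <- gbm_region(c(0, 0), angle_deg = 30)
  expect_lt(abs(sqrt(sum(r$normal^2)) - 1), 1e-9)
  expect_lt(max(abs(r$normal - c(cos(pi / 6), sin(pi / 6)))), 1e-9)
  expect_error(gbm_region(c(0, 0), normal = c(0, 0)), "nonzero")
  expect_error(gbm_region(c(0, 0), angle_deg = 0, width = -1))
})

test_that("selection places non-overlapping outward windows", {
  tr <- gbm_ground_truth(mid_radius = 2000)
  regs <- select_regions(tr, 8, width = 800)
  expect_equal(length(regs), 8L)
  for (r in regs) {
    # outward normal: points away from the loop centre
    expect_gt(sum(r$normal * r$center), 0)
    expect_equal(r$curvature, 1 / 2000)
  }
  # adjacent windows have positive tangential separation
  # (arc pitch 2*pi*2000/15 = 838 nm > 800 nm width)
  pitch <- 2 * pi * 2000 / 15
  expect_gt(pitch, 800)
  # capacity bound: floor(2*pi*2000/800) = 15
  expect_error(select_regions(tr, 16, width = 800), "maximum is 15")
})

test_that("region files round trip", {
  regs <- list(gbm_region(c(100, 200), angle_deg = 30, id = "a"),
               gbm_region(c(-50, 75), angle_deg = 120, width = 600,
                          depth = 1200, id = "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_regions(regs, path)
  back <- read_regions(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$center, c(100, 200))
  expect_lt(max(abs(back[[1]]$normal - c(cos(pi / 6), sin(pi / 6)))), 1e-9)
  expect_equal(back[[2]]$depth, 1200)
  writeLines("id,center_x_nm", path)
  expect_error(read_regions(path), "missing column")
})

test_that("flat projection uses the signed normal and half-open window", {
  reg <- gbm_region(c(1000, 500), angle_deg = 90, width = 800, depth = 600,
                    id = "r1")
  # at the centre, and at centre + 68.9 nm along the normal
  tab <- loc_table(c(1000, 1000, 1000), c(500, 568.9, 431.1))
  pr <- project_region(tab, reg, "test")
  expect_equal(sort(pr$positions), c(-68.9, 0, 68.9))
  # histogram counts sum to the number of positions; 0 is a bin centre
  expect_equal(sum(pr$counts), pr$n)
  expect_true(0 %in% pr$centers)

  # boundary convention: tangential and axial upper bounds are excluded.
  # With normal (0,1) the tangent is (-1,0), so x = center + 400 maps to
  # tangential -400 (included) and x = center - 400 to +400 (excluded);
  # axial +300 (= +depth/2) is excluded too.
  edge <- loc_table(c(1000 + 400, 1000 - 400, 1000), c(500, 500, 800))
  pre <- project_region(edge, reg, "test")
  expect_equal(pre$n, 1L)
  expect_lt(abs(pre$positions), 1e-9)
})

test_that("window membership matches a brute-force check", {
  set.seed(31)
  reg <- gbm_region(c(200, -100), angle_deg = 35, width = 800, depth = 600)
  n <- 2000
  tab <- loc_table(runif(n, -800, 1200), runif(n, -1100, 900))
  pr <- project_region(tab, reg, "test")
  a <- 35 * pi / 180
  nr <- c(cos(a), sin(a))
  tg <- c(-sin(a), cos(a))
  inside <- vapply(seq_len(n), function(i) {
    d <- c(tab$x[i] - 200, tab$y[i] + 100)
    t1 <- sum(d * tg)
    a1 <- sum(d * nr)
    t1 >= -400 && t1 < 400 && a1 >= -300 && a1 < 300
  }, logical(1))
  expect_equal(pr$n, sum(inside))
  d <- cbind(tab$x[inside] - 200, tab$y[inside] + 100)
  expect_equal(sort(pr$positions), sort(as.numeric(d %*% nr)))
})

test_that("curved projection measures radially and reduces to flat", {
  # loop of radius 2000 centred at the origin; window at angle 0
  reg <- gbm_region(c(2000, 0), angle_deg = 0, width = 800, depth = 600,
                    curvature = 1 / 2000)
  th <- seq(-0.15, 0.15, length.out = 41)
  tab <- loc_table(2068.9 * cos(th), 2068.9 * sin(th))
  pr <- project_region(tab, reg, "test")
  expect_equal(pr$n, 41L)
  expect_true(all(abs(pr$positions - 68.9) < 1e-9))
  # arc-length window: theta = width/2/r is excluded, just inside kept
  lim <- 400 / 2000
  edge <- loc_table(2000 * cos(c(lim, lim - 1e-6)),
                    2000 * sin(c(lim, lim - 1e-6)))
  expect_equal(project_region(edge, reg, "test")$n, 1L)
  # curvature -> 0 agrees with the flat window for central points
  flat <- gbm_region(c(2000, 0), angle_deg = 0, width = 800, depth = 600)
  near <- loc_table(c(2010, 1990), c(5, -5))
  expect_equal(sort(project_region(near, flat, "test")$positions),
               sort(c(10, -10)))
  curved <- project_region(near, reg, "test")
  # radial distances of (2010, 5) and (1990, -5) from the r = 2000 circle
  expect_equal(sort(curved$positions),
               sort(c(sqrt(2010^2 + 25) - 2000, sqrt(1990^2 + 25) - 2000)),
               tolerance = 1e-12)
})

test_that("profile shifting preserves counts and re-bins", {
  pr <- flat_profile(c(-50, -40, 60, 70))
  sh <- shift_profile(pr, -10)
  expect_equal(sort(sh$positions), c(-60, -50, 50, 60))
  expect_equal(sum(sh$counts), 4)
})
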