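test_that("a zero-radius tip with no artifacts reproduces the ideal raster", {
  pop <- population_preset("wt", n_molecules = 3, molecules_per_field = 3,
                           seed = 9)
  out <- generate_population(pop, clean_scan())
  f <- out$fields[[1]]
  expect_identical(f$topograph$heights, f$ideal)
})

test_that("tip dilation equals the brute-force neighbourhood-max oracle", {
  set.seed(8)
  px <- 2.0
  # smooth random surface
  h <- matrix(0, 64, 64)
  for (k in 1:8) {
    r0 <- sample(10:54, 1); c0 <- sample(10:54, 1)
    hgt <- runif(1, 0.5, 3)
    rad <- runif(1, 3, 10)
    for (di in -6:6) for (dj in -6:6) {
      rr <- r0 + di; cc <- c0 + dj
      d <- sqrt(di^2 + dj^2) * px
      if (d < rad) h[rr, cc] <- max(h[rr, cc], hgt * sqrt(1 - (d / rad)^2))
    }
  }
  for (R in c(0, 2, 3, 5)) {
    expect_equal(tip_dilate(h, px, R), dilate_oracle(h, px, R),
                 tolerance = 0)
  }
  # and on a rendered molecule field
  pop <- population_preset("wt", n_molecules = 1, molecules_per_field = 1,
                           seed = 13)
  sc <- clean_scan(resolution_px = 64L, field_size_nm = 150)
  ideal <- generate_population(pop, sc)$fields[[1]]$ideal
  expect_equal(tip_dilate(ideal, pixel_size(sc), 3),
               dilate_oracle(ideal, pixel_size(sc), 3), tolerance = 0)
})

test_that("tip dilation preserves peak heights and broadens widths", {
  px <- 1.0
  h <- matrix(0, 41, 41)
  for (i in 1:41) for (j in 1:41) {
    d <- sqrt((i - 21)^2 + (j - 21)^2) * px
    if (d < 6) h[i, j] <- 3 * sqrt(1 - (d / 6)^2)
  }
  fwhm <- function(m) sum(m[21, ] >= max(m) / 2)
  d2 <- tip_dilate(h, px, 2)
  d5 <- tip_dilate(h, px, 5)
  expect_equal(max(d2), max(h))
  expect_equal(max(d5), max(h))
  expect_gt(fwhm(d5), fwhm(d2))
  expect_gte(fwhm(d2), fwhm(h))
  expect_error(tip_dilate(h, px, -1), ">= 0")
})

test_that("placement flags borders and rejects far-out geometries", {
  pop <- population_preset("wt", n_molecules = 40, molecules_per_field = 40,
                           seed = 17)
  out <- generate_population(pop, clean_scan())
  expect_true(any(out$truth$touches_border))

  # geometry beyond twice the field errors out
  sc <- clean_scan(resolution_px = 64L, field_size_nm = 150)
  geom <- list(polylines = list(list(
    xy = cbind(x = c(400, 450), y = c(400, 450)), role = "stalk",
    height = 1.5)), disks = list())
  expect_error(render_topograph(list(geom), sc), "twice the field")
})
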