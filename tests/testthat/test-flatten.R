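test_that("flattening removes row and column offsets exactly", {
  # constants are their own medians
  tp <- topograph(matrix(5, 4, 4), 2)
  expect_equal(flatten(tp)$heights, matrix(0, 4, 4))

  # per-row offsets are the row medians
  tp <- topograph(matrix(rep(0:3, each = 4), 4, 4, byrow = TRUE), 2)
  expect_equal(flatten(tp)$heights, matrix(0, 4, 4))

  # additive row-offset + column-offset field flattens to zero
  set.seed(7)
  ro <- rnorm(16); co <- rnorm(16)
  tp <- topograph(outer(ro, rep(1, 16)) + outer(rep(1, 16), co), 1)
  expect_equal(flatten(tp)$heights, matrix(0, 16, 16), tolerance = 1e-12)
})

test_that("flatten matches an independently coded two-pass loop oracle", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(8:32, 1); m <- sample(8:32, 1)
    h <- matrix(sample.int(100, n * m, replace = TRUE), n, m)
    got <- flatten(topograph(h + 0.0, 1))$heights
    expect_equal(got, flatten_oracle(h + 0.0), tolerance = 0)
  }
})

test_that("flattening invariants hold", {
  set.seed(1)
  h <- matrix(rnorm(30 * 40), 30, 40)
  f1 <- flatten(topograph(h, 1.5))

  # every column median of the output is exactly 0
  expect_equal(max(abs(apply(f1$heights, 2, median))), 0)

  # idempotence where the pass leaves nothing to remove: an additive
  # row+column offset field flattens to zero, and zero is a fixed point
  ro <- rnorm(24); co <- rnorm(24)
  add <- flatten(topograph(outer(ro, rep(1, 24)) +
                             outer(rep(1, 24), co), 1.5))
  expect_equal(add$heights, matrix(0, 24, 24), tolerance = 1e-12)
  expect_equal(flatten(topograph(add$heights, 1.5))$heights, add$heights,
               tolerance = 1e-12)

  # translation invariance
  fshift <- flatten(topograph(h + 17.3, 1.5))
  expect_equal(fshift$heights, f1$heights, tolerance = 1e-9)

  # pixel size and provenance
  expect_equal(f1$pixel_size_nm, 1.5)
  expect_identical(f1$provenance, "flattened")
  expect_error(flatten(f1), "raw")
})

test_that("non-finite heights are rejected with offending indices", {
  h <- matrix(0, 4, 4); h[2, 3] <- NaN
  expect_error(topograph(h, 1), "\\(2,3\\)")
})
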