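test_that("stiff-limit chains are straight and construction is exact", {
  set.seed(1)
  b <- sample_backbone(100, 1e9, 2)
  expect_equal(nrow(b), 51L)
  ee <- sqrt(sum((b[nrow(b), ] - b[1, ])^2))
  expect_lt(abs(ee - 100), 2 + 1e-9)

  # segment lengths sum to the contour length
  seg <- sqrt(rowSums(diff(b)^2))
  expect_equal(sum(seg), 100, tolerance = 1e-9)

  # non-multiple contour keeps total within one step
  b2 <- sample_backbone(101.3, 50, 2)
  expect_equal(sum(sqrt(rowSums(diff(b2)^2))), 101.3, tolerance = 1e-9)
})

test_that("mean squared end-to-end distance matches the closed form", {
  set.seed(99)
  n_rep <- 2000
  r2 <- replicate(n_rep, {
    b <- sample_backbone(150, 50, 2)
    sum((b[nrow(b), ] - b[1, ])^2)
  })
  expected <- wlc_mean_sq_end_to_end(150, 50, 2)
  # Monte-Carlo standard error of the mean is ~2% here; assert within 5%
  expect_lt(abs(mean(r2) / expected - 1), 0.05)
})

test_that("invalid worm-like-chain parameters are rejected", {
  expect_error(sample_backbone(-5, 50, 1), "positive")
  expect_error(sample_backbone(100, 0, 1), "positive")
  expect_error(sample_backbone(100, 50, 20), "step")
})
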