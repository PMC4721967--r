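test_that("splay fraction statistics count ends correctly", {
  sf <- splay_fraction_stats(c("rod", "rod", "rod"))
  expect_equal(sf$fraction, c(0, 0))

  sf1 <- splay_fraction_stats("splay-both+bubble")
  expect_equal(sf1$fraction, c(1, 1))

  sf2 <- splay_fraction_stats(c("rod", "splay-N", "splay-C+bubble",
                                "splay-both"))
  expect_equal(sf2$fraction, c(3 / 4, 1 / 4))
  expect_true(all(sf2$ci_lo <= sf2$fraction & sf2$fraction <= sf2$ci_hi))
  expect_error(splay_fraction_stats(character(0)), "empty")
})

test_that("the independent-ends model links the two splay fractions", {
  # calibrating p to the printed 38% both-ends fraction predicts 85%
  expect_equal(independent_ends_check(0.38), 0.8528, tolerance = 1e-4)
  expect_equal(round(100 * independent_ends_check(0.38)), 85)
  expect_equal(independent_ends_check(0), 0)
  expect_equal(independent_ends_check(1), 1)
  expect_error(independent_ends_check(1.2), "\\[0, 1\\]")
})

test_that("predicted lengths and shortfalls reproduce the printed values", {
  expect_equal(predicted_length(889), 132.0165, tolerance = 1e-6)
  expect_equal(percent_shortfall(91.2, predicted_length(889)), 30.9,
               tolerance = 0.05)
  expect_equal(percent_shortfall(100, 100), 0)
  # full length vs the predicted minimum
  expect_equal(percent_shortfall(145, 204), 28.9, tolerance = 0.05)
  expect_error(percent_shortfall(10, 0), "positive")
  expect_error(predicted_length(-1), "positive")

  tab <- shortfall_table(c(`1_889` = 91.2, full = 145))
  expect_equal(tab$shortfall_pct[tab$construct == "1_889"], 30.9,
               tolerance = 0.05)
})

test_that("group comparison is a two-tailed Welch test with conventions", {
  expect_equal(compare_groups(c(1, 1, 1), c(1, 1))$p, 1)
  set.seed(6)
  a <- rnorm(100, 27, 5); b <- rnorm(100, 17, 5)
  cg <- compare_groups(a, b)
  expect_lt(cg$p, 1e-4)
  # swapping groups flips t and keeps p
  cg2 <- compare_groups(b, a)
  expect_equal(cg2$p, cg$p)
  expect_equal(cg2$t, -cg$t)
  # matches the reference implementation
  ref <- t.test(a, b)
  expect_equal(cg$t, unname(ref$statistic))
  expect_equal(cg$p, ref$p.value)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("population summaries conserve counts and order", {
  s <- summarize_population(c(1, 2, 3), "demo", bin_width = 1)
  expect_equal(s$mean, 2)
  expect_equal(s$ecdf_f, c(1, 2, 3) / 3)
  expect_equal(sum(s$counts), 3L)

  set.seed(2)
  v <- rnorm(137, 140, 20)
  for (bw in c(5, 10, 25)) {
    expect_equal(sum(summarize_population(v, bin_width = bw)$counts), 137L)
  }
  ov <- ecdf_overlay(list(a = v, b = v + 5))
  expect_true(all(ov$cum_fraction > 0 & ov$cum_fraction <= 1))
  expect_false(is.unsorted(ov$value[ov$group == "a"]))

  expect_lt(ks_distance(v, v), 1e-12)
  expect_gt(ks_distance(v, v + 50), 0.5)
})
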