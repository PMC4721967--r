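xs_of <- function(...) {
  xs <- stats::setNames(numeric(8), paste0("X", 1:8))
  args <- list(...)
  xs[names(args)] <- unlist(args)
  xs
}

test_that("bubble size and total length follow the printed formulas", {
  expect_equal(bubble_size(xs_of(X4 = 30, X5 = 24)), 27)
  expect_equal(bubble_size(xs_of(X4 = 17, X5 = 17)), 17)
  expect_equal(bubble_size(xs_of()), 0)

  expect_equal(total_length(xs_of(X3 = 145)), 145)
  expect_equal(total_length(xs_of(X1 = 20, X2 = 20, X3 = 40, X4 = 30,
                                  X5 = 24, X6 = 50, X7 = 10, X8 = 10)), 147)

  # linearity: scaling every segment scales both metrics
  xs <- xs_of(X1 = 12, X2 = 9, X3 = 50, X4 = 28, X5 = 24, X6 = 40,
              X7 = 14, X8 = 11)
  expect_equal(bubble_size(xs * 3), 3 * bubble_size(xs))
  expect_equal(total_length(xs * 3), 3 * total_length(xs))
})

test_that("normalized splay-to-splay distance hits its geometric limits", {
  t <- seq(0, 145, length.out = 200)
  rod <- shape_anatomy(cbind(x = 200 + t, y = 300))
  expect_lt(abs(normalized_splay_distance(rod) - 1), 0.02)

  R <- 145 / pi
  th <- seq(0, pi, length.out = 300)
  semi <- shape_anatomy(cbind(x = 300 + R * cos(th), y = 300 + R * sin(th)))
  expect_lt(abs(normalized_splay_distance(semi) - 2 / pi), 0.03)

  hairpin <- rbind(
    cbind(x = seq(300, 230, length.out = 100), y = 300),
    cbind(x = 230 + 2.5 * cos(seq(pi / 2, 3 * pi / 2, length.out = 20)),
          y = 297.5 + 2.5 * sin(seq(pi / 2, 3 * pi / 2, length.out = 20))),
    cbind(x = seq(230, 300, length.out = 100), y = 295))
  hp <- shape_anatomy(hairpin)
  expect_lt(abs(normalized_splay_distance(hp) - 5 / 140), 0.01)

  # scale invariance: the same shape at twice the physical scale
  rod2 <- shape_anatomy(cbind(x = 150 + 2 * t, y = 300))
  expect_lt(abs(normalized_splay_distance(rod2) -
                 normalized_splay_distance(rod)), 0.02)
})

test_that("relative bubble positions recover the generated span", {
  pop <- population_preset("wt", n_molecules = 1, molecules_per_field = 1,
                           seed = 2, splay_prob_per_end = 0, bubble_prob = 1,
                           persistence_length_nm = 1e4)
  sim <- generate_population(pop, clean_scan())
  res <- suppressWarnings(analyze_population(sim))
  m <- res$metrics
  expect_equal(nrow(m), 1L)
  expect_true(m$has_bubble)
  expect_lte(m$rel_begin, m$rel_center)
  expect_lte(m$rel_center, m$rel_end)
  tc <- (m$true_bubble_start_rel + m$true_bubble_end_rel) / 2
  err <- min(abs(m$rel_center - tc), abs((1 - m$rel_center) - tc))
  expect_lt(err, 0.04)
})

test_that("conformation classes enumerate the three binary features", {
  expect_identical(class_label(FALSE, FALSE, FALSE), "rod")
  expect_identical(class_label(TRUE, FALSE, FALSE), "splay-N")
  expect_identical(class_label(FALSE, TRUE, TRUE), "splay-C+bubble")
  expect_identical(class_label(TRUE, TRUE, TRUE), "splay-both+bubble")
  combos <- expand.grid(n = c(TRUE, FALSE), c = c(TRUE, FALSE),
                        b = c(TRUE, FALSE))
  expect_length(unique(class_label(combos$n, combos$c, combos$b)), 8L)
})
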