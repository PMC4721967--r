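test_that("population generation is deterministic for a fixed seed", {
  pop <- population_preset("wt", n_molecules = 6, molecules_per_field = 3,
                           seed = 7)
  sc <- clean_scan()
  a <- generate_population(pop, sc)
  b <- generate_population(pop, sc)
  expect_identical(a$truth, b$truth)
  expect_identical(a$fields[[1]]$topograph$heights,
                   b$fields[[1]]$topograph$heights)
})

test_that("an empty population yields an empty table and background field", {
  pop <- population_preset("wt", n_molecules = 0, seed = 1)
  sc <- clean_scan(resolution_px = 64L, field_size_nm = 150)
  out <- generate_population(pop, sc)
  expect_equal(nrow(out$truth), 0L)
  expect_equal(max(out$fields[[1]]$ideal), 0)
})

test_that("presets encode the documented study contrasts", {
  wt <- population_preset("wt")
  dh <- population_preset("dhinge")
  nd <- population_preset("noDTT")
  expect_equal(wt$bubble_prob, 0.5)
  expect_equal(dh$bubble_prob, 0.2)
  expect_equal(wt$bubble_strand_length_mean_nm, 27)
  expect_equal(dh$bubble_strand_length_mean_nm, 17)
  expect_lt(dh$bubble_strand_length_sd_nm, wt$bubble_strand_length_sd_nm)
  expect_lt(dh$contour_length_mean_nm, wt$contour_length_mean_nm)
  expect_gt(dh$persistence_length_nm, wt$persistence_length_nm)
  # the non-reducing preset is rod-like: few splays, few bubbles, stiff
  expect_lt(nd$splay_prob_per_end, 0.1)
  expect_lt(nd$bubble_prob, 0.1)
  expect_gt(nd$persistence_length_nm, 1e3)
  # unshared fields are identical between wt and dhinge
  same <- setdiff(names(unclass(wt)),
                  c("contour_length_mean_nm", "contour_length_sd_nm",
                    "persistence_length_nm", "bubble_prob",
                    "bubble_strand_length_mean_nm",
                    "bubble_strand_length_sd_nm"))
  expect_identical(unclass(wt)[same], unclass(dh)[same])
})

test_that("splay incidence follows the per-end binomial model", {
  pop <- population_preset("wt", seed = 1)
  set.seed(123)
  draws <- replicate(1000, {
    d <- tethermorph:::draw_molecule(pop)
    sum(d$splay_n, d$splay_c)
  })
  frac_ge1 <- mean(draws >= 1)
  ci <- binom.test(sum(draws >= 1), length(draws))$conf.int
  expect_true(ci[1] <= 0.853 && 0.853 <= ci[2])
})

test_that("molecule geometry conserves the contour length", {
  # arms only: a bubble deliberately trades removed span for strand arc
  # length (strands are longer than the span they replace)
  pop <- population_preset("wt", n_molecules = 20, seed = 5,
                           bubble_prob = 0)
  sc <- clean_scan()
  px <- pixel_size(sc)
  set.seed(5)
  for (i in 1:20) {
    set.seed(tethermorph:::molecule_seed(pop$seed, i))
    d <- tethermorph:::draw_molecule(pop)
    bb <- sample_backbone(d$contour_length_nm, pop$persistence_length_nm,
                          min(px, d$contour_length_nm / 12))
    mf <- add_features(bb, d, pop, sc)
    lens <- vapply(mf$geometry$polylines, function(p)
      tethermorph:::polyline_arclength(p$xy), numeric(1))
    roles <- vapply(mf$geometry$polylines, function(p) p$role, character(1))
    tot <- sum(lens[grepl("stalk", roles)]) +
      sum(lens[grepl("arm-N", roles)]) / 2 +
      sum(lens[grepl("arm-C", roles)]) / 2 +
      sum(lens[grepl("bubble", roles)]) / 2
    expect_lt(abs(tot - d$contour_length_nm), 2 * px + 1e-9)
  }
})

test_that("degenerate and pass-through feature draws behave as documented", {
  pop <- population_preset("wt", seed = 2, splay_prob_per_end = 0,
                           bubble_prob = 0)
  set.seed(11)
  d <- tethermorph:::draw_molecule(pop)
  bb <- sample_backbone(d$contour_length_nm, pop$persistence_length_nm, 2)
  mf <- add_features(bb, d, pop, clean_scan())
  roles <- vapply(mf$geometry$polylines, function(p) p$role, character(1))
  expect_identical(roles, "stalk")
  expect_identical(mf$truth$class_label, "rod")
  expect_false(mf$truth$has_bubble)

  # bubble strand lengths pass through to the ground truth
  pop2 <- population_preset("wt", seed = 2, splay_prob_per_end = 0,
                            bubble_prob = 1)
  set.seed(12)
  d2 <- tethermorph:::draw_molecule(pop2)
  d2$strand_lengths <- c(30, 26)
  bb2 <- sample_backbone(145, 1e4, 2)
  mf2 <- add_features(bb2, d2, pop2, clean_scan())
  expect_equal(mf2$truth$bubble_strand1_nm, 30)
  expect_equal(mf2$truth$bubble_strand2_nm, 26)
  expect_lt(mf2$truth$bubble_start_rel, mf2$truth$bubble_end_rel)

  expect_error(add_features(matrix(0, 1, 2), d2, pop2, clean_scan()),
               "backbone")
})

test_that("the antibody disk sits at the requested backbone fraction", {
  pop <- population_preset("wt", seed = 3, splay_prob_per_end = 0,
                           bubble_prob = 0, antibody_label_rel = 0.48)
  set.seed(21)
  d <- tethermorph:::draw_molecule(pop)
  bb <- sample_backbone(d$contour_length_nm, 1e4, 2)
  sc <- clean_scan()
  mf <- add_features(bb, d, pop, sc)
  roles <- vapply(mf$geometry$disks, function(dd) dd$role, character(1))
  ab <- mf$geometry$disks[[which(roles == "antibody")]]
  target <- tethermorph:::polyline_point_at(bb,
                                            0.48 * d$contour_length_nm)$point
  expect_lt(sqrt(sum((ab$center - target)^2)),
            sc$antibody_offset_nm + 1e-9)
  expect_equal(mf$truth$label_rel, 0.48)
})
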