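test_that("the taller terminal cap defines the N end", {
  sc <- clean_scan()
  t <- seq(0, 120, length.out = 200)
  rod <- cbind(x = 220 + t, y = 300)
  geom <- list(
    polylines = list(list(xy = rod, role = "stalk", height = 1.5)),
    disks = list(list(center = c(220, 300), radius = 3, height = 2.5,
                      role = "gfp"),
                 list(center = c(340, 300), radius = 2.2, height = 2.0,
                      role = "grip")))
  out <- render_topograph(list(geom), sc)
  fl <- topograph(out$topograph$heights, pixel_size(sc),
                  provenance = "flattened")
  obj <- detect_objects(fl)
  an <- identify_features(skeletonize_molecule(
    obj$mask[[which.max(obj$area_px)]], fl))
  expect_identical(an$status, "ok")
  expect_false(an$ambiguous)
  # N anchor is the left (GFP) end
  nd <- an$graph$nodes
  n_col <- nd$col[an$ends[[1]]$anchor]
  c_col <- nd$col[an$ends[[2]]$anchor]
  expect_lt(n_col, c_col)
  expect_gt(an$ends[[1]]$cap_h, an$ends[[2]]$cap_h)
})

test_that("segment measurement recovers known bubble strand lengths", {
  pop <- population_preset("wt", seed = 2, splay_prob_per_end = 0,
                           bubble_prob = 1)
  sc <- clean_scan()
  set.seed(12)
  d <- tethermorph:::draw_molecule(pop)
  # generator-typical strand asymmetry; strongly asymmetric bubbles bias
  # the short strand low (see the methods vignette's limitations)
  d$strand_lengths <- c(28.5, 27.5)
  bb <- sample_backbone(145, 1e4, 2, start = c(150, 250))
  mf <- add_features(bb, d, pop, sc)
  out <- render_topograph(list(mf$geometry), sc)
  fl <- topograph(out$topograph$heights, pixel_size(sc),
                  provenance = "flattened")
  obj <- detect_objects(fl)
  an <- identify_features(skeletonize_molecule(
    obj$mask[[which.max(obj$area_px)]], fl))
  expect_identical(an$status, "ok")
  xs <- measure_segments(an)
  expect_true(xs[["X4"]] > 0 && xs[["X5"]] > 0)
  expect_lt(abs(xs[["X4"]] - 28.5) / 28.5, 0.1)
  # the shorter strand carries more junction-placement jitter; the
  # calibrated quantity is the strand mean (bubble size)
  expect_lt(abs(xs[["X5"]] - 27.5) / 27.5, 0.2)
  expect_lt(abs(bubble_size(xs) - 28) / 28, 0.1)
  # sum rule: averaged arms and strands plus stalks track the contour
  tot <- total_length(xs)
  expect_lt(abs(tot - 145) / 145, 0.1)
  # bubble-free convention: X6 = 0 only when no bubble
  expect_gt(xs[["X6"]], 0)
})

test_that("anatomy labels agree with ground truth on a clean population", {
  pop <- population_preset("wt", n_molecules = 60, seed = 19)
  sim <- generate_population(pop, clean_scan(resolution_px = 512L,
                                             field_size_nm = 1200))
  res <- suppressWarnings(analyze_population(sim))
  m <- res$metrics[!is.na(res$metrics$true_molecule_id), ]
  expect_gt(nrow(m), 25)
  acc <- mean(m$conformation_class == m$true_class_label)
  expect_gte(acc, 0.85)
  # bubble-free molecules keep the whole stalk in X3
  rods <- m[m$conformation_class == "rod", ]
  if (nrow(rods)) {
    expect_true(all(rods$X6 == 0))
    expect_true(all(rods$X3 > 0))
  }
  # splay pairs come sorted and paired
  expect_true(all((m$X1 > 0) == (m$X2 > 0)))
  expect_true(all((m$X4 > 0) == (m$X5 > 0)))
  expect_true(all((m$X7 > 0) == (m$X8 > 0)))
  expect_true(all(m$X1 >= m$X2 & m$X4 >= m$X5 & m$X7 >= m$X8))
})

test_that("an antibody blob is located at its backbone fraction", {
  pop <- population_preset("wt", n_molecules = 1, molecules_per_field = 1,
                           seed = 3, splay_prob_per_end = 0, bubble_prob = 0,
                           antibody_label_rel = 0.48,
                           persistence_length_nm = 300)
  sim <- generate_population(pop, clean_scan())
  res <- suppressWarnings(analyze_population(sim))
  m <- res$metrics
  expect_equal(nrow(m), 1L)
  expect_false(is.na(m$ab_rel_center))
  # orientation may flip the fraction; accept either end as reference
  err <- min(abs(m$ab_rel_center - 0.48), abs((1 - m$ab_rel_center) - 0.48))
  expect_lt(err, 0.06)
})
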