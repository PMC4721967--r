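test_that("a background-only field yields no molecule-scale objects", {
  set.seed(5)
  h <- matrix(rnorm(256^2, 0, 0.1), 256, 256)
  fl <- topograph(h, 2.34, provenance = "flattened")
  obj <- detect_objects(fl)
  expect_equal(sum(obj$rejection_reason == "none"), 0L)
})

test_that("a single molecule is detected with most of its footprint", {
  pop <- population_preset("wt", n_molecules = 1, molecules_per_field = 1,
                           seed = 25)
  sim <- generate_population(pop, default_scan_small())
  f <- sim$fields[[1]]
  fl <- flatten(f$topograph)
  obj <- suppressWarnings(
    select_molecules(detect_objects(fl), img_dim = dim(fl$heights)))
  keep <- which(obj$rejection_reason == "none")
  expect_length(keep, 1L)
  fp <- f$footprints[[1]]
  cover <- length(intersect(obj$mask[[keep]], fp)) / length(fp)
  expect_gte(cover, 0.9)
})

test_that("selection applies border and aggregate criteria and partitions", {
  # many molecules at high density: borders and aggregates both occur
  pop <- population_preset("wt", n_molecules = 40, molecules_per_field = 40,
                           seed = 31)
  sim <- generate_population(pop, default_scan_small())
  fl <- flatten(sim$fields[[1]]$topograph)
  obj <- detect_objects(fl)
  px <- fl$pixel_size_nm
  anchors <- cbind(round(sim$truth$anchor_y_nm / px + 0.5),
                   round(sim$truth$anchor_x_nm / px + 0.5))
  sel <- select_molecules(obj, truth_anchors_px = anchors,
                          img_dim = dim(fl$heights))
  expect_true(any(sel$rejection_reason == "border"))
  expect_true(any(sel$rejection_reason == "aggregate"))
  # every detected object appears exactly once with exactly one reason
  expect_equal(nrow(sel), nrow(obj))
  expect_true(all(sel$rejection_reason %in%
                    c("none", "border", "aggregate", "too_small")))
  # border-touching objects are never retained
  expect_true(all(!sel$touches_border[sel$rejection_reason == "none"]))

  # determinism
  sel2 <- select_molecules(obj, truth_anchors_px = anchors,
                           img_dim = dim(fl$heights))
  expect_identical(sel$rejection_reason, sel2$rejection_reason)
})
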