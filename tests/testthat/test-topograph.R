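test_that("ASCII grid round-trips exactly with sidecar metadata", {
  set.seed(3)
  tp <- topograph(matrix(rnorm(64, 1, 0.3), 8, 8), pixel_size_nm = 2.34375,
                  metadata = list(seed = 3L, note = "fixture"))
  path <- file.path(tempdir(), "grid_test.txt")
  write_topograph_ascii(tp, path)
  back <- read_topograph_ascii(path)
  expect_equal(back$heights, tp$heights, tolerance = 0)
  expect_equal(back$pixel_size_nm, tp$pixel_size_nm)
  expect_identical(back$provenance, "raw")
  expect_equal(back$metadata$seed, 3L)
  unlink(c(path, paste0(path, ".json")))
})

test_that("float TIFF round-trips at binary32 precision", {
  skip_if_not_installed("tiff")
  set.seed(4)
  tp <- topograph(matrix(abs(rnorm(64, 2, 0.5)), 8, 8), 2.34)
  path <- file.path(tempdir(), "grid_test.tif")
  write_topograph_tiff(tp, path)
  back <- read_topograph_tiff(path)
  expect_equal(back$heights, tp$heights, tolerance = 1e-6)
  expect_equal(back$pixel_size_nm, 2.34)
  unlink(c(path, paste0(path, ".json")))
})

test_that("topograph construction validates its inputs", {
  expect_error(topograph(matrix(0, 2, 2), 0), "positive")
  expect_error(topograph(1:4, 1), "matrix")
  expect_error(topograph(matrix(c(0, Inf, 0, 0), 2), 1), "non-finite")
  expect_error(topograph(matrix(0, 2, 2), 1, provenance = "weird"))
})
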