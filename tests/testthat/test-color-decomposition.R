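test_that("rgb_to_od matches its closed form and round trips", {
  expect_equal(rgb_to_od(255), 0, tolerance = 1e-15)
  expect_equal(rgb_to_od(0), log(256), tolerance = 1e-15)   # about 5.545
  x <- array(0:255, dim = c(16, 16, 1))
  back <- od_to_rgb(rgb_to_od(x))
  expect_lt(max(abs(back - x)), 1e-9)
})

test_that("stain matrix validates unit columns and rejects collinearity", {
  S <- stain_matrix()
  expect_equal(unname(colSums(S^2)), c(1, 1), tolerance = 1e-12)
  expect_true(all(S >= 0))
  expect_error(stain_matrix(h = c(1, 1, 0), e = c(1, 1, 0)), "collinear")
})

test_that("stain matrix text config round trips", {
  S <- stain_matrix(h = c(0.6, 0.7, 0.3), e = c(0.1, 0.9, 0.2))
  f <- withr::local_tempfile(fileext = ".txt")
  write_stain_matrix(S, f)
  expect_equal(unclass(read_stain_matrix(f)), unclass(S), tolerance = 1e-9)
  writeLines("1 2 3", f)
  expect_error(read_stain_matrix(f), "6 numbers")
})

test_that("decompose inverts the forward renderer exactly (noise-free)", {
  S <- stain_matrix()
  set.seed(7)
  h <- matrix(runif(30 * 20, 0, 1.5), 30, 20)
  e <- matrix(runif(30 * 20, 0, 0.6), 30, 20)
  d <- decompose(render_he(h, e, S, quantize = FALSE), S)
  expect_lt(max(abs(d$h - h)), 1e-3)
  expect_lt(max(abs(d$e - e)), 1e-3)
  # hematoxylin-only pixel leaves no eosin residue
  d1 <- decompose(render_he(matrix(1, 1, 1), matrix(0, 1, 1), S,
                            quantize = FALSE), S)
  expect_lt(abs(d1$e[1, 1]), 1e-3)
})

test_that("decompose is permutation-consistent and clips negatives", {
  sc <- small_scene(5)
  S <- stain_matrix()
  Sswap <- structure(S[, 2:1], class = class(S))
  a <- decompose(sc$image, S)
  b <- decompose(sc$image, Sswap)
  expect_equal(a$h, b$e)
  expect_equal(a$e, b$h)
  expect_true(all(a$h >= 0) && all(a$e >= 0))
})

test_that("nuclear_channel separates nuclei from background", {
  white <- array(255L, dim = c(8, 8, 3))
  expect_true(all(nuclear_channel(white) == 0))
  sc <- generate_scene(scene_spec(height = 64, width = 64, n_nuclei = 2,
                                  overlap_fraction = 0, seed = 2))
  nc <- nuclear_channel(sc$image)
  expect_gt(mean(nc[sc$mask > 0L]), mean(nc[sc$mask == 0L]))
  expect_true(all(nc >= 0 & nc <= 1))
})

test_that("nuclear_channel is invariant to a global OD scale", {
  sc <- small_scene(9)
  # min-max rescaling removes a common OD factor exactly (continuous images)
  a <- nuclear_channel(render_he(sc$h_od, sc$e_od, quantize = FALSE))
  b <- nuclear_channel(render_he(1.3 * sc$h_od, 1.3 * sc$e_od,
                                 quantize = FALSE))
  expect_equal(a, b, tolerance = 1e-9)
})
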