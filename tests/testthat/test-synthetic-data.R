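test_that("empty spec yields pure background", {
  sc <- generate_scene(scene_spec(n_nuclei = 0, noise_sd = 0, seed = 1))
  expect_true(all(sc$mask == 0L))
  expect_equal(nrow(sc$touching_pairs), 0L)
  # background carries only the eosin stain; all pixels identical
  expect_equal(length(unique(as.vector(sc$image[, , 1]))), 1L)
})

test_that("identical specs generate bit-identical scenes", {
  sp <- scene_spec(seed = 11)
  expect_identical(generate_scene(sp), generate_scene(sp))
})

test_that("mask labels are consecutive and non-empty", {
  for (seed in 1:5) {
    sc <- small_scene(seed, n = 12L, hw = 96L)
    labs <- sort(unique(sc$mask[sc$mask > 0L]))
    expect_identical(labs, seq_len(max(sc$mask)))
    expect_lte(max(sc$mask), 12L)
  }
})

test_that("touching_pairs matches the exhaustive adjacency oracle", {
  for (seed in 1:20) {
    sc <- small_scene(seed, n = 8L, hw = 64L, overlap = 0.4)
    expect_equal(unname(sc$touching_pairs),
                 unname(oracle_touching_pairs(sc$mask)),
                 info = paste("seed", seed))
  }
})

test_that("observed touching fraction honours the requested overlap rate", {
  # pooled over 10 seeds: Binomial(500, 0.4) 99% bounds via the oracle scan
  n <- 50L; p <- 0.4
  touched <- 0L; total <- 0L
  for (seed in 1:10) {
    sc <- generate_scene(scene_spec(height = 160, width = 160, n_nuclei = n,
                                    overlap_fraction = p, seed = seed))
    tp <- oracle_touching_pairs(sc$mask)
    touched <- touched + length(unique(as.vector(tp)))
    total <- total + max(sc$mask)
  }
  mu <- total * p
  half <- qnorm(0.995) * sqrt(total * p * (1 - p))
  expect_gt(touched, mu - half)
  expect_lt(touched, mu + half)
})

test_that("over-dense specs fail fast with a clear error", {
  expect_error(
    generate_scene(scene_spec(height = 48, width = 48, n_nuclei = 60,
                              overlap_fraction = 0, seed = 1)),
    "over-dense")
})

test_that("render_he obeys the Beer-Lambert forward model", {
  S <- stain_matrix()
  z <- matrix(0, 4, 4)
  expect_true(all(render_he(z, z, S) == 255L))
  # single pixel, unit hematoxylin OD: closed-form 256*exp(-S[,1]) - 1
  h <- matrix(1, 1, 1); e <- matrix(0, 1, 1)
  img <- render_he(h, e, S, quantize = FALSE)
  expect_equal(as.vector(img), 256 * exp(-S[, 1]) - 1, tolerance = 1e-12)
  # monotonicity: more hematoxylin never brightens any channel
  h2 <- matrix(1.5, 1, 1)
  expect_true(all(render_he(h2, e, S, quantize = FALSE) <= img))
  expect_error(render_he(matrix(0, 2, 2), matrix(0, 3, 3), S), "shape")
})

test_that("split_dataset is disjoint, exact and deterministic", {
  scenes <- as.list(1:10)
  sp <- split_dataset(scenes, 0.5, seed = 4)
  expect_length(sp$train, 5L)
  expect_length(sp$test, 5L)
  expect_length(intersect(unlist(sp$train), unlist(sp$test)), 0L)
  expect_identical(sp, split_dataset(scenes, 0.5, seed = 4))
  sp2 <- split_dataset(as.list(1:2), 0.5, seed = 1)
  expect_length(sp2$train, 1L)
  expect_length(sp2$test, 1L)
  expect_error(split_dataset(as.list(1), 0.5, seed = 1), "at least 2")
})
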