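test_that("binarize applies the >= tie rule and is monotone", {
  p <- matrix(0.6, 4, 4)
  expect_true(all(binarize(p, 0.5)))
  expect_true(all(binarize(matrix(0.5, 3, 3), 0.5)))     # ties -> foreground
  set.seed(1)
  q <- matrix(runif(100), 10, 10)
  expect_true(all(binarize(q, 0.7) <= binarize(q, 0.3)))
  expect_error(binarize(q, 0), "threshold")
  expect_error(binarize(q, 1), "threshold")
})

test_that("watershed handles empty and single-object inputs", {
  expect_true(all(watershed_split(matrix(FALSE, 12, 12)) == 0L))
  one <- disc_mask(32, 32, 16, 16, 10)
  lab <- watershed_split(one)
  expect_equal(max(lab), 1L)
  expect_equal(lab > 0L, one)
})

test_that("fused two-disc blobs split near the nearest-centre oracle", {
  c1 <- c(20, 22); c2 <- c(20, 36)               # 14 px apart, radius 10
  fg <- disc_mask(40, 60, c1[1], c1[2], 10) | disc_mask(40, 60, c2[1], c2[2], 10)
  lab <- watershed_split(fg)
  expect_equal(max(lab), 2L)
  oracle <- oracle_nearest_centre(fg, c1, c2)
  areas <- sort(tabulate(lab[lab > 0L]))
  oracle_areas <- sort(tabulate(oracle[oracle > 0L]))
  expect_true(all(abs(areas - oracle_areas) / oracle_areas < 0.15))
})

test_that("segment labels disjoint discs exactly and handles empty maps", {
  prob <- matrix(0, 48, 48)
  d1 <- disc_mask(48, 48, 12, 12, 7); d2 <- disc_mask(48, 48, 34, 34, 7)
  prob[d1 | d2] <- 1
  lab <- segment(prob, postprocess_params())
  expect_equal(max(lab), 2L)
  expect_equal(lab > 0L, d1 | d2)
  expect_true(all(tapply(lab[lab > 0], lab[lab > 0], length) > 0))
  expect_true(all(watershed_split(matrix(FALSE, 8, 8)) == 0L))
  expect_equal(max(segment(matrix(0, 16, 16))), 0L)
})

test_that("labels partition the binarized foreground and are consecutive", {
  for (seed in 1:5) {
    sc <- small_scene(seed, n = 10L, overlap = 0.5)
    prob <- (sc$mask > 0L) * 1
    pp <- postprocess_params(min_object_area = 5)
    lab <- segment(prob, pp)
    labs <- sort(unique(lab[lab > 0L]))
    expect_identical(labs, seq_len(max(lab)))
    # removed small objects aside, labels cover exactly the foreground
    expect_true(all(lab[prob < 0.5] == 0L))
    covered <- sum(lab > 0L) / sum(prob >= 0.5)
    expect_gt(covered, 0.95)
  }
})

test_that("segment is idempotent on its own output indicator", {
  sc <- small_scene(4, n = 8L, overlap = 0.5)
  pp <- postprocess_params()
  lab1 <- segment((sc$mask > 0L) * 1, pp)
  lab2 <- segment((lab1 > 0L) * 1, pp)
  expect_equal(lab1 > 0L, lab2 > 0L)
  # same partition up to label permutation: contingency rows/cols are 1-1
  tab <- table(lab1[lab1 > 0L], lab2[lab1 > 0L])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})
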