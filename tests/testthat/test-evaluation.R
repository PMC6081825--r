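test_that("iou matches explicit pixel enumeration", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(iou(a, b), 0)
  # two 2x2 squares overlapping in a 1x2 strip: |int| = 2, |union| = 6
  c1 <- matrix(FALSE, 4, 4); c1[1:2, 1:2] <- TRUE
  c2 <- matrix(FALSE, 4, 4); c2[2:3, 1:2] <- TRUE
  expect_equal(iou(c1, c2), 1 / 3)
  expect_error(iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("match_objects counts and the strict >0.5 rule are exact", {
  gt <- random_object_mask(30, 30, 3, seed = 1)
  m <- match_objects(gt, gt)
  expect_equal(m$tp, max(gt)); expect_equal(m$fp, 0L); expect_equal(m$fn, 0L)
  # IoU exactly 0.5: 1-pixel prediction inside a 2-pixel object
  g <- matrix(0L, 5, 5); g[2, 2:3] <- 1L
  p <- matrix(0L, 5, 5); p[2, 2] <- 1L
  m2 <- match_objects(g, p)
  expect_equal(m2$tp, 0L); expect_equal(m2$fp, 1L); expect_equal(m2$fn, 1L)
})

test_that("conservation identities hold on random masks", {
  for (seed in 1:10) {
    gt <- random_object_mask(40, 40, 5, seed)
    pred <- random_object_mask(40, 40, 5, seed + 500)
    m <- match_objects(gt, pred)
    expect_equal(m$tp + m$fn, max(gt))
    expect_equal(m$tp + m$fp, max(pred))
    expect_lte(anyDuplicated(m$pairs$gt_label), 0)
    expect_lte(anyDuplicated(m$pairs$pred_label), 0)
  }
})

test_that("greedy matching equals exhaustive optimal assignment", {
  for (seed in 1:12) {
    gt <- random_object_mask(36, 36, 5, seed)
    pred <- random_object_mask(36, 36, 5, seed + 1000)
    expect_equal(match_objects(gt, pred)$tp, oracle_optimal_tp(gt, pred),
                 info = paste("seed", seed))
  }
})

test_that("compute_metrics implements the exact formulas", {
  expect_equal(unname(compute_metrics(list(tp = 1, fp = 0, fn = 1))),
               c(1, 0.5, 2 / 3))
  expect_equal(unname(compute_metrics(list(tp = 0, fp = 0, fn = 0))),
               c(0, 0, 0))
  expect_equal(unname(compute_metrics(list(tp = 7, fp = 0, fn = 0))),
               c(1, 1, 1))
  set.seed(3)
  for (i in 1:1000) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    m <- compute_metrics(list(tp = tp, fp = fp, fn = fn))
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    expect_equal(unname(m), c(pr, rc, f1), tolerance = 1e-12)
  }
})

test_that("swapping gt and pred swaps precision and recall", {
  for (seed in 1:5) {
    gt <- random_object_mask(32, 32, 4, seed)
    pred <- random_object_mask(32, 32, 4, seed + 50)
    a <- compute_metrics(match_objects(gt, pred))
    b <- compute_metrics(match_objects(pred, gt))
    expect_equal(a[["precision"]], b[["recall"]])
    expect_equal(a[["recall"]], b[["precision"]])
    expect_equal(a[["f1"]], b[["f1"]])
  }
})

test_that("standard_error is sigma/sqrt(n) with population sigma", {
  g <- matrix(0, 2, 2)
  expect_equal(standard_error(g, g), 0)
  # differences (0, 0, 1, 1): sigma = 0.5, n = 4 -> 0.25
  o <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(standard_error(o, g), 0.25)
  # tiling the grid 4x divides the SE by 2 (sigma unchanged)
  o4 <- rbind(cbind(o, o), cbind(o, o))
  g4 <- matrix(0, 4, 4)
  expect_equal(standard_error(o4, g4), 0.125)
})

test_that("touching separation counts distinctly matched pairs", {
  sc <- small_scene(2, n = 8L, overlap = 0.6)
  expect_gt(nrow(sc$touching_pairs), 0L)
  perfect <- touching_separation(sc, sc$mask)
  expect_equal(perfect$rate, 1)
  # merge every touching pair into one label
  merged <- sc$mask
  for (r in seq_len(nrow(sc$touching_pairs)))
    merged[merged == sc$touching_pairs[r, 2]] <- sc$touching_pairs[r, 1]
  merged <- nucleofuse:::relabel_consecutive(merged)
  expect_equal(touching_separation(sc, merged)$rate, 0)
})

test_that("a constructed 5-pair scene with 3 split pairs scores 0.6", {
  # five horizontally touching rectangle pairs, one pair per row band
  gt <- matrix(0L, 40, 22)
  for (k in 0:4) {
    gt[(k * 8 + 2):(k * 8 + 6), 3:10] <- 2L * k + 1L
    gt[(k * 8 + 2):(k * 8 + 6), 11:18] <- 2L * k + 2L
  }
  scene <- list(mask = gt, touching_pairs = cbind(a = c(1L, 3L, 5L, 7L, 9L),
                                                  b = c(2L, 4L, 6L, 8L, 10L)))
  pred <- gt                                   # split pairs 1..3 correctly
  pred[gt == 8L] <- 7L                         # merge pair 4
  pred[gt == 10L] <- 9L                        # merge pair 5
  pred <- nucleofuse:::relabel_consecutive(pred)
  r <- touching_separation(scene, pred)
  expect_equal(r$separated, 3L)
  expect_equal(r$total_touching, 5L)
  expect_equal(r$rate, 0.6)
})

test_that("match_table lists TP pairs plus FN and FP rows", {
  gt <- matrix(0L, 12, 12); gt[2:5, 2:5] <- 1L; gt[8:11, 8:11] <- 2L
  pred <- matrix(0L, 12, 12); pred[2:5, 2:5] <- 1L; pred[2:5, 9:12] <- 2L
  tab <- match_table(match_objects(gt, pred))
  expect_setequal(tab$status, c("TP", "FN", "FP"))
  expect_equal(sum(tab$status == "TP"), 1L)
  expect_equal(tab$iou[tab$status == "TP"], 1)
  expect_equal(nrow(tab), 3L)
})

test_that("multi-split standard error pools test pixels across permutations", {
  scenes <- lapply(1:6, function(i) generate_scene(scene_spec(
    height = 32, width = 32, n_nuclei = 3, radius_range = c(3, 5), seed = i)))
  # stub "model": predict the (noisy) truth so the SE is small but nonzero
  r <- multi_split_standard_error(
    scenes,
    train_fn = function(train) NULL,
    predict_fn = function(fit, sc) (sc$mask > 0L) * 0.9,
    n_splits = 3L, seed = 2L)
  expect_length(r$per_split, 3L)
  expect_true(all(r$per_split > 0))
  expect_gt(r$standard_error, 0)
  # pooled n is 3x the per-split n, so pooled SE ~ per-split / sqrt(3)
  expect_lt(r$standard_error, max(r$per_split))
})
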