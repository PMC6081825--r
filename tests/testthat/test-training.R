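oracle_boundary <- function(mask, thickness) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0L) next
    for (di in -thickness:thickness) for (dj in -thickness:thickness) {
      ii <- i + di; jj <- j + dj
      nb <- if (ii < 1 || ii > H || jj < 1 || jj > W) 0L else mask[ii, jj]
      if (nb != mask[i, j]) { out[i, j] <- TRUE; break }
    }
  }
  out
}

test_that("boundary targets follow the Chebyshev contact rule", {
  expect_equal(boundary_from_mask(matrix(0L, 6, 6)), matrix(FALSE, 6, 6))
  # filled rectangle, thickness 1: boundary count = 2w + 2h - 4
  m <- matrix(0L, 20, 20); m[5:12, 4:15] <- 1L     # h = 8, w = 12
  expect_equal(sum(boundary_from_mask(m, 1L)), 2L * 8L + 2L * 12L - 4L)
  # two instances sharing an edge: every contact pixel marked on both sides
  m2 <- matrix(0L, 10, 10); m2[2:9, 2:5] <- 1L; m2[2:9, 6:9] <- 2L
  b2 <- boundary_from_mask(m2, 1L)
  expect_true(all(b2[2:9, 5]) && all(b2[2:9, 6]))
})

test_that("boundary targets match the per-pixel scan oracle", {
  for (seed in 1:20) {
    m <- random_object_mask(24, 24, 4, seed)
    expect_equal(boundary_from_mask(m, 2L), oracle_boundary(m, 2L),
                 info = paste("seed", seed))
  }
})

make_tiny_dataset <- function(n = 6L, hw = 32L) {
  scenes <- lapply(seq_len(n), function(i)
    generate_scene(scene_spec(height = hw, width = hw, n_nuclei = 3,
                              radius_range = c(3, 5), seed = 100L + i)))
  list(scenes = scenes,
       inputs = lapply(scenes, function(s) nuclear_channel(s$image)),
       targets = lapply(scenes, function(s) (s$mask > 0L) * 1L))
}

test_that("training reduces the loss and is seed-reproducible", {
  d <- make_tiny_dataset()
  m <- build_symmetric(3, seed = 1)
  cfg <- train_config(max_epochs = 4, batch_size = 2, seed = 5)
  r1 <- train_model(m, d$inputs, d$targets, cfg)
  r2 <- train_model(m, d$inputs, d$targets, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(param_checksum(r1$model), param_checksum(r2$model))
  expect_lt(r1$history[4], r1$history[1])
  expect_length(r1$history, 4L)
})

test_that("zero learning rate leaves parameters and loss untouched", {
  d <- make_tiny_dataset(4L)
  m <- build_symmetric(3, dropout_rate = 0, seed = 2)
  # full-batch, no dropout: every epoch sees the identical batch
  cfg <- train_config(learning_rate = 0, max_epochs = 3, batch_size = 4L,
                      dropout_rate = 0, seed = 1)
  r <- train_model(m, d$inputs, d$targets, cfg)
  expect_identical(param_checksum(r$model), param_checksum(m))
  expect_lt(diff(range(r$history)), 1e-6)
})

test_that("uniform class weights equal the unweighted gradient", {
  d <- make_tiny_dataset(2L)
  m <- build_symmetric(3, dropout_rate = 0, seed = 3)
  nf <- asNamespace("nucleofuse")
  x <- nf$stack_batch(lapply(d$inputs, nf$as_input_array))
  t <- nf$stack_batch(d$targets)
  fw <- nf$net_forward(m, x, training = TRUE)
  a <- nf$softmax_ce(fw$out, t, NULL)
  b <- nf$softmax_ce(fw$out, t, c(1, 1))
  expect_identical(a$dlogits, b$dlogits)
  expect_identical(a$loss, b$loss)
})

test_that("train_fusion trains independent stages and a 2-channel fusion net", {
  d <- make_tiny_dataset(4L)
  cfg <- train_config(max_epochs = 1, batch_size = 2, seed = 11)
  fm <- train_fusion(d$scenes, family = "symmetric", n_modules = 3,
                     config = cfg)
  expect_s3_class(fm, "nf_fusion_model")
  expect_equal(fm$fusion$in_channels, 2L)
  # independence: stage nets equal models trained separately, same seeds
  cfg_b <- cfg; cfg_b$seed <- cfg$seed + 1L
  region <- train_model(build_symmetric(3, seed = cfg$seed),
                        d$inputs, d$targets, cfg)
  bt <- lapply(d$scenes, function(s)
    boundary_from_mask(s$mask, cfg$boundary_thickness) * 1L)
  boundary <- train_model(build_symmetric(3, seed = cfg_b$seed),
                          d$inputs, bt, cfg_b)
  expect_identical(param_checksum(fm$region), param_checksum(region$model))
  expect_identical(param_checksum(fm$boundary), param_checksum(boundary$model))
})

test_that("multitask model shares the trunk and normalises both heads", {
  d <- make_tiny_dataset(4L)
  cfg <- train_config(max_epochs = 1, batch_size = 2, seed = 21)
  r <- train_multitask(d$scenes, family = "symmetric", n_modules = 3,
                       config = cfg)
  x <- nuclear_channel(d$scenes[[1]]$image)
  p <- forward(r$model, x)
  expect_named(p, c("region", "boundary"))
  for (h in p) {
    expect_equal(dim(h), c(32L, 32L, 2L))
    expect_lt(max(abs(apply(h, c(1, 2), sum) - 1)), 1e-6)
  }
  # trunk parameter count equals the single-task trunk (heads excluded)
  single <- build_symmetric(3, seed = 1)
  head_params <- function(ch) 2L * ch + 2L        # 1x1 conv to 2 classes
  trunk_ch <- single$ops[[single$logits_op]]$in_ch
  expect_equal(parameter_count(r$model) - 2L * head_params(trunk_ch),
               parameter_count(single) - head_params(trunk_ch))
})

test_that("zero-epoch training returns the seeded initialisation unchanged", {
  d <- make_tiny_dataset(2L)
  m <- build_symmetric(3, seed = 6)
  r <- train_model(m, d$inputs, d$targets,
                   train_config(max_epochs = 0, batch_size = 2, seed = 1))
  expect_identical(param_checksum(r$model), param_checksum(m))
  expect_length(r$history, 0L)
})

test_that("train_config enforces the documented defaults", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 5e-4)
  expect_equal(cfg$weight_decay_l2, 2e-4)
  expect_equal(cfg$batch_size, 4L)
  expect_error(train_config(batch_size = 0), "batch_size")
})
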