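n_blocks <- function(model) {
  sum(vapply(model$ops, function(o) o$type == "btail", logical(1)))
}

test_that("symmetric family has mirrored encoder/decoder block counts", {
  m <- build_symmetric(3, seed = 1)
  expect_equal(n_blocks(m), 6L)              # 3 encoder + 3 decoder
  m10 <- build_symmetric(10, seed = 1)
  expect_equal(n_blocks(m10), 20L)
  expect_error(build_symmetric(2), "between 3 and 10")
  expect_error(build_symmetric(11), "between 3 and 10")
})

test_that("all symmetric sizes keep the shape and normalization contract", {
  set.seed(1)
  x <- matrix(runif(32 * 32), 32, 32)
  for (n in 3:10) {
    m <- build_symmetric(n, seed = n)
    p <- forward(m, x)
    expect_equal(dim(p), c(32L, 32L, 2L), info = paste("n =", n))
    expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("parameter_count matches hand-derived closed forms", {
  # minimal block: one 1x1 conv (1 -> 4 maps) + fused tail
  # conv: 4 * (1*1*1) + 4 = 8; bn affine: 2 * 4 = 8
  B <- nucleofuse:::new_builder()
  c1 <- nucleofuse:::op_conv(B, 0L, 1L, 4L, 1L, 1L)
  t1 <- nucleofuse:::op_btail(B, c1, NULL, 4L)
  mini <- structure(list(ops = B$ops), class = "nf_model")
  expect_equal(parameter_count(mini), 16L)

  # full 3-module symmetric net with 1x1 kernels, hand-computed per block:
  # conv k=1: out*in + out; projection (in != out): out*in + out; bn: 2*out
  block <- function(i, o) (o * i + o) + (if (i != o) o * i + o else 0) + 2 * o
  expected <- block(1, 32) + block(32, 64) + block(64, 128) +   # encoder
    block(128, 64) + block(64, 32) + block(32, 32) +            # decoder
    (2 * 32 + 2)                                                # 1x1 head
  m <- build_symmetric(3, kernel = "1x1", seed = 2)
  expect_equal(parameter_count(m), expected)
})

test_that("parameter count grows strictly with module count", {
  counts <- vapply(3:10, function(n)
    parameter_count(build_symmetric(n, seed = 1)), numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("initialisation is seed-reproducible", {
  a <- build_symmetric(3, seed = 7)
  b <- build_symmetric(3, seed = 7)
  c <- build_symmetric(3, seed = 8)
  expect_identical(param_checksum(a), param_checksum(b))
  expect_false(identical(param_checksum(a), param_checksum(c)))
})

test_that("forward pass is deterministic and constant on constant input", {
  m <- build_symmetric(3, seed = 3)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(forward(m, x), forward(m, x))
  p0 <- forward(m, matrix(0, 64, 64))[, , 2]
  interior <- p0[17:48, 17:48]                # away from padding effects
  expect_lt(diff(range(interior)), 1e-6)
  expect_error(forward(m, array(runif(64 * 64 * 3), c(64, 64, 3))), "channels")
  expect_error(forward(m, matrix(0, 60, 60)), "divisible")
})

test_that("ENet-style decoder is shallower than its encoder", {
  m <- build_enet(seed = 4)
  expect_gt(sum(m$units$side == "encoder"), sum(m$units$side == "decoder"))
  x <- matrix(runif(128 * 128), 128, 128)
  p <- forward(m, x)
  expect_equal(dim(p), c(128L, 128L, 2L))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)
})

test_that("dilated units enlarge the receptive field per the analytic oracle", {
  m <- build_enet(seed = 5)
  u <- m$units
  expect_true(all(u$dilation >= 1))
  dil <- which(u$dilation > 1)
  expect_gt(length(dil), 1L)
  for (k in dil) {
    upto <- u[1:k, ]
    undilated <- upto
    undilated$dilation[k] <- 1
    expect_gt(receptive_field(upto), receptive_field(undilated))
  }
})

test_that("checkpoints are self-describing and reproduce predictions", {
  m <- build_symmetric(3, seed = 9)
  x <- matrix(runif(32 * 32), 32, 32)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(forward(m2, x), forward(m, x))
  expect_equal(m2$family, "symmetric")
})

test_that("network specs round trip through the plain-text config", {
  m <- build_symmetric(4, kernel = "5f", dropout_rate = 0.2, seed = 13)
  f <- withr::local_tempfile(fileext = ".json")
  write_network_spec(m, f)
  m2 <- read_network_spec(f)
  expect_identical(param_checksum(m2), param_checksum(m))
  e <- build_enet(seed = 3)
  write_network_spec(e, f)
  expect_identical(param_checksum(read_network_spec(f)), param_checksum(e))
})
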