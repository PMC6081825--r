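#' Encoder-decoder network families
#'
#' Two families are provided. The *symmetric* family has n encoder blocks
#' mirrored by n decoder blocks (n = 3..10). Each block wraps a convolution
#' stack (3x3 by default; 1x1 or a factorized 5 — 5x1 followed by 1x5 — may be
#' chosen) in batch normalisation, an additive identity skip (1x1 projection
#' when channel counts differ), ReLU, and dropout; encoder blocks end in 2x2
#' max-pooling whose argmax indices drive max-unpooling in the mirrored
#' decoder block (the SegNet convention). Feature maps follow the
#' (initial, middle, last) = (32, 64, 128) plan, blocks split as evenly as
#' possible across the three tiers with the remainder given to the middle
#' tier. Spatial downsampling is capped at `max_downsamples` (default 5):
#' deeper blocks run in identity mode, so a 10-module network still accepts
#' practical tile sizes (sides divisible by 2^5) within CPU memory.
#'
#' The *ENet-style* family is asymmetric: an initial downsampling block, an
#' encoder of bottleneck units mixing normal, dilated and factorized
#' (asymmetric) convolutions with two further downsampling units, and a
#' deliberately shallower decoder of two upsampling units — fewer
#' convolutional layers on the decoding path cut the computational load.
#'
#' The final layer of both families is a 1x1 projection to `out_classes`
#' followed by a per-pixel softmax, so every output pixel is a probability
#' vector summing to 1.
#'
#' @name networks
NULL

feature_tiers <- function(n_modules, feature_plan) {
  base <- n_modules %/% 3L
  rem <- n_modules %% 3L
  sizes <- c(base, base + rem, base)
  rep(feature_plan, times = sizes)
}

conv_stack <- function(B, input, in_ch, out_ch, kernel) {
  switch(kernel,
    "3x3" = op_conv(B, input, in_ch, out_ch, 3L, 3L),
    "1x1" = op_conv(B, input, in_ch, out_ch, 1L, 1L),
    "5f" = {
      mid <- op_conv(B, input, in_ch, out_ch, 5L, 1L)
      op_conv(B, mid, out_ch, out_ch, 1L, 5L)
    },
    stop("kernel must be one of '3x3', '1x1', '5f'")
  )
}

symmetric_block <- function(B, input, in_ch, out_ch, kernel, dropout_rate) {
  c1 <- conv_stack(B, input, in_ch, out_ch, kernel)
  skip <- if (in_ch == out_ch) input else op_conv(B, input, in_ch, out_ch, 1L, 1L)
  op_btail(B, c1, skip, out_ch, rate = dropout_rate, use_relu = TRUE)
}

#' Build a symmetric encoder-decoder segmentation network
#'
#' @param n_modules number of encoder blocks (= decoder blocks), 3..10.
#' @param in_channels input channels: 1 for the colour-decomposed nuclear
#'   channel, 3 for raw RGB.
#' @param out_classes output classes (2: background/nucleus).
#' @param feature_plan (initial, middle, last) feature-map counts.
#' @param kernel convolution type for every block: `"3x3"`, `"1x1"`, or
#'   `"5f"` (factorized 5: 5x1 then 1x5).
#' @param dropout_rate per-block dropout rate in [0, 1).
#' @param max_downsamples cap on the number of pooling stages; blocks beyond
#'   the cap run in identity (no-pool) mode.
#' @param seed initialisation seed (He-normal weights).
#' @return an `nf_model`. Forward inputs must have sides divisible by
#'   `2^model$downs`.
#' @export
build_symmetric <- function(n_modules, in_channels = 1L, out_classes = 2L,
                            feature_plan = c(32L, 64L, 128L), kernel = "3x3",
                            dropout_rate = 0.1, max_downsamples = 5L,
                            seed = 1L) {
  if (n_modules < 3L || n_modules > 10L)
    stop("n_modules must be between 3 and 10")
  with_seed(seed, {
    B <- new_builder()
    ch <- feature_tiers(n_modules, feature_plan)
    pools <- integer(n_modules)          # pool op id per encoder block (0 = none)
    cur <- 0L                            # op id of current tensor (0 = input)
    prev_ch <- in_channels
    for (j in seq_len(n_modules)) {
      cur <- symmetric_block(B, cur, prev_ch, ch[j], kernel, dropout_rate)
      if (j <= max_downsamples) {
        cur <- op_pool(B, cur)
        pools[j] <- cur
      }
      prev_ch <- ch[j]
    }
    for (j in rev(seq_len(n_modules))) {
      if (pools[j] > 0L) cur <- op_unpool(B, cur, from = pools[j])
      out_ch <- if (j > 1L) ch[j - 1L] else ch[1L]
      cur <- symmetric_block(B, cur, ch[j], out_ch, kernel, dropout_rate)
    }
    logits <- op_conv(B, cur, ch[1L], out_classes, 1L, 1L)
    out <- op_softmax(B, logits)
    structure(list(ops = B$ops, out_op = out, logits_op = logits,
                   family = "symmetric", n_modules = n_modules,
                   in_channels = as.integer(in_channels),
                   out_classes = as.integer(out_classes),
                   feature_plan = feature_plan, kernel = kernel,
                   dropout_rate = dropout_rate,
                   downs = min(n_modules, max_downsamples),
                   seed = as.integer(seed), multitask = FALSE,
                   units = NULL),
              class = "nf_model")
  })
}

# One ENet-style bottleneck. type: "normal", "dilated" (with dilation d),
# "asym" (factorized 5), "down", "up" (with pool_from = matching down pool id).
bottleneck <- function(B, input, in_ch, out_ch, type, dropout_rate,
                       dilation = 1L, pool_from = NULL) {
  mid <- max(out_ch %/% 4L, 4L)
  if (type == "down") {
    c1 <- op_conv(B, input, in_ch, mid, 2L, 2L, stride = 2L, pad = "valid")
    r1 <- op_btail(B, c1, NULL, mid)
    c2 <- op_conv(B, r1, mid, mid, 3L, 3L)
    r2 <- op_btail(B, c2, NULL, mid)
    c3 <- op_conv(B, r2, mid, out_ch, 1L, 1L)
    pool <- op_pool(B, input)
    skip <- if (in_ch == out_ch) pool else op_chanpad(B, pool, in_ch, out_ch)
    # bn + skip-add + relu + dropout fused on the expansion conv
    out <- op_btail(B, c3, skip, out_ch, rate = dropout_rate)
    list(out = out, pool = pool)
  } else if (type == "up") {
    c1 <- op_conv(B, input, in_ch, out_ch, 1L, 1L)
    r1 <- op_btail(B, c1, NULL, out_ch)
    u <- op_unpool(B, r1, from = pool_from)
    c2 <- op_conv(B, u, out_ch, out_ch, 3L, 3L)
    s1 <- op_conv(B, input, in_ch, out_ch, 1L, 1L)
    skip <- op_unpool(B, s1, from = pool_from)
    out <- op_btail(B, c2, skip, out_ch, rate = dropout_rate)
    list(out = out, pool = NA_integer_)
  } else {
    c1 <- op_conv(B, input, in_ch, mid, 1L, 1L)
    r1 <- op_btail(B, c1, NULL, mid)
    sp <- switch(type,
      normal = op_conv(B, r1, mid, mid, 3L, 3L),
      dilated = op_conv(B, r1, mid, mid, 3L, 3L, dh = dilation, dw = dilation),
      asym = {
        t1 <- op_conv(B, r1, mid, mid, 5L, 1L)
        op_conv(B, t1, mid, mid, 1L, 5L)
      },
      stop("unknown bottleneck type: ", type))
    r2 <- op_btail(B, sp, NULL, mid)
    c3 <- op_conv(B, r2, mid, out_ch, 1L, 1L)
    skip <- if (in_ch == out_ch) input else op_conv(B, input, in_ch, out_ch, 1L, 1L)
    out <- op_btail(B, c3, skip, out_ch, rate = dropout_rate)
    list(out = out, pool = NA_integer_)
  }
}

#' Build the ENet-style asymmetric encoder-decoder
#'
#' Declared unit list (9 encoder units, 5 decoder units): initial downsampling
#' conv (to 16 maps); stage 1 at 64 maps (1 down + 2 normal bottlenecks);
#' stage 2 at 128 maps (1 down + normal, dilated-2, asymmetric-5, dilated-4
#' bottlenecks); decoder: up to 64 + normal, up to 16 + normal, final
#' unpooling to full resolution and 1x1 projection. Total downsampling 2^3.
#'
#' @inheritParams build_symmetric
#' @return an `nf_model` with `model$units` describing the declared unit list
#'   (name, side, kernel, stride, dilation) used by the receptive-field
#'   calculator.
#' @export
build_enet <- function(in_channels = 1L, out_classes = 2L, dropout_rate = 0.1,
                       seed = 1L) {
  with_seed(seed, {
    B <- new_builder()
    units <- list()
    note <- function(name, side, k, s, d)
      units[[length(units) + 1L]] <<- data.frame(
        name = name, side = side, kernel = k, stride = s, dilation = d)
    # initial block: conv + BN + ReLU + pool (indices kept for the final unpool)
    c0 <- op_conv(B, 0L, in_channels, 16L, 3L, 3L)
    r0 <- op_btail(B, c0, NULL, 16L)
    p0 <- op_pool(B, r0)
    note("initial", "encoder", 3L, 2L, 1L)
    # stage 1 (64 maps)
    d1 <- bottleneck(B, p0, 16L, 64L, "down", dropout_rate)
    note("bottleneck1.0-down", "encoder", 3L, 2L, 1L)
    u11 <- bottleneck(B, d1$out, 64L, 64L, "normal", dropout_rate)
    note("bottleneck1.1", "encoder", 3L, 1L, 1L)
    u12 <- bottleneck(B, u11$out, 64L, 64L, "normal", dropout_rate)
    note("bottleneck1.2", "encoder", 3L, 1L, 1L)
    # stage 2 (128 maps): normal, dilated 2, asymmetric 5, dilated 4
    d2 <- bottleneck(B, u12$out, 64L, 128L, "down", dropout_rate)
    note("bottleneck2.0-down", "encoder", 3L, 2L, 1L)
    u21 <- bottleneck(B, d2$out, 128L, 128L, "normal", dropout_rate)
    note("bottleneck2.1", "encoder", 3L, 1L, 1L)
    u22 <- bottleneck(B, u21$out, 128L, 128L, "dilated", dropout_rate, dilation = 2L)
    note("bottleneck2.2-dilated2", "encoder", 3L, 1L, 2L)
    u23 <- bottleneck(B, u22$out, 128L, 128L, "asym", dropout_rate)
    note("bottleneck2.3-asym5", "encoder", 5L, 1L, 1L)
    u24 <- bottleneck(B, u23$out, 128L, 128L, "dilated", dropout_rate, dilation = 4L)
    note("bottleneck2.4-dilated4", "encoder", 3L, 1L, 4L)
    # decoder (shallower: 5 units against the encoder's 9)
    v1 <- bottleneck(B, u24$out, 128L, 64L, "up", dropout_rate, pool_from = d2$pool)
    note("bottleneck4.0-up", "decoder", 3L, 1L, 1L)
    v2 <- bottleneck(B, v1$out, 64L, 64L, "normal", dropout_rate)
    note("bottleneck4.1", "decoder", 3L, 1L, 1L)
    v3 <- bottleneck(B, v2$out, 64L, 16L, "up", dropout_rate, pool_from = d1$pool)
    note("bottleneck5.0-up", "decoder", 3L, 1L, 1L)
    v4 <- bottleneck(B, v3$out, 16L, 16L, "normal", dropout_rate)
    note("bottleneck5.1", "decoder", 3L, 1L, 1L)
    fu <- op_unpool(B, v4$out, from = p0)
    logits <- op_conv(B, fu, 16L, out_classes, 1L, 1L)
    note("fullconv", "decoder", 1L, 1L, 1L)
    out <- op_softmax(B, logits)
    structure(list(ops = B$ops, out_op = out, logits_op = logits,
                   family = "enet", n_modules = NA_integer_,
                   in_channels = as.integer(in_channels),
                   out_classes = as.integer(out_classes),
                   feature_plan = c(16L, 64L, 128L), kernel = "mixed",
                   dropout_rate = dropout_rate, downs = 3L,
                   seed = as.integer(seed), multitask = FALSE,
                   units = do.call(rbind, units)),
              class = "nf_model")
  })
}

#' Forward pass: per-pixel class probabilities
#'
#' Deterministic in inference mode (dropout disabled, batch-norm running
#' statistics).
#'
#' @param model an `nf_model`.
#' @param x input: H x W matrix (single channel), H x W x C array, or
#'   H x W x C x N batch. Sides must be divisible by `2^model$downs`
#'   ([predict_probmap()] pads arbitrary sizes).
#' @param training internal flag: batch statistics + dropout active.
#' @return H x W x out_classes x N probability array (pixel sums = 1); if a
#'   single image was given, drop = H x W x out_classes.
#' @export
forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "nf_model"))
  single <- length(dim(x)) < 4L
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  if (d[3] != model$in_channels)
    stop("input has ", d[3], " channels but the model expects ",
         model$in_channels)
  f <- 2^model$downs
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stop("input sides must be divisible by ", f,
         " (use predict_probmap() for automatic padding)")
  r <- net_forward(model, x, training = training)
  out <- r$out
  if (model$multitask)
    out <- list(region = r$outs[[model$out_op]],
                boundary = r$outs[[model$out_op2]])
  if (single && !model$multitask) out <- out[, , , 1L]
  if (single && model$multitask) out <- lapply(out, function(o) o[, , , 1L])
  out
}

#' Analytic receptive-field calculator
#'
#' Standard recursion over a layer sequence: the receptive field grows by
#' (effective kernel - 1) times the cumulative stride, where the effective
#' kernel of a dilated convolution is (k - 1) d + 1.
#'
#' @param layers data frame with columns `kernel`, `stride`, `dilation`.
#' @return receptive-field side length (pixels) after the last layer.
#' @export
receptive_field <- function(layers) {
  rf <- 1; jump <- 1
  for (i in seq_len(nrow(layers))) {
    keff <- (layers$kernel[i] - 1) * layers$dilation[i] + 1
    rf <- rf + (keff - 1) * jump
    jump <- jump * layers$stride[i]
  }
  rf
}

#' Serialize a network description to a plain-text (JSON) config
#'
#' Writes the declarative architecture description — family, module count,
#' channels, feature plan, kernel, dropout and seed — without parameters;
#' `read_network_spec()` rebuilds a freshly initialised model from it.
#'
#' @param model an `nf_model`.
#' @param path text file path.
#' @export
write_network_spec <- function(model, path) {
  stopifnot(inherits(model, "nf_model"))
  spec <- list(family = model$family, n_modules = model$n_modules,
               in_channels = model$in_channels,
               out_classes = model$out_classes,
               feature_plan = model$feature_plan, kernel = model$kernel,
               dropout_rate = model$dropout_rate, seed = model$seed)
  writeLines(jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (x$family == "enet")
    build_enet(in_channels = x$in_channels, out_classes = x$out_classes,
               dropout_rate = x$dropout_rate, seed = x$seed)
  else
    build_symmetric(x$n_modules, in_channels = x$in_channels,
                    out_classes = x$out_classes,
                    feature_plan = x$feature_plan, kernel = x$kernel,
                    dropout_rate = x$dropout_rate, seed = x$seed)
}

#' Save / load a self-describing model checkpoint
#'
#' A checkpoint is a single RDS file embedding the architecture description
#' and all parameters, so `load_checkpoint()` needs no side information.
#'
#' @param model an `nf_model` (or `nf_fusion_model`).
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
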