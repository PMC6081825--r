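# Minimal CPU encoder-decoder engine.
#
# A model is an ordered list of ops forming a DAG: each op names its input op
# ids (0 = the network input). Tensors are R arrays with dim (H, W, C, N).
# Forward stores per-op outputs and caches; backward walks the list in reverse
# accumulating gradients, so additive skip connections and multi-head models
# fall out naturally. Heavy kernels (convolution via im2col + GEMM, pooling,
# unpooling) live in compiled code.

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$ops <- list()
  env
}

add_op <- function(B, type, inputs, ...) {
  id <- length(B$ops) + 1L
  B$ops[[id]] <- c(list(id = id, type = type, inputs = as.integer(inputs)),
                   list(...))
  id
}

# He-initialised convolution; kernel (kh, kw), dilation (dh, dw), stride s,
# "same" padding for odd kernels (even kernels pad 0, used by stride-2 down).
op_conv <- function(B, input, in_ch, out_ch, kh = 3L, kw = 3L,
                    dh = 1L, dw = 1L, stride = 1L, pad = "same") {
  K <- kh * kw * in_ch
  W <- matrix(rnorm(out_ch * K, 0, sqrt(2 / K)), nrow = out_ch)
  if (identical(pad, "same")) {
    ph <- ((kh - 1L) * dh) %/% 2L
    pw <- ((kw - 1L) * dw) %/% 2L
  } else { ph <- 0L; pw <- 0L }
  add_op(B, "conv", input, W = W, b = numeric(out_ch),
         kh = as.integer(kh), kw = as.integer(kw),
         dh = as.integer(dh), dw = as.integer(dw),
         stride = as.integer(stride), ph = ph, pw = pw,
         in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

op_bn <- function(B, input, ch, momentum = 0.1, eps = 1e-5) {
  add_op(B, "bn", input, gamma = rep(1, ch), beta = numeric(ch),
         rmean = numeric(ch), rvar = rep(1, ch),
         momentum = momentum, eps = eps, ch = as.integer(ch))
}

op_relu <- function(B, input) add_op(B, "relu", input)

# Fused block tail: batch-norm, optional additive skip, optional ReLU,
# optional dropout — one op, one compiled pass each way.
op_btail <- function(B, input, skip = NULL, ch, rate = 0, use_relu = TRUE,
                     momentum = 0.1, eps = 1e-5) {
  inputs <- if (is.null(skip)) input else c(input, skip)
  add_op(B, "btail", inputs, gamma = rep(1, ch), beta = numeric(ch),
         rmean = numeric(ch), rvar = rep(1, ch), momentum = momentum,
         eps = eps, ch = as.integer(ch), rate = rate, use_relu = use_relu)
}
op_dropout <- function(B, input, rate) add_op(B, "dropout", input, rate = rate)
op_pool <- function(B, input) add_op(B, "pool", input)
op_unpool <- function(B, input, from) add_op(B, "unpool", input, from = as.integer(from))
op_add <- function(B, a, b) add_op(B, "add", c(a, b))
op_chanpad <- function(B, input, in_ch, out_ch)
  add_op(B, "chanpad", input, in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
op_softmax <- function(B, input) add_op(B, "softmax", input)

# broadcast a per-channel vector over an (H, W, C, N) array
bcast_ch <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

op_forward <- function(op, ins, training, caches) {
  x <- ins[[1]]
  switch(op$type,
    conv = {
      y <- .cpp_conv_fwd(x, op$W, op$b, dim(x), op$kh, op$kw, op$dh, op$dw,
                         op$stride, op$ph, op$pw)
      list(y = y, cache = list(x = x), op = op)
    },
    bn = {
      d <- dim(x)
      if (training) {
        st <- .cpp_bn_stats(x, d)
        m <- prod(d[c(1, 2, 4)])
        op$rmean <- (1 - op$momentum) * op$rmean + op$momentum * st$mu
        # unbiased running variance, biased batch variance for normalisation
        op$rvar <- (1 - op$momentum) * op$rvar +
          op$momentum * st$var * m / max(m - 1, 1)
        mu <- st$mu; v <- st$var
      } else { mu <- op$rmean; v <- op$rvar }
      ivar <- 1 / sqrt(v + op$eps)
      r <- .cpp_bn_apply(x, d, mu, ivar, op$gamma, op$beta)
      list(y = r$y, cache = list(xhat = r$xhat, ivar = ivar, train = training),
           op = op)
    },
    relu = list(y = .cpp_relu_fwd(x), cache = NULL, op = op),
    btail = {
      d <- dim(x)
      if (training) {
        st <- .cpp_bn_stats(x, d)
        m <- prod(d[c(1, 2, 4)])
        op$rmean <- (1 - op$momentum) * op$rmean + op$momentum * st$mu
        op$rvar <- (1 - op$momentum) * op$rvar +
          op$momentum * st$var * m / max(m - 1, 1)
        mu <- st$mu; v <- st$var
      } else { mu <- op$rmean; v <- op$rvar }
      ivar <- 1 / sqrt(v + op$eps)
      skip <- if (length(op$inputs) > 1L) ins[[2]] else NULL
      rate_eff <- if (training) op$rate else 0
      r <- .cpp_btail_fwd(x, d, skip, mu, ivar, op$gamma, op$beta,
                          rate_eff, op$use_relu)
      list(y = r$y, cache = list(s = r$s, mask = r$mask, x = x, mu = mu,
                                 ivar = ivar, train = training), op = op)
    },
    dropout = {
      if (training && op$rate > 0) {
        r <- .cpp_dropout_fwd(x, op$rate)
        list(y = r$y, cache = list(mask = r$mask), op = op)
      } else list(y = x, cache = NULL, op = op)
    },
    pool = {
      r <- .cpp_maxpool(x, dim(x))
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)), op = op)
    },
    unpool = {
      idx <- caches[[op$from]]$idx
      d <- dim(x)
      y <- .cpp_maxunpool(x, idx, c(2L * d[1], 2L * d[2], d[3], d[4]))
      list(y = y, cache = list(idx = idx, indim = d), op = op)
    },
    add = list(y = ins[[1]] + ins[[2]], cache = NULL, op = op),
    chanpad = {
      d <- dim(x)
      y <- array(0, dim = c(d[1], d[2], op$out_ch, d[4]))
      y[, , seq_len(op$in_ch), ] <- x
      list(y = y, cache = NULL, op = op)
    },
    softmax = {
      d <- dim(x)
      C <- d[3]
      # stabilise then normalise across the channel dimension (channel slices
      # keep everything vectorised without aperm)
      ch <- function(a, c) a[, , c, , drop = FALSE]
      mx <- ch(x, 1)
      if (C > 1) for (c in 2:C) mx <- pmax(mx, ch(x, c))
      es <- vector("list", C)
      tot <- 0
      for (c in seq_len(C)) { es[[c]] <- exp(ch(x, c) - mx); tot <- tot + es[[c]] }
      y <- array(0, d)
      for (c in seq_len(C)) y[, , c, ] <- es[[c]] / tot
      list(y = y, cache = list(y = y), op = op)
    },
    stop("unknown op type: ", op$type)
  )
}

op_backward <- function(op, dy, cache, y) {
  switch(op$type,
    conv = {
      need_dx <- any(op$inputs != 0L)
      r <- .cpp_conv_bwd(cache$x, dy, op$W, dim(cache$x), op$kh, op$kw,
                         op$dh, op$dw, op$stride, op$ph, op$pw, need_dx)
      list(dx = list(r$dx), grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    bn = {
      d <- dim(dy)
      # s1 = channel sum of dy (= dbeta); s2 = channel sum of dy*xhat
      # (= dgamma); dx folds gamma into the compiled kernel
      s <- .cpp_bn_sums(dy, cache$xhat, d)
      dx <- .cpp_bn_bwd_dx(dy, cache$xhat, d, cache$ivar, op$gamma,
                           s$s1, s$s2, cache$train)
      list(dx = list(dx), grads = list(gamma = s$s2, beta = s$s1))
    },
    relu = list(dx = list(.cpp_relu_bwd(dy, y)), grads = NULL),
    btail = {
      r <- .cpp_btail_bwd(dy, cache$s, cache$x, dim(dy), cache$mu,
                          cache$ivar, op$gamma, cache$mask, op$use_relu,
                          length(op$inputs) > 1L, cache$train)
      dxs <- list(r$dx)
      if (length(op$inputs) > 1L) dxs[[2]] <- r$dskip
      list(dx = dxs, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    dropout = {
      if (is.null(cache)) list(dx = list(dy), grads = NULL)
      else list(dx = list(dy * cache$mask), grads = NULL)
    },
    pool = list(dx = list(.cpp_maxpool_bwd(dy, cache$idx, cache$xdim)),
                grads = NULL),
    unpool = list(dx = list(.cpp_maxunpool_bwd(dy, cache$idx, cache$indim)),
                  grads = NULL),
    add = list(dx = list(dy, dy), grads = NULL),
    chanpad = list(dx = list(dy[, , seq_len(op$in_ch), , drop = FALSE]),
                   grads = NULL),
    softmax = {
      y <- cache$y
      d <- dim(y)
      C <- d[3]
      ch <- function(a, c) a[, , c, , drop = FALSE]
      s <- 0
      for (c in seq_len(C)) s <- s + ch(dy, c) * ch(y, c)
      dx <- array(0, d)
      for (c in seq_len(C)) dx[, , c, ] <- ch(y, c) * (ch(dy, c) - s)
      list(dx = list(dx), grads = NULL)
    },
    stop("unknown op type: ", op$type)
  )
}

# Forward pass. Returns network output, per-op outputs and caches, and the
# (possibly updated, via batch-norm running statistics) model.
net_forward <- function(model, x, training = FALSE) {
  n <- length(model$ops)
  outs <- vector("list", n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    op <- model$ops[[i]]
    ins <- lapply(op$inputs, function(j) if (j == 0L) x else outs[[j]])
    r <- op_forward(op, ins, training, caches)
    outs[[i]] <- r$y
    caches[[i]] <- r$cache
    model$ops[[i]] <- r$op
  }
  list(out = outs[[model$out_op]], outs = outs, caches = caches, model = model)
}

# Backward pass from seeded gradients (named list: op id -> gradient array).
# Returns per-op parameter gradients.
net_backward <- function(model, fw, seeds) {
  n <- length(model$ops)
  darr <- vector("list", n)
  for (nm in names(seeds)) {
    id <- as.integer(nm)
    darr[[id]] <- if (is.null(darr[[id]])) seeds[[nm]]
                  else darr[[id]] + seeds[[nm]]
  }
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    if (is.null(darr[[i]])) next
    op <- model$ops[[i]]
    r <- op_backward(op, darr[[i]], fw$caches[[i]], fw$outs[[i]])
    grads[i] <- list(r$grads)
    for (k in seq_along(op$inputs)) {
      j <- op$inputs[k]
      if (j == 0L) next
      darr[[j]] <- if (is.null(darr[[j]])) r$dx[[k]] else darr[[j]] + r$dx[[k]]
    }
    darr[i] <- list(NULL)   # free memory without shrinking the list
  }
  grads
}

trainable_params <- function(op) {
  switch(op$type, conv = c("W", "b"), bn = c("gamma", "beta"),
         btail = c("gamma", "beta"), character(0))
}

adam_init <- function(model) {
  st <- vector("list", length(model$ops))
  for (i in seq_along(model$ops)) {
    op <- model$ops[[i]]
    ps <- trainable_params(op)
    if (length(ps))
      st[[i]] <- lapply(stats::setNames(ps, ps), function(p)
        list(m = op[[p]] * 0, v = op[[p]] * 0))
  }
  list(slots = st, t = 0L)
}

# One Adam update. L2 weight decay is applied to convolution weights only
# (not biases, not batch-norm affine parameters).
adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(model$ops)) {
    g <- grads[[i]]
    if (is.null(g)) next
    op <- model$ops[[i]]
    for (p in names(g)) {
      gp <- g[[p]]
      if (op$type == "conv" && p == "W" && weight_decay > 0)
        gp <- gp + weight_decay * op[[p]]
      sl <- state$slots[[i]][[p]]
      sl$m <- beta1 * sl$m + (1 - beta1) * gp
      sl$v <- beta2 * sl$v + (1 - beta2) * gp^2
      op[[p]] <- op[[p]] - lr * (sl$m / bc1) / (sqrt(sl$v / bc2) + eps)
      state$slots[[i]][[p]] <- sl
    }
    model$ops[[i]] <- op
  }
  list(model = model, state = state)
}

#' Number of trainable parameters of a model
#' @param model an `nf_model`.
#' @return integer count (convolution weights and biases, batch-norm affine
#'   parameters).
#' @export
parameter_count <- function(model) {
  sum(vapply(model$ops, function(op) {
    sum(vapply(trainable_params(op), function(p) length(op[[p]]), 0L))
  }, 0L))
}

#' Order-sensitive checksum of all trainable parameters
#' @param model an `nf_model`.
#' @return a single numeric; equal checksums for bit-identical parameters.
#' @export
param_checksum <- function(model) {
  acc <- 0
  for (op in model$ops)
    for (p in trainable_params(op)) {
      v <- as.numeric(op[[p]])
      acc <- acc + sum(v * seq_along(v)) + sum(v^2)
    }
  acc
}

# Weighted per-pixel cross-entropy on softmax probabilities.
# probs: (H, W, C, N); target: (H, W, N) integer classes in 0..C-1.
# Returns loss and the gradient wrt logits (mean-over-pixels convention).
softmax_ce <- function(probs, target, class_weights = NULL) {
  d <- dim(probs)
  C <- d[3]
  if (is.null(class_weights)) class_weights <- rep(1, C)
  tgt <- as.integer(target) + 1L
  pm <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = C)    # pixels x C
  npx <- nrow(pm)
  pt <- pm[cbind(seq_len(npx), tgt)]
  w <- class_weights[tgt]
  loss <- -sum(w * log(pmax(pt, 1e-12))) / npx
  onehot <- matrix(0, npx, C)
  onehot[cbind(seq_len(npx), tgt)] <- 1
  dl <- (pm - onehot) * w / npx
  dlogits <- aperm(array(dl, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(loss = loss, dlogits = dlogits)
}
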