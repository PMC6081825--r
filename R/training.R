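#' Training configuration
#'
#' Default optimisation settings: Adam with learning
#' rate 5e-4, L2 weight decay 2e-4, batch size 4 (a GPU-memory-driven choice
#' kept as the default), dropout for regularisation, no data augmentation and
#' no early stopping.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay_l2 L2 penalty applied to convolution weights.
#' @param batch_size samples per optimisation step.
#' @param max_epochs training epochs.
#' @param dropout_rate per-block dropout rate used when building models.
#' @param seed master seed; all shuffling, dropout and initialisation derive
#'   from it.
#' @param loss loss identifier; `"cross_entropy"` is the only option.
#' @param class_weights optional per-class loss weights (length =
#'   out_classes), e.g. inverse class frequencies for thin boundary targets.
#' @param boundary_thickness boundary-target half-width in pixels (Chebyshev).
#' @return an `nf_train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay_l2 = 2e-4,
                         batch_size = 4L, max_epochs = 100L,
                         dropout_rate = 0.1, seed = 1L,
                         loss = "cross_entropy", class_weights = NULL,
                         boundary_thickness = 2L) {
  stopifnot(learning_rate >= 0, weight_decay_l2 >= 0, batch_size >= 1L,
            max_epochs >= 0L, dropout_rate >= 0, dropout_rate < 1,
            identical(loss, "cross_entropy"), boundary_thickness >= 1L)
  structure(list(learning_rate = learning_rate,
                 weight_decay_l2 = weight_decay_l2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 dropout_rate = dropout_rate, seed = as.integer(seed),
                 loss = loss, class_weights = class_weights,
                 boundary_thickness = as.integer(boundary_thickness)),
            class = "nf_train_config")
}

#' Boundary targets computed from an instance mask
#'
#' A pixel is boundary iff it lies inside some instance and a pixel with a
#' different label (another instance or background) exists within `thickness`
#' in Chebyshev distance. Contact lines between touching instances are
#' therefore always marked on both sides — exactly the perceptual boundaries
#' the boundary network is meant to learn.
#'
#' @param mask integer label matrix (0 = background).
#' @param thickness boundary half-width in pixels, >= 1.
#' @return logical matrix.
#' @export
boundary_from_mask <- function(mask, thickness = 2L) {
  stopifnot(thickness >= 1L)
  H <- nrow(mask); W <- ncol(mask)
  t <- as.integer(thickness)
  # pad with background so image borders count as label changes
  pm <- matrix(0L, H + 2L * t, W + 2L * t)
  pm[t + (1:H), t + (1:W)] <- mask
  bnd <- matrix(FALSE, H, W)
  for (dr in -t:t)
    for (dc in -t:t) {
      if (dr == 0L && dc == 0L) next
      nb <- pm[t + dr + (1:H), t + dc + (1:W)]
      bnd <- bnd | (mask > 0L & nb != mask)
    }
  bnd
}

# stack same-shaped arrays along a new trailing dimension (column-major)
stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  if (is.null(d)) d <- length(lst[[1]])
  array(unlist(lst, use.names = FALSE), dim = c(d, length(lst)))
}

as_input_array <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

#' Train a segmentation model
#'
#' Adam steps with the configured hyperparameters over shuffled mini-batches;
#' per-pixel (optionally class-weighted) cross-entropy on the softmax output.
#' Fully seeded: identical configs and data give identical loss histories and
#' parameter checksums on one device.
#'
#' @param model an `nf_model` from [build_symmetric()] or [build_enet()].
#' @param inputs list of H x W matrices or H x W x C arrays.
#' @param targets list of integer H x W matrices of class ids in
#'   0..out_classes-1 (for multitask models: list of lists with `region` and
#'   `boundary` targets).
#' @param config an [train_config()].
#' @return list with `model` (trained) and `history` (per-epoch mean loss).
#' @export
train_model <- function(model, inputs, targets, config = train_config()) {
  stopifnot(inherits(model, "nf_model"), length(inputs) == length(targets),
            config$batch_size <= length(inputs))
  inputs <- lapply(inputs, as_input_array)
  n <- length(inputs)
  state <- adam_init(model)
  history <- numeric(0)
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1L, n)]
        x <- stack_batch(inputs[take])
        fw <- net_forward(model, x, training = TRUE)
        model <- fw$model
        if (model$multitask) {
          tr <- stack_batch(lapply(targets[take], `[[`, "region"))
          tb <- stack_batch(lapply(targets[take], `[[`, "boundary"))
          lr_ <- softmax_ce(fw$outs[[model$out_op]], tr, config$class_weights)
          lb_ <- softmax_ce(fw$outs[[model$out_op2]], tb, config$class_weights)
          loss <- lr_$loss + lb_$loss
          seeds <- stats::setNames(list(lr_$dlogits, lb_$dlogits),
                                   c(model$logits_op, model$logits_op2))
        } else {
          t <- stack_batch(targets[take])
          l <- softmax_ce(fw$out, t, config$class_weights)
          loss <- l$loss
          seeds <- stats::setNames(list(l$dlogits), model$logits_op)
        }
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch,
               " (exploding gradients? lower the learning rate)")
        grads <- net_backward(model, fw, seeds)
        st <- adam_step(model, grads, state, lr = config$learning_rate,
                        weight_decay = config$weight_decay_l2)
        model <- st$model
        state <- st$state
        losses <- c(losses, loss)
      }
      history <- c(history, mean(losses))
    }
  })
  list(model = model, history = history)
}

scene_input <- function(scene, input_mode = c("cd", "rgb"),
                        stains = stain_matrix()) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "cd") nuclear_channel(scene$image, stains)
  else scene$image / 255
}

build_family <- function(family, n_modules, in_channels, dropout_rate, seed) {
  if (family == "enet")
    build_enet(in_channels = in_channels, dropout_rate = dropout_rate,
               seed = seed)
  else
    build_symmetric(n_modules, in_channels = in_channels,
                    dropout_rate = dropout_rate, seed = seed)
}

#' Train the three-network fusion model
#'
#' Stage 1 trains the region network (target: instance mask > 0) and the
#' boundary network (target: [boundary_from_mask()]) independently, with seeds
#' `config$seed` and `config$seed + 1`. Stage 2 freezes both, runs them over
#' the training scenes, stacks the two foreground-probability maps as a
#' 2-channel input, and trains the fusion network (same family, seed
#' `config$seed + 2`) against the region target with the same optimisation
#' parameters.
#'
#' @param scenes list of `nf_scene` training scenes.
#' @param family `"symmetric"` or `"enet"` — used for all three networks.
#' @param n_modules module count for the symmetric family.
#' @param config an [train_config()].
#' @param input_mode `"cd"` (colour-decomposed nuclear channel, 1 input
#'   channel) or `"rgb"` (3 channels).
#' @param stains stain matrix for the colour decomposition front-end.
#' @return an `nf_fusion_model`: list with trained `region`, `boundary` and
#'   `fusion` models and the three loss histories.
#' @export
train_fusion <- function(scenes, family = c("symmetric", "enet"),
                         n_modules = 3L, config = train_config(),
                         input_mode = "cd", stains = stain_matrix()) {
  family <- match.arg(family)
  inputs <- lapply(scenes, scene_input, input_mode = input_mode,
                   stains = stains)
  in_ch <- if (input_mode == "cd") 1L else 3L
  region_t <- lapply(scenes, function(s) (s$mask > 0L) * 1L)
  bound_t <- lapply(scenes, function(s)
    boundary_from_mask(s$mask, config$boundary_thickness) * 1L)

  run_stage <- function(stage, model, targets, cfg) {
    tryCatch(train_model(model, inputs, targets, cfg),
             error = function(e) stop("fusion stage '", stage, "' failed: ",
                                      conditionMessage(e)))
  }
  cfg_r <- config; cfg_r$seed <- config$seed
  cfg_b <- config; cfg_b$seed <- config$seed + 1L
  cfg_f <- config; cfg_f$seed <- config$seed + 2L

  region <- run_stage("region",
    build_family(family, n_modules, in_ch, config$dropout_rate, cfg_r$seed),
    region_t, cfg_r)
  boundary <- run_stage("boundary",
    build_family(family, n_modules, in_ch, config$dropout_rate, cfg_b$seed),
    bound_t, cfg_b)

  # stage 2: frozen upstream nets produce the 2-channel fusion input
  fusion_in <- lapply(inputs, function(x) {
    pr <- forward(region$model, as_input_array(x))
    pb <- forward(boundary$model, as_input_array(x))
    array(c(pr[, , 2L], pb[, , 2L]), dim = c(dim(pr)[1:2], 2L))
  })
  fusion_model <- build_family(family, n_modules, 2L, config$dropout_rate,
                               cfg_f$seed)
  fusion <- tryCatch(train_model(fusion_model, fusion_in, region_t, cfg_f),
                     error = function(e) stop("fusion stage 'fusion' failed: ",
                                              conditionMessage(e)))
  structure(list(region = region$model, boundary = boundary$model,
                 fusion = fusion$model,
                 history = list(region = region$history,
                                boundary = boundary$history,
                                fusion = fusion$history),
                 input_mode = input_mode, stains = stains),
            class = "nf_fusion_model")
}

#' Train a multitask model (shared trunk, two output heads)
#'
#' One encoder-decoder trunk with two 1x1 output heads predicting the region
#' and boundary maps in a single pass; per-head cross-entropy losses are
#' summed. The comparator to network fusion: the trunk parameters are shared
#' across tasks.
#'
#' @inheritParams train_fusion
#' @return list with `model` (an `nf_model` with `multitask = TRUE`) and
#'   `history`.
#' @export
train_multitask <- function(scenes, family = c("symmetric", "enet"),
                            n_modules = 3L, config = train_config(),
                            input_mode = "cd", stains = stain_matrix()) {
  family <- match.arg(family)
  in_ch <- if (input_mode == "cd") 1L else 3L
  model <- build_multitask(family, n_modules, in_ch, config$dropout_rate,
                           config$seed)
  inputs <- lapply(scenes, scene_input, input_mode = input_mode,
                   stains = stains)
  targets <- lapply(scenes, function(s)
    list(region = (s$mask > 0L) * 1L,
         boundary = boundary_from_mask(s$mask, config$boundary_thickness) * 1L))
  train_model(model, inputs, targets, config)
}

#' @rdname train_multitask
#' @param in_channels trunk input channels.
#' @param dropout_rate,seed see [build_symmetric()].
#' @export
build_multitask <- function(family = c("symmetric", "enet"), n_modules = 3L,
                            in_channels = 1L, dropout_rate = 0.1, seed = 1L) {
  family <- match.arg(family)
  base <- build_family(family, n_modules, in_channels, dropout_rate, seed)
  # replace the single head by two 1x1 heads fed by the trunk output
  trunk_end <- base$ops[[base$logits_op]]$inputs[1]
  trunk_ch <- base$ops[[base$logits_op]]$in_ch
  B <- new_builder()
  B$ops <- base$ops[seq_len(base$logits_op - 1L)]
  with_seed(seed + 1000L, {
    l1 <- op_conv(B, trunk_end, trunk_ch, base$out_classes, 1L, 1L)
    s1 <- op_softmax(B, l1)
    l2 <- op_conv(B, trunk_end, trunk_ch, base$out_classes, 1L, 1L)
    s2 <- op_softmax(B, l2)
  })
  m <- base
  m$ops <- B$ops
  m$logits_op <- l1; m$out_op <- s1
  m$logits_op2 <- l2; m$out_op2 <- s2
  m$multitask <- TRUE
  m$trunk_ops <- seq_len(base$logits_op - 1L)
  m
}
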