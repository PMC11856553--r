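# Classifier handles: the access contract the attribution methods interrogate.
# A handle wraps a differentiable scorer and exposes forward scores, input
# gradients (plain or guided), and named-layer activations/gradients. Two
# flavours exist: handles backed by the built-in CNN engine (full contract)
# and custom handles wrapping user-supplied forward/gradient closures (used
# for analytically tractable scorers).

#' Wrap a custom differentiable scorer as a classifier handle
#'
#' Builds a [ClassifierHandle] around user-supplied closures. Perturbation
#' methods (occlusion, feature ablation) only need `forward`; gradient
#' methods additionally need `input_gradient`. Capabilities that are not
#' supplied raise an error when a method requires them.
#'
#' @param forward function(image) returning a numeric score vector, one score
#'   per class (deterministic).
#' @param input_gradient optional function(image, target) returning the
#'   gradient of the target-class score with respect to every input value,
#'   same shape as the image.
#' @param input_size integer (H, W) the scorer expects.
#' @param n_classes number of classes scored.
#' @param in_channels input channels the scorer expects.
#' @return an object of class `xaiseg_handle`.
#' @export
classifier_handle <- function(forward, input_gradient = NULL,
                              input_size, n_classes = 2L, in_channels = 1L) {
  stopifnot(is.function(forward))
  structure(list(kind = "custom", forward = forward,
                 input_gradient = input_gradient,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 guided_supported = FALSE),
            class = "xaiseg_handle")
}

new_nn_handle <- function(net, n_classes) {
  structure(list(kind = "nn", net = net,
                 input_size = net$input_size,
                 n_classes = as.integer(n_classes),
                 in_channels = net$in_channels,
                 guided_supported = TRUE),
            class = "xaiseg_handle")
}

#' Build the small convolutional test backbone
#'
#' A four-stage convolutional network (3x3 convolutions, ReLU, 2x2 max
#' pooling per stage) followed by global average pooling and a linear
#' classification head. It exposes named stages `conv1..conv4` (pre-ReLU),
#' `relu1..relu4` (rectified feature maps) and `fc` (class scores), which is
#' the access every attribution method needs, while training in seconds on
#' phantom data. Weight initialisation is seeded and fully deterministic.
#'
#' @param input_size integer (H, W); must be divisible by 2^4. Default 64x64:
#'   large enough for the phantom tumours to span many feature-map cells,
#'   small enough for desk-scale training.
#' @param in_channels input image channels (medical slices are single
#'   channel; 3 replicates grayscale input on demand).
#' @param channels feature channels of the four stages.
#' @param n_classes size of the classification head (the adaptation step
#'   replaces it, mirroring the take-a-pretrained-backbone workflow).
#' @param seed RNG seed for weight initialisation.
#' @return an `xaiseg_net` backbone, to be passed to [adapt_backbone()].
#' @export
tiny_cnn_backbone <- function(input_size = c(64L, 64L), in_channels = 1L,
                              channels = c(8L, 16L, 32L, 32L),
                              n_classes = 1000L, seed = 42L) {
  input_size <- as.integer(input_size)
  n_stages <- length(channels)
  if (any(input_size %% 2L^n_stages != 0L) || any(input_size < 2L^n_stages))
    stop(sprintf("input_size must be a multiple of %d", 2L^n_stages),
         call. = FALSE)
  with_rng_seed(seed, {
    layers <- list()
    cin <- in_channels
    for (s in seq_len(n_stages)) {
      layers <- c(layers, list(
        nn_conv_layer(cin, channels[s], name = paste0("conv", s)),
        nn_relu_layer(name = paste0("relu", s)),
        nn_pool_layer()))
      cin <- channels[s]
    }
    layers <- c(layers, list(nn_gap_layer(),
                             nn_dense_layer(cin, n_classes, name = "fc")))
    nn_network(layers, input_size, in_channels, seed = seed)
  })
}

#' Adapt a classification backbone to a two-class scorer
#'
#' Replaces the final classification stage of a backbone with a freshly
#' initialised head of `n_classes` outputs; no other part of the backbone is
#' modified. Applying it to an already-adapted network is idempotent in the
#' output dimension.
#'
#' @param backbone an `xaiseg_net` (e.g. from [tiny_cnn_backbone()]) or an
#'   `xaiseg_handle` backed by one.
#' @param n_classes number of output classes (default 2: tumour vs no
#'   tumour).
#' @return a [classifier_handle()]-compatible `xaiseg_handle`.
#' @export
adapt_backbone <- function(backbone, n_classes = 2L) {
  if (inherits(backbone, "xaiseg_handle")) {
    if (backbone$kind != "nn")
      stop("cannot adapt a custom handle: no identifiable final classification stage",
           call. = FALSE)
    backbone <- backbone$net
  }
  if (!inherits(backbone, "xaiseg_net"))
    stop("backbone has no identifiable final classification stage", call. = FALSE)
  idx <- NULL
  for (li in rev(seq_along(backbone$layers)))
    if (backbone$layers[[li]]$type == "dense") { idx <- li; break }
  if (is.null(idx))
    stop("backbone has no identifiable final classification stage", call. = FALSE)
  old <- backbone$layers[[idx]]
  seed <- if (is.na(backbone$seed)) 0L else backbone$seed
  backbone$layers[[idx]] <- with_rng_seed(seed + 1L,
    nn_dense_layer(old$cin, as.integer(n_classes), name = old$name))
  new_nn_handle(backbone, n_classes)
}

#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed RNG seed governing the train/validation split and batch order.
#' @param input_size optional (H, W) override; defaults to the handle's.
#' @param val_fraction fraction of items held out for validation.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 12L, batch_size = 16L, lr = 3e-3,
                         seed = 1L, input_size = NULL, val_fraction = 0.2) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), input_size = input_size,
                 val_fraction = val_fraction),
            class = "train_config")
}

prep_input <- function(handle, image, resize = FALSE) {
  x <- as_chw_array(image)
  hw <- dim(x)[1:2]
  if (!all(hw == handle$input_size)) {
    if (!resize)
      stop(sprintf("image is %dx%d but the classifier expects %dx%d",
                   hw[1], hw[2], handle$input_size[1], handle$input_size[2]),
           call. = FALSE)
    x <- resize_image(x, handle$input_size, kind = "bilinear")
    x <- as_chw_array(x)
  }
  as_chw_array(x, handle$in_channels)
}

#' Forward scores of a classifier handle
#'
#' @param handle an `xaiseg_handle`.
#' @param image matrix or (H, W, C) array matching the handle's input size.
#' @return numeric vector of per-class scores (logits).
#' @export
clf_scores <- function(handle, image) {
  if (handle$kind == "custom") return(handle$forward(image))
  nn_forward(handle$net, prep_input(handle, image))$scores
}

#' Gradient of a class score with respect to the input
#'
#' With `guided = TRUE` every rectifier's backward pass transmits gradient
#' only where the forward pre-activation is strictly positive AND the
#' incoming gradient is strictly positive (ties at exactly zero block).
#' With `guided = FALSE` this is plain backpropagation.
#'
#' @inheritParams clf_scores
#' @param target class index in `0:(n_classes-1)`.
#' @param guided use the guided-backpropagation rectifier rule.
#' @return array with the shape of the (channel-expanded) input.
#' @export
clf_input_gradient <- function(handle, image, target, guided = FALSE) {
  check_target(handle, target)
  if (handle$kind == "custom") {
    if (guided)
      stop("this handle does not support guided mode", call. = FALSE)
    if (is.null(handle$input_gradient))
      stop("this handle does not expose input gradients", call. = FALSE)
    return(handle$input_gradient(image, target))
  }
  fw <- nn_forward(handle$net, prep_input(handle, image))
  dout <- numeric(length(fw$scores)); dout[target + 1L] <- 1
  nn_backward(handle$net, fw$caches, dout, guided = guided)$dx
}

#' Activations and gradients of a named internal layer
#'
#' @inheritParams clf_input_gradient
#' @param layer stage name (see [layer_names()]).
#' @return list with `activation` (the layer output) and `gradient` (the
#'   gradient of the target-class score with respect to that output).
#' @export
clf_layer <- function(handle, image, target, layer) {
  check_nn(handle); check_target(handle, target)
  li <- nn_layer_index(handle$net, layer)
  fw <- nn_forward(handle$net, prep_input(handle, image))
  dout <- numeric(length(fw$scores)); dout[target + 1L] <- 1
  bw <- nn_backward(handle$net, fw$caches, dout)
  list(activation = fw$caches[[li]]$out, gradient = bw$layer_grads[[layer]])
}

#' Gradient of a single internal activation with respect to the input
#'
#' @inheritParams clf_scores
#' @param neuron list with `layer` (stage name) and either `index` (for
#'   vector-valued layers such as `fc`) or `channel`, `row`, `col` (for
#'   feature maps); all 1-based.
#' @return array with the shape of the input.
#' @export
clf_neuron_gradient <- function(handle, image, neuron) {
  check_nn(handle)
  li <- nn_layer_index(handle$net, neuron$layer)
  fw <- nn_forward(handle$net, prep_input(handle, image))
  out <- fw$caches[[li]]$out
  dout <- array(0, dim = if (is.null(dim(out))) length(out) else dim(out))
  if (is.null(dim(out))) {
    idx <- neuron$index
    if (is.null(idx) || idx < 1L || idx > length(out))
      stop("neuron index outside layer shape", call. = FALSE)
    dout[idx] <- 1
  } else {
    d <- dim(out)
    if (is.null(neuron$channel) || is.null(neuron$row) || is.null(neuron$col) ||
        neuron$row < 1L || neuron$row > d[1] ||
        neuron$col < 1L || neuron$col > d[2] ||
        neuron$channel < 1L || neuron$channel > d[3])
      stop("neuron index outside layer shape", call. = FALSE)
    dout[neuron$row, neuron$col, neuron$channel] <- 1
  }
  dout <- if (is.null(dim(out))) as.numeric(dout) else dout
  nn_backward(handle$net, fw$caches, dout, from = li)$dx
}

#' Named stages of a handle's network
#' @param handle an `xaiseg_handle` backed by the CNN engine.
#' @return character vector of stage names.
#' @export
layer_names <- function(handle) {
  check_nn(handle)
  nn_layer_names(handle$net)
}

check_nn <- function(handle) {
  if (!inherits(handle, "xaiseg_handle") || handle$kind != "nn")
    stop("this operation needs a handle with internal-layer access", call. = FALSE)
}

check_target <- function(handle, target) {
  if (!is.numeric(target) || length(target) != 1L ||
      target < 0L || target >= handle$n_classes)
    stop(sprintf("target class must be in 0..%d", handle$n_classes - 1L),
         call. = FALSE)
}

#' Predict the class of an image
#'
#' Images that do not match the handle's input size are resized bilinearly.
#' Ties in the score vector break toward the lowest class index (class 0).
#'
#' @inheritParams clf_scores
#' @return list with `class` (0-based) and `scores`.
#' @export
clf_predict <- function(handle, image) {
  s <- clf_scores(handle, if (handle$kind == "nn")
    prep_input(handle, image, resize = TRUE) else image)
  list(class = which.max(s) - 1L, scores = s)
}

# ---- training ---------------------------------------------------------------

softmax_ce <- function(scores, y) {
  z <- scores - max(scores)
  p <- exp(z) / sum(exp(z))
  list(loss = -log(max(p[y + 1L], 1e-12)), dscores = { d <- p; d[y + 1L] <- d[y + 1L] - 1; d })
}

#' Train a two-class classifier handle on phantoms
#'
#' Minimises softmax cross-entropy with Adam. The train/validation split,
#' batch order and all arithmetic are deterministic given `config$seed`, so
#' two runs produce identical losses. Images are resized bilinearly to the
#' handle's input size when needed.
#'
#' @param handle an adapted `xaiseg_handle` (see [adapt_backbone()]).
#' @param phantoms list of phantoms (from [generate_phantom()] /
#'   [generate_dataset()]) or any list of items with `image` and `label`.
#' @param config a [train_config()].
#' @return list with `handle` (trained), `log` (data.frame: epoch,
#'   train_acc, val_acc, train_loss, val_loss).
#' @export
train_classifier <- function(handle, phantoms, config = train_config()) {
  check_nn(handle)
  labels <- vapply(phantoms, function(p) as.integer(p$label), 1L)
  if (length(unique(labels)) < 2L)
    stop("training requires examples of both classes", call. = FALSE)
  xs <- lapply(phantoms, function(p) prep_input(handle, p$image, resize = TRUE))

  net <- handle$net
  with_rng_seed(config$seed, {
    n <- length(xs)
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)

    # Adam state per parameterised layer
    state <- lapply(net$layers, function(l)
      if (l$type %in% c("conv", "dense"))
        list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L

    eval_split <- function(idx) {
      if (!length(idx)) return(c(acc = NA_real_, loss = NA_real_))
      acc <- 0; loss <- 0
      for (i in idx) {
        s <- nn_forward(net, xs[[i]])$scores
        acc <- acc + as.integer((which.max(s) - 1L) == labels[i])
        loss <- loss + softmax_ce(s, labels[i])$loss
      }
      c(acc = acc / length(idx), loss = loss / length(idx))
    }

    log <- data.frame(epoch = integer(), train_acc = numeric(),
                      val_acc = numeric(), train_loss = numeric(),
                      val_loss = numeric())
    for (ep in seq_len(config$epochs)) {
      order_idx <- sample(train_idx)
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
      for (batch in batches) {
        grads <- NULL
        for (i in batch) {
          fw <- nn_forward(net, xs[[i]])
          d <- softmax_ce(fw$scores, labels[i])$dscores
          bw <- nn_backward(net, fw$caches, d, params = TRUE)
          if (is.null(grads)) grads <- bw$param_grads
          else for (li in seq_along(grads))
            if (!is.null(grads[[li]])) {
              grads[[li]]$dW <- grads[[li]]$dW + bw$param_grads[[li]]$dW
              grads[[li]]$db <- grads[[li]]$db + bw$param_grads[[li]]$db
            }
        }
        t <- t + 1L
        for (li in seq_along(net$layers)) {
          if (is.null(grads[[li]])) next
          gW <- grads[[li]]$dW / length(batch)
          gb <- grads[[li]]$db / length(batch)
          st <- state[[li]]
          st$mW <- b1 * st$mW + (1 - b1) * gW; st$vW <- b2 * st$vW + (1 - b2) * gW^2
          st$mb <- b1 * st$mb + (1 - b1) * gb; st$vb <- b2 * st$vb + (1 - b2) * gb^2
          corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
          net$layers[[li]]$W <- net$layers[[li]]$W -
            config$lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
          net$layers[[li]]$b <- net$layers[[li]]$b -
            config$lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
          state[[li]] <- st
        }
      }
      tr <- eval_split(train_idx); va <- eval_split(val_idx)
      log <- rbind(log, data.frame(epoch = ep, train_acc = tr["acc"],
                                   val_acc = va["acc"], train_loss = tr["loss"],
                                   val_loss = va["loss"], row.names = NULL))
    }
    handle$net <- net
    list(handle = handle, log = log)
  })
}

#' Save / load a trained classifier checkpoint
#'
#' Single-file checkpoint with a versioned header recording the adaptation
#' and training configuration and seed.
#'
#' @param handle a trained `xaiseg_handle`.
#' @param path checkpoint file path.
#' @param config optional [train_config()] stored alongside the weights.
#' @return `path`, invisibly (for `save_classifier`); the restored handle
#'   (for `load_classifier`).
#' @export
save_classifier <- function(handle, path, config = NULL) {
  check_nn(handle)
  saveRDS(list(format = "xaiseg-checkpoint", version = 1L,
               n_classes = handle$n_classes, config = config,
               seed = handle$net$seed, net = handle$net), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "xaiseg-checkpoint"))
    stop("not an xaiseg checkpoint: ", path, call. = FALSE)
  new_nn_handle(ck$net, ck$n_classes)
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
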