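# Attribution heatmaps: gradient-based (saliency, input-x-gradient, guided
# backprop, Grad-CAM, guided Grad-CAM), perturbation-based (occlusion,
# feature ablation), plus one layer-level and one neuron-level method.
# Every input-level method yields a Heatmap: absolute attributions reduced
# over channels by maximum, then min-max normalised to [0, 1] (all-equal
# maps normalise to all zeros), which is what makes a fixed downstream
# threshold meaningful.

new_heatmap <- function(raw, method, target) {
  rng <- range(raw)
  values <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng)
            else matrix(0, nrow(raw), ncol(raw))
  structure(list(values = values, method = method,
                 target_class = as.integer(target), raw_range = rng),
            class = "xaiseg_heatmap")
}

#' @export
print.xaiseg_heatmap <- function(x, ...) {
  cat(sprintf("<heatmap> method=%s target=%d %dx%d raw_range=[%.4g, %.4g]\n",
              x$method, x$target_class, nrow(x$values), ncol(x$values),
              x$raw_range[1], x$raw_range[2]))
  invisible(x)
}

# reduce a (H, W, C) attribution array to (H, W) by max of absolute values
reduce_abs_max <- function(g) {
  if (is.matrix(g)) return(abs(g))
  a <- abs(g[, , 1L])
  if (dim(g)[3] > 1L)
    for (c in 2:dim(g)[3]) a <- pmax(a, abs(g[, , c]))
  a
}

#' Saliency map
#'
#' Absolute gradient of the target-class score with respect to the input,
#' reduced over channels by maximum and min-max normalised.
#'
#' @param handle an `xaiseg_handle`.
#' @param image input matching the handle's input size.
#' @param target 0-based class index (default 1, the tumour class: the
#'   method attributes the tumour class, not the predicted one).
#' @return an `xaiseg_heatmap`.
#' @export
saliency <- function(handle, image, target = 1L) {
  g <- clf_input_gradient(handle, image, target)
  new_heatmap(reduce_abs_max(g), "saliency", target)
}

#' Input-times-gradient map
#'
#' As [saliency()] but on `|x * dy/dx|`: the gradient weighted by the input
#' itself.
#'
#' @inheritParams saliency
#' @return an `xaiseg_heatmap`.
#' @export
input_x_gradient <- function(handle, image, target = 1L) {
  g <- clf_input_gradient(handle, image, target)
  x <- if (handle$kind == "nn") prep_input(handle, image)
       else as_chw_array(image, handle$in_channels)
  new_heatmap(reduce_abs_max(x * g), "input_x_gradient", target)
}

#' Guided backpropagation map
#'
#' Gradient computed with the guided rectifier backward rule: at every
#' rectifier, gradient passes only where the forward pre-activation is
#' strictly positive and the incoming gradient is strictly positive. On
#' rectifier-free networks this equals plain saliency.
#'
#' @inheritParams saliency
#' @return an `xaiseg_heatmap`.
#' @export
guided_backprop <- function(handle, image, target = 1L) {
  if (!isTRUE(handle$guided_supported))
    stop("this handle does not support guided mode", call. = FALSE)
  g <- clf_input_gradient(handle, image, target, guided = TRUE)
  new_heatmap(reduce_abs_max(g), "guided_backprop", target)
}

default_cam_layer <- function(handle) {
  nm <- layer_names(handle)
  relus <- grep("^relu", nm, value = TRUE)
  if (length(relus)) relus[length(relus)] else nm[length(nm) - 1L]
}

grad_cam_raw <- function(handle, image, target, layer) {
  la <- clf_layer(handle, image, target, layer)
  A <- la$activation; dA <- la$gradient
  d <- dim(A)
  alpha <- colMeans(matrix(dA, d[1] * d[2], d[3]))        # spatial mean per channel
  cam <- matrix(matrix(A, d[1] * d[2], d[3]) %*% alpha, d[1], d[2])
  cam <- pmax(cam, 0)
  resize_image(cam, handle$input_size, kind = "bilinear")
}

#' Grad-CAM localisation map
#'
#' Channel weights are the spatial means of the gradients of the target
#' score with respect to the named stage's activation maps; the weighted
#' activation sum is rectified, upsampled bilinearly to the input size and
#' normalised. Non-negative by construction.
#'
#' @inheritParams saliency
#' @param layer named stage (default: last rectified convolutional stage).
#' @return an `xaiseg_heatmap`.
#' @export
grad_cam <- function(handle, image, target = 1L, layer = NULL) {
  if (is.null(layer)) layer <- default_cam_layer(handle)
  new_heatmap(grad_cam_raw(handle, image, target, layer),
              paste0("grad_cam[", layer, "]"), target)
}

#' Guided Grad-CAM map
#'
#' Elementwise product of the pre-normalisation guided backpropagation map
#' and the pre-normalisation Grad-CAM map, then normalised: the localisation
#' of Grad-CAM with the pixel detail of guided backprop.
#'
#' @inheritParams grad_cam
#' @return an `xaiseg_heatmap`.
#' @export
guided_grad_cam <- function(handle, image, target = 1L, layer = NULL) {
  if (!isTRUE(handle$guided_supported))
    stop("this handle does not support guided mode", call. = FALSE)
  if (is.null(layer)) layer <- default_cam_layer(handle)
  gb <- reduce_abs_max(clf_input_gradient(handle, image, target, guided = TRUE))
  cam <- grad_cam_raw(handle, image, target, layer)
  new_heatmap(gb * cam, paste0("guided_grad_cam[", layer, "]"), target)
}

#' Occlusion configuration
#'
#' @param window (h, w) occlusion window in pixels.
#' @param stride (h, w) window step.
#' @param baseline fill value replacing occluded pixels.
#' @return list of class `occlusion_config`.
#' @export
occlusion_config <- function(window = c(16L, 16L), stride = c(8L, 8L),
                             baseline = 0) {
  window <- rep(as.integer(window), length.out = 2L)
  stride <- rep(as.integer(stride), length.out = 2L)
  if (any(window < 1L) || any(stride < 1L))
    stop("window and stride must be >= 1", call. = FALSE)
  structure(list(window = window, stride = stride, baseline = baseline),
            class = "occlusion_config")
}

#' Occlusion sensitivity map
#'
#' Slides a window over the image; at each placement the window (all
#' channels) is replaced by the baseline value and the drop in the target
#' score is recorded. Each pixel's raw attribution is the mean drop over all
#' placements covering it (pixels covered by none get 0).
#'
#' @inheritParams saliency
#' @param config an [occlusion_config()].
#' @return an `xaiseg_heatmap`.
#' @export
occlusion <- function(handle, image, target = 1L, config = occlusion_config()) {
  check_target(handle, target)
  x <- if (handle$kind == "nn") prep_input(handle, image)
       else as_chw_array(image, handle$in_channels)
  H <- dim(x)[1]; W <- dim(x)[2]
  wh <- config$window[1]; ww <- config$window[2]
  if (wh > H || ww > W)
    stop("occlusion window larger than the image", call. = FALSE)
  score0 <- clf_scores(handle, x)[target + 1L]
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (r0 in seq(1L, H - wh + 1L, by = config$stride[1])) {
    for (c0 in seq(1L, W - ww + 1L, by = config$stride[2])) {
      xo <- x
      xo[r0:(r0 + wh - 1L), c0:(c0 + ww - 1L), ] <- config$baseline
      delta <- score0 - clf_scores(handle, xo)[target + 1L]
      acc[r0:(r0 + wh - 1L), c0:(c0 + ww - 1L)] <-
        acc[r0:(r0 + wh - 1L), c0:(c0 + ww - 1L)] + delta
      cnt[r0:(r0 + wh - 1L), c0:(c0 + ww - 1L)] <-
        cnt[r0:(r0 + wh - 1L), c0:(c0 + ww - 1L)] + 1
    }
  }
  raw <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  new_heatmap(raw, "occlusion", target)
}

#' Feature ablation map
#'
#' Occlusion generalised to arbitrary pixel groups: every pixel of group g
#' receives the score drop observed when the whole group is set to the
#' baseline. With single-pixel groups this equals occlusion with a 1x1
#' window and stride 1.
#'
#' @inheritParams saliency
#' @param groups integer matrix (H, W) labelling the pixel groups.
#' @param baseline fill value for ablated groups.
#' @return an `xaiseg_heatmap`.
#' @export
feature_ablation <- function(handle, image, target = 1L, groups, baseline = 0) {
  check_target(handle, target)
  x <- if (handle$kind == "nn") prep_input(handle, image)
       else as_chw_array(image, handle$in_channels)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (!is.matrix(groups) || !all(dim(groups) == c(H, W)))
    stop("groups must be an (H, W) label matrix", call. = FALSE)
  labs <- sort(unique(as.vector(groups)))
  if (length(labs) < 1L || anyNA(labs))
    stop("groups must contain at least one non-missing label", call. = FALSE)
  score0 <- clf_scores(handle, x)[target + 1L]
  raw <- matrix(0, H, W)
  for (g in labs) {
    sel <- groups == g
    xo <- x
    for (c in seq_len(dim(x)[3])) {
      plane <- xo[, , c]; plane[sel] <- baseline; xo[, , c] <- plane
    }
    raw[sel] <- score0 - clf_scores(handle, xo)[target + 1L]
  }
  new_heatmap(raw, "feature_ablation", target)
}

#' Layer gradient-times-activation attribution
#'
#' Per-channel maps `A_k * dy/dA_k` at the named stage's native resolution.
#' No automatic channel reduction is applied: channel selection is explicit
#' (the practical limitation of layer-level methods), via [as_heatmap()].
#'
#' @inheritParams grad_cam
#' @return a `layer_attribution`: `channels` (h, w, K array), `layer`,
#'   `selected_channel`.
#' @export
layer_gradient_x_activation <- function(handle, image, target = 1L, layer) {
  la <- clf_layer(handle, image, target, layer)
  structure(list(channels = la$activation * la$gradient, layer = layer,
                 target_class = as.integer(target), selected_channel = NULL),
            class = "layer_attribution")
}

#' Convert one channel of a layer attribution to a heatmap
#'
#' @param x a `layer_attribution`.
#' @param channel 1-based channel index.
#' @param ... unused.
#' @return an `xaiseg_heatmap` (absolute values, min-max normalised) at the
#'   layer's native resolution.
#' @export
as_heatmap <- function(x, ...) UseMethod("as_heatmap")

#' @rdname as_heatmap
#' @export
as_heatmap.layer_attribution <- function(x, channel, ...) {
  K <- dim(x$channels)[3]
  if (channel < 1L || channel > K)
    stop(sprintf("channel must be in 1..%d", K), call. = FALSE)
  new_heatmap(abs(x$channels[, , channel]),
              sprintf("layer_gradient_x_activation[%s:%d]", x$layer, channel),
              x$target_class)
}

#' Neuron gradient map
#'
#' Absolute gradient of a single internal activation with respect to the
#' input, reduced and normalised as saliency. Addressing the target-class
#' output unit reproduces saliency exactly.
#'
#' @inheritParams saliency
#' @param neuron list with `layer` and either `index` (vector layers) or
#'   `channel`, `row`, `col` (feature maps); 1-based.
#' @return an `xaiseg_heatmap`.
#' @export
neuron_gradient <- function(handle, image, neuron) {
  g <- clf_neuron_gradient(handle, image, neuron)
  new_heatmap(reduce_abs_max(g), sprintf("neuron_gradient[%s]", neuron$layer),
              if (identical(neuron$layer, "fc") && !is.null(neuron$index))
                neuron$index - 1L else -1L)
}

attribution_registry <- function(handle, target, occl_config, layer = NULL) {
  if (is.null(layer) && isTRUE(handle$kind == "nn"))
    layer <- default_cam_layer(handle)
  list(
    saliency = function(img) saliency(handle, img, target),
    input_x_gradient = function(img) input_x_gradient(handle, img, target),
    guided_backprop = function(img) guided_backprop(handle, img, target),
    grad_cam = function(img) grad_cam(handle, img, target, layer),
    guided_grad_cam = function(img) guided_grad_cam(handle, img, target, layer),
    occlusion = function(img) occlusion(handle, img, target, occl_config),
    feature_ablation = function(img) {
      hw <- dim(as_chw_array(img))[1:2]
      # default grouping: occlusion-window-sized tiles
      gr <- outer(ceiling(seq_len(hw[1]) / occl_config$window[1]),
                  ceiling(seq_len(hw[2]) / occl_config$window[2]),
                  function(a, b) (a - 1) * 10000 + b)
      feature_ablation(handle, img, target, gr, occl_config$baseline)
    })
}

#' Benchmark attribution methods
#'
#' Times each requested method on one image and reports the median
#' wall-clock seconds over `repeats` runs. Absolute values are
#' hardware-dependent and are reported, never asserted.
#'
#' @inheritParams saliency
#' @param methods character vector of method names (see
#'   [attribution_methods()]).
#' @param repeats timing repetitions per method.
#' @param config an [occlusion_config()] used by the perturbation methods.
#' @param file optional CSV output path.
#' @return data.frame (method, seconds), sorted ascending by time.
#' @export
benchmark_methods <- function(handle, image, methods = attribution_methods(),
                              repeats = 3L, target = 1L,
                              config = occlusion_config(), file = NULL) {
  if (length(methods) < 1L) stop("no methods given", call. = FALSE)
  reg <- attribution_registry(handle, target, config)
  unknown <- setdiff(methods, names(reg))
  if (length(unknown))
    stop("unknown method(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  secs <- vapply(methods, function(m) {
    stats::median(vapply(seq_len(repeats), function(i)
      system.time(reg[[m]](image))[["elapsed"]], 0))
  }, 0)
  out <- data.frame(method = methods, seconds = unname(secs),
                    stringsAsFactors = FALSE)
  out <- out[order(out$seconds), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Names of the pipeline-ready attribution methods
#' @return character vector.
#' @export
attribution_methods <- function()
  c("saliency", "input_x_gradient", "guided_backprop", "grad_cam",
    "guided_grad_cam", "occlusion", "feature_ablation")

#' Write a heatmap as an 8-bit grayscale PNG
#'
#' Pixel value = round(255 * normalised attribution).
#'
#' @param heatmap an `xaiseg_heatmap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "xaiseg_heatmap"))
  write_image_png(heatmap$values, path)
}
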