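# Shared fixtures: analytically tractable scorers, micro networks built on
# the engine's layer primitives, finite-difference oracles, and a small
# phantom configuration for fast training tests.

# phantom config scaled down for speed (64x64 slices)
small_phantom_config <- function()
  phantom_config(size = c(64L, 64L), head_axes_range = c(18, 26),
                 tumour_radius_range = c(5, 8), tumour_contrast = 0.45,
                 noise_sd = 0.05)

# drop a trailing singleton channel axis
as2d <- function(img) if (is.matrix(img)) img else matrix(img[, , 1L],
                                                          dim(img)[1],
                                                          dim(img)[2])

# custom handle: linear scorer y_1 = sum(w * x), y_0 = 0
linear_handle <- function(w) {
  classifier_handle(
    forward = function(img) c(0, sum(w * as2d(img))),
    input_gradient = function(img, target)
      array(if (target == 1L) w else 0 * w, dim = c(dim(w), 1L)),
    input_size = dim(w), n_classes = 2L)
}

# custom handle: additive scorer y_1 = sum(x)
additive_handle <- function(size)
  linear_handle(matrix(1, size[1], size[2]))

# custom handle: constant scorer
constant_handle <- function(size)
  classifier_handle(
    forward = function(img) c(0, 5),
    input_gradient = function(img, target) array(0, dim = c(size, 1L)),
    input_size = size, n_classes = 2L)

# nonlinear custom scorer (for perturbation-method oracles)
quadratic_handle <- function(size) {
  classifier_handle(
    forward = function(img) {
      x <- as2d(img)
      c(0, sum(x^2) + 0.5 * sum(x[seq_len(nrow(x) %/% 2), ]))
    },
    input_size = size, n_classes = 2L)
}

# micro network assembled from engine primitives
micro_handle <- function(layers, input_size, in_channels = 1L, n_classes = 1L) {
  net <- xaiseg:::nn_network(layers, input_size, in_channels)
  xaiseg:::new_nn_handle(net, n_classes)
}

# y = a * relu(x) on a 1x1 single-channel image
relu_scalar_handle <- function(a = 1) {
  micro_handle(list(
    xaiseg:::nn_relu_layer(),
    xaiseg:::nn_flatten_layer(),
    xaiseg:::nn_dense_layer(1L, 1L, W = matrix(a), b = 0)),
    input_size = c(1L, 1L))
}

# rectifier-free linear network y = w . x
linear_net_handle <- function(w) {
  micro_handle(list(
    xaiseg:::nn_flatten_layer(),
    xaiseg:::nn_dense_layer(length(w), 1L, W = matrix(as.numeric(w)), b = 0)),
    input_size = dim(w))
}

# y = spatial mean of the (identity) feature map named "feat"
mean_of_feature_handle <- function(size) {
  micro_handle(list(
    xaiseg:::nn_identity_layer(name = "feat"),
    xaiseg:::nn_gap_layer(),
    xaiseg:::nn_dense_layer(1L, 1L, W = matrix(1), b = 0)),
    input_size = size)
}

# random small CNN handle for oracle tests
random_cnn_handle <- function(input_size = c(16L, 16L), seed = 3L)
  adapt_backbone(tiny_cnn_backbone(input_size = input_size,
                                   channels = c(4L, 4L, 8L, 8L), seed = seed),
                 n_classes = 2L)

# central finite differences of the target score w.r.t. every pixel
fd_gradient <- function(handle, x, target, eps = 1e-5) {
  fd <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    xp <- x; xp[i, j] <- x[i, j] + eps
    xm <- x; xm[i, j] <- x[i, j] - eps
    fd[i, j] <- (clf_scores(handle, xp)[target + 1L] -
                 clf_scores(handle, xm)[target + 1L]) / (2 * eps)
  }
  fd
}

# min-max normalisation matching the heatmap contract
norm01 <- function(raw) {
  rng <- range(raw)
  if (diff(rng) == 0) matrix(0, nrow(raw), ncol(raw))
  else (raw - rng[1]) / diff(rng)
}

# independent brute-force binary dilation (nested loops)
brute_dilate <- function(m, k) {
  r <- (k - 1L) %/% 2L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] == 0) next
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
        out[ii, jj] <- 1L
    }
  }
  out
}

# independent flood fill from the border (queue-based, 4-connectivity)
brute_fill_holes <- function(m) {
  H <- nrow(m); W <- ncol(m)
  visited <- matrix(FALSE, H, W)
  queue <- list()
  for (i in seq_len(H)) for (j in seq_len(W))
    if ((i == 1 || i == H || j == 1 || j == W) && m[i, j] == 0)
      queue[[length(queue) + 1L]] <- c(i, j)
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    if (visited[p[1], p[2]]) next
    visited[p[1], p[2]] <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
          !visited[q[1], q[2]] && m[q[1], q[2]] == 0)
        queue[[length(queue) + 1L]] <- q
    }
  }
  out <- matrix(1L, H, W)
  out[m == 0 & visited] <- 0L
  out
}
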