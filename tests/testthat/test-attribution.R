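test_that("saliency of a linear scorer is the normalised |w| pattern", {
  w <- matrix(c(0, 1, -2, 4, 0.5, -1, 3, 2, 0), 3, 3)  # contains zeros
  h <- linear_handle(w)
  hm <- saliency(h, matrix(0.5, 3, 3), target = 1)
  expect_equal(hm$values, abs(w) / max(abs(w)))
  expect_equal(hm$raw_range, range(abs(w)))
})

test_that("constant scorers yield all-zero heatmaps", {
  h <- constant_handle(c(4L, 4L))
  img <- matrix(0.7, 4, 4)
  expect_true(all(saliency(h, img, 1)$values == 0))
  expect_true(all(input_x_gradient(h, img, 1)$values == 0))
  expect_true(all(occlusion(h, img, 1, occlusion_config(c(2, 2), c(1, 1)))$values == 0))
})

test_that("input-times-gradient follows |x * w| and collapses to saliency on all-ones input", {
  w <- matrix(c(0, 2, -1, 3), 2, 2)
  h <- linear_handle(w)
  expect_true(all(input_x_gradient(h, matrix(0, 2, 2), 1)$values == 0))
  x <- matrix(c(1, 0.5, 2, 0), 2, 2)
  expect_equal(input_x_gradient(h, x, 1)$values, norm01(abs(w * x)))
  ones <- matrix(1, 2, 2)
  expect_equal(input_x_gradient(h, ones, 1)$values, saliency(h, ones, 1)$values)
})

test_that("guided backprop applies the rectifier backward rule", {
  # y = relu(x): positive input passes gradient 1
  h_pos <- relu_scalar_handle(a = 1)
  g <- xaiseg:::clf_input_gradient(h_pos, matrix(2), 0, guided = TRUE)
  expect_equal(as.numeric(g), 1)
  # y = -relu(x): incoming gradient -1 is blocked
  h_neg <- relu_scalar_handle(a = -1)
  g <- xaiseg:::clf_input_gradient(h_neg, matrix(2), 0, guided = TRUE)
  expect_equal(as.numeric(g), 0)
  # pre-activation exactly 0 blocks too
  g <- xaiseg:::clf_input_gradient(h_pos, matrix(0), 0, guided = TRUE)
  expect_equal(as.numeric(g), 0)
})

test_that("guided backprop equals saliency on rectifier-free networks", {
  w <- matrix(c(1, -3, 0, 2, 5, -1), 2, 3)
  h <- linear_net_handle(w)
  x <- matrix(rnorm(6), 2, 3)
  expect_equal(guided_backprop(h, x, 0)$values, saliency(h, x, 0)$values)
})

test_that("guided backprop requires guided capability", {
  h <- additive_handle(c(2L, 2L))
  expect_error(guided_backprop(h, matrix(1, 2, 2), 1), "guided")
})

test_that("grad_cam matches its closed form on a mean-of-feature-map scorer", {
  h <- mean_of_feature_handle(c(4L, 4L))
  set.seed(31)
  x <- matrix(rnorm(16), 4, 4)  # mixed signs
  hm <- grad_cam(h, x, target = 0, layer = "feat")
  expect_equal(hm$values, pmax(x, 0) / max(pmax(x, 0)))
  expect_true(all(hm$values >= 0))

  # all-negative weighted sum rectifies to an all-zero heatmap
  xneg <- matrix(-abs(rnorm(16)), 4, 4)
  expect_true(all(grad_cam(h, xneg, 0, "feat")$values == 0))
})

test_that("grad_cam output has the input's shape for any layer resolution", {
  h <- random_cnn_handle(seed = 12)
  x <- matrix(runif(256), 16, 16)
  for (layer in c("relu1", "relu3", "relu4"))
    expect_identical(dim(grad_cam(h, x, 1, layer)$values), c(16L, 16L))
  expect_error(grad_cam(h, x, 1, "nope"), "unknown layer")
})

test_that("guided grad-cam is the normalised product of its components", {
  h <- random_cnn_handle(seed = 13)
  set.seed(41)
  x <- matrix(runif(256), 16, 16)
  gb_raw <- xaiseg:::reduce_abs_max(
    xaiseg:::clf_input_gradient(h, x, 1, guided = TRUE))
  cam_raw <- xaiseg:::grad_cam_raw(h, x, 1, "relu4")
  expect_equal(guided_grad_cam(h, x, 1, "relu4")$values, norm01(gb_raw * cam_raw))
  # zero grad-cam component annihilates the product
  if (all(cam_raw == 0)) expect_true(all(guided_grad_cam(h, x, 1, "relu4")$values == 0))
  # constant positive product normalises to all zeros (all-equal rule)
  expect_true(all(xaiseg:::new_heatmap(matrix(3, 4, 4), "m", 1)$values == 0))
})

test_that("occlusion matches hand-derived drops for an additive scorer", {
  h <- additive_handle(c(4L, 4L))
  x <- matrix(seq(0.1, 1.6, by = 0.1), 4, 4)
  # window = whole image: one placement, drop = sum(x) everywhere
  hm <- occlusion(h, x, 1, occlusion_config(c(4, 4), c(1, 1), baseline = 0))
  expect_equal(hm$raw_range, c(sum(x), sum(x)))
  expect_true(all(hm$values == 0))  # all-equal raw map normalises to zero
  # 1x1 window, stride 1: raw attribution at pixel i is x_i
  hm1 <- occlusion(h, x, 1, occlusion_config(c(1, 1), c(1, 1), baseline = 0))
  expect_equal(hm1$values, norm01(x))
  expect_equal(hm1$raw_range, range(x))
  expect_error(occlusion(h, x, 1, occlusion_config(c(8, 8), c(1, 1))),
               "larger than the image")
})

test_that("occlusion equals an independent brute-force per-window loop", {
  h <- quadratic_handle(c(8L, 8L))
  set.seed(51)
  x <- matrix(runif(64), 8, 8)
  cfg <- occlusion_config(window = c(3, 3), stride = c(2, 2), baseline = 0.1)
  hm <- occlusion(h, x, 1, cfg)
  # independent loop: explicit per-window forward calls
  base <- clf_scores(h, x)[2]
  acc <- matrix(0, 8, 8); cnt <- matrix(0, 8, 8)
  for (r in seq(1, 6, by = 2)) for (c in seq(1, 6, by = 2)) {
    xo <- x; xo[r:(r + 2), c:(c + 2)] <- 0.1
    d <- base - clf_scores(h, xo)[2]
    acc[r:(r + 2), c:(c + 2)] <- acc[r:(r + 2), c:(c + 2)] + d
    cnt[r:(r + 2), c:(c + 2)] <- cnt[r:(r + 2), c:(c + 2)] + 1
  }
  raw <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  expect_equal(hm$values, norm01(raw), tolerance = 0)
  expect_equal(hm$raw_range, range(raw), tolerance = 0)
})

test_that("feature ablation generalises occlusion", {
  h <- additive_handle(c(3L, 3L))
  x <- matrix(runif(9), 3, 3)
  # one group covering the image: drop = sum(x) everywhere
  hm <- feature_ablation(h, x, 1, groups = matrix(1L, 3, 3))
  expect_equal(hm$raw_range, c(sum(x), sum(x)))
  # single-pixel groups equal occlusion with 1x1 window, stride 1
  hq <- quadratic_handle(c(6L, 6L))
  set.seed(61)
  xq <- matrix(runif(36), 6, 6)
  fa <- feature_ablation(hq, xq, 1, groups = matrix(seq_len(36), 6, 6))
  oc <- occlusion(hq, xq, 1, occlusion_config(c(1, 1), c(1, 1), baseline = 0))
  expect_equal(fa$values, oc$values, tolerance = 0)
  expect_equal(fa$raw_range, oc$raw_range, tolerance = 0)
  expect_error(feature_ablation(hq, xq, 1, groups = matrix(1, 2, 2)),
               "label matrix")
})

test_that("layer attribution exposes per-channel maps at native resolution", {
  h <- random_cnn_handle(seed = 14)
  x <- matrix(runif(256), 16, 16)
  la <- layer_gradient_x_activation(h, x, 1, "conv1")
  expect_identical(dim(la$channels), c(16L, 16L, 4L))  # stage channel count
  hm <- as_heatmap(la, channel = 2)
  expect_equal(hm$values, norm01(abs(la$channels[, , 2])))
  expect_error(as_heatmap(la, channel = 99), "channel")
  # zero activations give zero maps
  la0 <- layer_gradient_x_activation(h, matrix(0, 16, 16), 1, "conv1")
  aconv <- xaiseg:::clf_layer(h, matrix(0, 16, 16), 1, "conv1")$activation
  expect_equal(la0$channels, aconv * xaiseg:::clf_layer(h, matrix(0, 16, 16), 1,
                                                        "conv1")$gradient)
})

test_that("neuron gradient of the target output unit reproduces saliency", {
  h <- random_cnn_handle(seed = 15)
  set.seed(71)
  x <- matrix(runif(256), 16, 16)
  ng <- neuron_gradient(h, x, list(layer = "fc", index = 2L))
  expect_equal(ng$values, saliency(h, x, 1)$values)
  expect_error(neuron_gradient(h, x, list(layer = "fc", index = 99L)),
               "outside layer shape")
  expect_error(neuron_gradient(h, x, list(layer = "conv1", channel = 99L,
                                          row = 1L, col = 1L)),
               "outside layer shape")
})

test_that("neuron gradient agrees with finite differences of the activation", {
  h <- random_cnn_handle(seed = 16)
  set.seed(81)
  x <- matrix(runif(256), 16, 16)
  neuron <- list(layer = "relu2", channel = 2L, row = 3L, col = 3L)
  g <- xaiseg:::clf_neuron_gradient(h, x, neuron)
  act <- function(xx) xaiseg:::clf_layer(h, xx, 1, "relu2")$activation[3, 3, 2]
  fd <- matrix(0, 16, 16); eps <- 1e-5
  for (i in 1:16) for (j in 1:16) {
    xp <- x; xp[i, j] <- x[i, j] + eps
    xm <- x; xm[i, j] <- x[i, j] - eps
    fd[i, j] <- (act(xp) - act(xm)) / (2 * eps)
  }
  expect_lt(max(abs(g[, , 1] - fd)), 1e-3)
})

test_that("benchmark produces a sorted timing table and rejects unknown methods", {
  h <- random_cnn_handle(seed = 17)
  x <- matrix(runif(256), 16, 16)
  tab <- benchmark_methods(h, x, methods = c("saliency", "guided_backprop"),
                           repeats = 2,
                           config = occlusion_config(c(4, 4), c(4, 4)))
  expect_identical(nrow(tab), 2L)
  expect_named(tab, c("method", "seconds"))
  expect_true(!is.unsorted(tab$seconds))
  expect_error(benchmark_methods(h, x, methods = "nope"), "unknown method")
  expect_error(benchmark_methods(h, x, methods = character(0)), "no methods")
})

test_that("heatmaps stay within [0,1] and reach 1 unless degenerate", {
  h <- random_cnn_handle(seed = 18)
  set.seed(91)
  for (k in 1:3) {
    x <- matrix(runif(256), 16, 16)
    for (fn in list(saliency, guided_backprop)) {
      v <- fn(h, x, 1)$values
      expect_true(all(v >= 0 & v <= 1))
      expect_true(max(v) == 1 || all(v == 0))
    }
  }
})
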