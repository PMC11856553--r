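# Minimal deterministic CNN engine: forward, exact analytic backprop,
# guided-ReLU backward mode, and named-layer access. Layers operate on
# (H, W, C) arrays; dense layers on plain numeric vectors. All arithmetic is
# double precision so gradients can be checked against central finite
# differences to tight tolerances.

#' @keywords internal
as_chw_array <- function(x, channels = NULL) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("image must be a matrix or an (H, W, C) array", call. = FALSE)
  if (!is.null(channels) && dim(x)[3] != channels) {
    if (dim(x)[3] == 1L) {
      x <- array(rep(x, channels), dim = c(dim(x)[1:2], channels))
    } else {
      stop(sprintf("image has %d channels, expected %d", dim(x)[3], channels),
           call. = FALSE)
    }
  }
  x
}

# ---- layer constructors -----------------------------------------------------

nn_conv_layer <- function(cin, cout, k = 3L, name = NULL) {
  sd <- sqrt(2 / (k * k * cin))
  list(type = "conv", name = name, k = k, cin = cin, cout = cout,
       W = matrix(stats::rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = numeric(cout))
}

nn_relu_layer <- function(name = NULL) list(type = "relu", name = name)
nn_pool_layer <- function(name = NULL) list(type = "pool", name = name)
nn_gap_layer <- function(name = NULL) list(type = "gap", name = name)
nn_flatten_layer <- function(name = NULL) list(type = "flatten", name = name)
nn_identity_layer <- function(name = NULL) list(type = "identity", name = name)

nn_dense_layer <- function(cin, cout, name = NULL, W = NULL, b = NULL) {
  if (is.null(W)) W <- matrix(stats::rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout)
  if (is.null(b)) b <- numeric(cout)
  list(type = "dense", name = name, cin = cin, cout = cout, W = W, b = b)
}

#' Assemble a network from a list of layers
#' @keywords internal
nn_network <- function(layers, input_size, in_channels = 1L, seed = NA_integer_) {
  structure(list(layers = layers, input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels), seed = seed),
            class = "xaiseg_net")
}

# ---- im2col convolution (3x3, stride 1, same padding) -----------------------

im2col <- function(xp, H, W, k) {
  C <- dim(xp)[3]
  cols <- matrix(0, k * k * C, H * W)
  r <- 1L
  for (c in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    cols[r, ] <- xp[di:(di + H - 1L), dj:(dj + W - 1L), c]
    r <- r + 1L
  }
  cols
}

conv_forward <- function(x, l) {
  H <- dim(x)[1]; W <- dim(x)[2]
  p <- (l$k - 1L) %/% 2L
  xp <- array(0, dim = c(H + 2L * p, W + 2L * p, l$cin))
  xp[(p + 1L):(p + H), (p + 1L):(p + W), ] <- x
  cols <- im2col(xp, H, W, l$k)
  out_mat <- crossprod(l$W, cols) + l$b          # (cout, H*W); b recycles by row
  out <- array(t(out_mat), dim = c(H, W, l$cout))
  list(out = out, cache = list(cols = cols, H = H, W = W, p = p))
}

conv_backward <- function(dout, l, cache) {
  H <- cache$H; W <- cache$W; p <- cache$p; k <- l$k
  dout_mat <- t(matrix(dout, H * W, l$cout))     # (cout, H*W)
  dW <- cache$cols %*% t(dout_mat)
  db <- rowSums(dout_mat)
  dcols <- l$W %*% dout_mat                      # (k*k*cin, H*W)
  dxp <- array(0, dim = c(H + 2L * p, W + 2L * p, l$cin))
  r <- 1L
  for (c in seq_len(l$cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    dxp[di:(di + H - 1L), dj:(dj + W - 1L), c] <-
      dxp[di:(di + H - 1L), dj:(dj + W - 1L), c] + matrix(dcols[r, ], H, W)
    r <- r + 1L
  }
  dx <- dxp[(p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L)
    stop("2x2 max pooling needs even spatial dimensions", call. = FALSE)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  a <- x[i1, j1, , drop = FALSE]; b <- x[i1 + 1L, j1, , drop = FALSE]
  cc <- x[i1, j1 + 1L, , drop = FALSE]; dd <- x[i1 + 1L, j1 + 1L, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out, cache = list(a = a, b = b, cc = cc, dd = dd, dims = d))
}

pool_backward <- function(dout, cache) {
  d <- cache$dims
  out <- pmax(cache$a, cache$b, cache$cc, cache$dd)
  # deterministic tie-break: first winner in scan order a, b, cc, dd
  wa <- cache$a == out
  wb <- (cache$b == out) & !wa
  wc <- (cache$cc == out) & !wa & !wb
  wd <- !wa & !wb & !wc
  dx <- array(0, dim = d)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dx[i1, j1, ] <- dout * wa
  dx[i1 + 1L, j1, ] <- dout * wb
  dx[i1, j1 + 1L, ] <- dout * wc
  dx[i1 + 1L, j1 + 1L, ] <- dout * wd
  dx
}

# ---- full network passes ----------------------------------------------------

nn_forward <- function(net, x) {
  x <- as_chw_array(x, net$in_channels)
  caches <- vector("list", length(net$layers))
  cur <- x
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    res <- switch(l$type,
      conv = conv_forward(cur, l),
      relu = list(out = pmax(cur, 0), cache = list(pre = cur)),
      pool = pool_forward(cur),
      gap = {
        d <- dim(cur)
        list(out = colMeans(matrix(cur, d[1] * d[2], d[3])),
             cache = list(dims = d))
      },
      flatten = list(out = as.numeric(cur), cache = list(dims = dim(cur))),
      identity = list(out = cur, cache = NULL),
      dense = list(out = drop(crossprod(l$W, cur)) + l$b,
                   cache = list(v = cur)),
      stop("unknown layer type: ", l$type, call. = FALSE))
    caches[[li]] <- c(res["cache"], list(out = res$out))
    cur <- res$out
  }
  list(scores = cur, caches = caches, input = x)
}

# Backpropagate `dout` from layer index `from` down to the input.
# Returns gradient w.r.t. the input, gradients w.r.t. every named layer's
# output, and (optionally) parameter gradients.
nn_backward <- function(net, caches, dout, from = length(net$layers),
                        guided = FALSE, params = FALSE) {
  layer_grads <- list()
  param_grads <- vector("list", length(net$layers))
  g <- dout
  for (li in seq(from, 1L)) {
    l <- net$layers[[li]]
    if (!is.null(l$name)) layer_grads[[l$name]] <- g
    cache <- caches[[li]]$cache
    g <- switch(l$type,
      conv = {
        res <- conv_backward(g, l, cache)
        if (params) param_grads[[li]] <- list(dW = res$dW, db = res$db)
        res$dx
      },
      relu = {
        m <- cache$pre > 0
        if (guided) m <- m & (g > 0)
        g * m
      },
      pool = pool_backward(g, cache),
      gap = {
        d <- cache$dims
        array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
      },
      flatten = array(g, dim = cache$dims),
      identity = g,
      dense = {
        if (params) param_grads[[li]] <- list(dW = outer(cache$v, g), db = g)
        drop(l$W %*% g)
      })
  }
  list(dx = g, layer_grads = layer_grads, param_grads = param_grads)
}

nn_layer_index <- function(net, name) {
  for (li in seq_along(net$layers))
    if (identical(net$layers[[li]]$name, name)) return(li)
  stop(sprintf("unknown layer '%s'; available: %s", name,
               paste(nn_layer_names(net), collapse = ", ")), call. = FALSE)
}

nn_layer_names <- function(net) {
  nm <- vapply(net$layers, function(l) if (is.null(l$name)) "" else l$name, "")
  nm[nzchar(nm)]
}
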