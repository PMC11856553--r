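# Heatmap-to-mask postprocessing: grayscale -> threshold -> connected
# component filtering/dilation -> hole filling + morphological closing ->
# convex hull fill -> binary mask, plus overlay rendering. The "faithful"
# mode reproduces the reference pipeline exactly as printed, including its
# quirks: the cluster and closing stages are computed but their results do
# not feed the final hull, which is taken over the thresholded image's
# foreground. "cleaned" mode instead hulls the filled-and-closed mask.

#' Postprocessing configuration
#'
#' Defaults are the reference pipeline's constants: threshold 0.35 on the
#' \[0,1\] grayscale heatmap, minimum cluster size 10 px, padding 2,
#' 5x5 neighbour-count kernel, 3x3 dilation, 5x5 elliptical closing kernel,
#' 4-connectivity, overlay weight 0.7.
#'
#' @param threshold grayscale cut; values `<= threshold` become background.
#' @param min_cluster_size connected components smaller than this are
#'   dropped.
#' @param pad_width zero padding around each component before the
#'   neighbour-count convolution.
#' @param neighbor_kernel side of the square ones kernel counting
#'   neighbours.
#' @param dilate_kernel side of the square dilation kernel.
#' @param close_kernel side of the elliptical closing kernel.
#' @param connectivity 4 or 8 for component labelling.
#' @param mode `"faithful"` (hull of the thresholded foreground, as printed)
#'   or `"cleaned"` (hull of the filled-and-closed mask).
#' @param overlay_alpha additive weight of the white mask in overlays.
#' @return list of class `postprocess_config`.
#' @export
postprocess_config <- function(threshold = 0.35, min_cluster_size = 10L,
                               pad_width = 2L, neighbor_kernel = 5L,
                               dilate_kernel = 3L, close_kernel = 5L,
                               connectivity = 4L,
                               mode = c("faithful", "cleaned"),
                               overlay_alpha = 0.7) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1, min_cluster_size >= 0,
            pad_width >= 0, connectivity %in% c(4L, 8L))
  for (k in c(neighbor_kernel, dilate_kernel, close_kernel))
    if (k < 1L || k %% 2L == 0L)
      stop("kernel sizes must be odd and >= 1", call. = FALSE)
  structure(list(threshold = threshold,
                 min_cluster_size = as.integer(min_cluster_size),
                 pad_width = as.integer(pad_width),
                 neighbor_kernel = as.integer(neighbor_kernel),
                 dilate_kernel = as.integer(dilate_kernel),
                 close_kernel = as.integer(close_kernel),
                 connectivity = as.integer(connectivity), mode = mode,
                 overlay_alpha = overlay_alpha),
            class = "postprocess_config")
}

#' Convert an image to grayscale in \[0, 1\]
#'
#' Four-channel input drops the alpha channel first; three-channel input is
#' converted with luminance weights (0.2125, 0.7154, 0.0721); single-channel
#' input passes through.
#'
#' @param image matrix or (H, W, C) array with C in {1, 3, 4}.
#' @return numeric matrix.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("image must be a matrix or (H, W, C) array", call. = FALSE)
  C <- dim(image)[3]; H <- dim(image)[1]; W <- dim(image)[2]
  if (C == 1L) return(matrix(image[, , 1L], H, W))
  if (C == 4L) image <- image[, , 1:3, drop = FALSE]
  if (dim(image)[3] != 3L)
    stop("unsupported channel count: ", C, call. = FALSE)
  matrix(0.2125 * image[, , 1L] + 0.7154 * image[, , 2L] +
         0.0721 * image[, , 3L], H, W)
}

#' Threshold a grayscale heatmap to a binary mask
#'
#' A pixel maps to 0 if its value is `<= threshold` (a value exactly at the
#' threshold is background) and 1 otherwise.
#'
#' @param gray numeric matrix in \[0, 1\].
#' @param config a [postprocess_config()].
#' @return integer 0/1 matrix.
#' @export
threshold_heatmap <- function(gray, config = postprocess_config()) {
  m <- matrix(0L, nrow(gray), ncol(gray))
  m[gray > config$threshold] <- 1L
  m
}

# ---- connected components (run-based union-find) ----------------------------

#' Label connected components of a binary mask
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 (edge-adjacency) or 8 (edge or corner adjacency).
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 4L) {
  H <- nrow(mask); W <- ncol(mask)
  # run-length encode each column of foreground
  runs <- list(); col_runs <- vector("list", W)
  for (j in seq_len(W)) {
    v <- mask[, j] != 0
    if (!any(v)) { col_runs[[j]] <- integer(0); next }
    d <- diff(c(0L, as.integer(v), 0L))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    ids <- length(runs) + seq_along(starts)
    for (r in seq_along(starts))
      runs[[ids[r]]] <- c(starts[r], ends[r], j)
    col_runs[[j]] <- ids
  }
  n <- length(runs)
  if (n == 0L) return(matrix(0L, H, W))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  slack <- if (connectivity == 8L) 1L else 0L
  for (j in 2:max(2L, W)) {
    if (j > W) break
    for (a in col_runs[[j - 1L]]) for (b in col_runs[[j]]) {
      ra <- runs[[a]]; rb <- runs[[b]]
      if (ra[1] <= rb[2] + slack && rb[1] <= ra[2] + slack) union(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  lab_of_root <- integer(n)
  lab_of_root[unique(roots)] <- seq_along(unique(roots))
  out <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    r <- runs[[i]]
    out[r[1]:r[2], r[3]] <- lab_of_root[roots[i]]
  }
  out
}

# ---- binary morphology (shift-accumulate; explicit border semantics) --------

shift_mat <- function(m, dr, dc, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  sr <- max(1L, 1L + dr):min(H, H + dr)
  sc <- max(1L, 1L + dc):min(W, W + dc)
  if (length(sr) && length(sc))
    out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

kernel_offsets <- function(kern) {
  c0 <- (nrow(kern) + 1L) %/% 2L
  w <- which(kern != 0, arr.ind = TRUE)
  cbind(w[, 1] - c0, w[, 2] - c0)
}

# dilation: outside the frame is background
binary_dilate <- function(m, kern) {
  off <- kernel_offsets(kern)
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- pmax(out, shift_mat(m, off[i, 1], off[i, 2], fill = 0L))
  out
}

# erosion: outside the frame is foreground (so closing has no frame artefacts)
binary_erode <- function(m, kern) {
  off <- kernel_offsets(kern)
  out <- matrix(1L, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- pmin(out, shift_mat(m, off[i, 1], off[i, 2], fill = 1L))
  out
}

square_kernel <- function(n) matrix(1L, n, n)

# inscribed-ellipse structuring element (cv-style): per row, the horizontal
# half-width is round(r * sqrt(1 - (dy/r)^2))
ellipse_kernel <- function(n) {
  r <- (n - 1) / 2
  k <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    dy <- i - 1 - r
    if (abs(dy) > r) next
    dx <- if (r > 0) round(r * sqrt(max(0, r * r - dy * dy)) / r) else 0
    k[i, (r - dx + 1):(r + dx + 1)] <- 1L
  }
  k
}

#' Filter and dilate connected components
#'
#' Components smaller than `min_cluster_size` pixels are removed. Each
#' surviving component is zero-padded, convolved with a square ones kernel
#' to obtain neighbour counts, and — whenever the neighbour-count sum
#' exceeds the component's pixel count, which holds for every non-empty
#' component — dilated with the square dilation kernel and merged into the
#' output by elementwise maximum. The always-true guard is retained for
#' fidelity with the reference pipeline.
#'
#' @param mask 0/1 matrix.
#' @param config a [postprocess_config()].
#' @return 0/1 matrix.
#' @export
process_clusters <- function(mask, config = postprocess_config()) {
  lab <- label_components(mask, config$connectivity)
  n <- max(lab)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0L) return(out)
  kern <- square_kernel(config$neighbor_kernel)
  off <- kernel_offsets(kern)
  for (id in seq_len(n)) {
    comp <- matrix(0L, nrow(mask), ncol(mask))
    comp[lab == id] <- 1L
    size <- sum(comp)
    if (size < config$min_cluster_size) next
    # neighbour counts over the zero-padded component (pad then crop ==
    # zero-fill shifts when pad_width covers the kernel radius)
    neigh <- matrix(0, nrow(mask), ncol(mask))
    for (i in seq_len(nrow(off)))
      neigh <- neigh + shift_mat(comp, off[i, 1], off[i, 2], fill = 0L)
    if (sum(neigh) > size) {
      expanded <- binary_dilate(comp, square_kernel(config$dilate_kernel))
      out <- pmax(out, expanded)
    }
  }
  out
}

#' Fill interior holes of a binary mask
#'
#' Background regions (4-connected) not reachable from the image border are
#' set to foreground. Idempotent.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix.
#' @export
fill_holes <- function(mask) {
  bg <- 1L - (mask != 0)
  lab <- label_components(bg, connectivity = 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  out <- matrix(1L, nrow(mask), ncol(mask))
  out[lab %in% border] <- 0L
  out
}

#' Fill holes then morphologically close
#'
#' Interior holes are filled, then the mask is closed (dilation followed by
#' erosion) with an elliptical structuring element of side `close_kernel`.
#'
#' @param mask 0/1 matrix.
#' @param config a [postprocess_config()].
#' @return 0/1 matrix.
#' @export
fill_and_close <- function(mask, config = postprocess_config()) {
  filled <- fill_holes(mask)
  kern <- ellipse_kernel(config$close_kernel)
  binary_erode(binary_dilate(filled, kern), kern)
}

# ---- convex hull rasterisation ----------------------------------------------

# inclusive point-in-polygon fill over integer pixel coordinates
fill_polygon <- function(shape, px, py) {
  H <- shape[1]; W <- shape[2]
  out <- matrix(0L, H, W)
  rmin <- max(1L, floor(min(py))); rmax <- min(H, ceiling(max(py)))
  cmin <- max(1L, floor(min(px))); cmax <- min(W, ceiling(max(px)))
  if (rmin > rmax || cmin > cmax) return(out)
  x <- rep(cmin:cmax, times = rmax - rmin + 1L)
  y <- rep(rmin:rmax, each = cmax - cmin + 1L)
  n <- length(px)
  inside <- logical(length(x)); onedge <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- x >= pmin(xi, xj) - 1e-9 & x <= pmax(xi, xj) + 1e-9 &
              y >= pmin(yi, yj) - 1e-9 & y <= pmax(yi, yj) + 1e-9
    onedge <- onedge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > y) != (yj > y)) &
               (x < xi + (xj - xi) * (y - yi) / (yj - yi))
    inside <- xor(inside, crosses)
    j <- i
  }
  keep <- inside | onedge
  out[cbind(y[keep], x[keep])] <- 1L
  out
}

#' Filled convex hull of a mask's foreground pixels
#'
#' With fewer than 3 foreground pixels, or a degenerate (collinear) point
#' set, the result is an all-zero mask. Otherwise the convex hull of the
#' foreground pixel coordinates is rasterised as a filled polygon whose
#' boundary pixels are included.
#'
#' @param source 0/1 matrix whose foreground seeds the hull.
#' @param shape (H, W) of the output (default: shape of `source`).
#' @return 0/1 matrix.
#' @export
convex_hull_mask <- function(source, shape = dim(source)) {
  coords <- which(source != 0, arr.ind = TRUE)
  if (nrow(coords) < 3L) return(matrix(0L, shape[1], shape[2]))
  # (row, col) -> (x = col, y = row), the plotting-coordinate flip
  x <- coords[, 2]; y <- coords[, 1]
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(matrix(0L, shape[1], shape[2]))
  px <- x[h]; py <- y[h]
  area2 <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py))
  if (area2 == 0) return(matrix(0L, shape[1], shape[2]))
  fill_polygon(shape, px, py)
}

#' Heatmap PNG to final binary mask
#'
#' Full composition: read -> drop alpha -> grayscale -> threshold -> run
#' the cluster and fill/close stages -> convex hull fill. In `"faithful"`
#' mode the hull is taken over the thresholded image's foreground (the
#' cluster/closing results are computed but do not feed it, exactly as the
#' reference pipeline does); in `"cleaned"` mode the hull is taken over the
#' filled-and-closed mask.
#'
#' @param input path to a heatmap PNG (grayscale, RGB or RGBA), or an
#'   in-memory matrix/array in \[0, 1\].
#' @param config a [postprocess_config()].
#' @return 0/1 matrix.
#' @export
process_mask <- function(input, config = postprocess_config()) {
  img <- if (is.character(input)) read_image_png(input) else input
  gray <- to_grayscale(img)
  binary <- threshold_heatmap(gray, config)
  clustered <- process_clusters(binary, config)
  closed <- fill_and_close(clustered, config)
  hull_source <- if (config$mode == "cleaned") closed else binary
  convex_hull_mask(hull_source, dim(binary))
}

#' Overlay a binary mask on an image
#'
#' The mask is resized (nearest-neighbour) to the image's shape, rendered
#' as white RGB, scaled by `overlay_alpha`, added to the 8-bit image and
#' saturated at 255.
#'
#' @param original matrix or (H, W, 3) array, in \[0, 1\] or 0..255.
#' @param mask 0/1 matrix (any resolution).
#' @param config a [postprocess_config()].
#' @return integer (H, W, 3) array in 0..255.
#' @export
overlay_mask <- function(original, mask, config = postprocess_config()) {
  if (is.matrix(original))
    original <- array(rep(original, 3L), dim = c(dim(original), 3L))
  orig255 <- if (max(original) <= 1) round(original * 255) else round(original)
  hw <- dim(orig255)[1:2]
  if (!all(dim(mask) == hw))
    mask <- resize_image(mask + 0, hw, kind = "nearest")
  out <- array(0L, dim = dim(orig255))
  add <- 255 * config$overlay_alpha * (mask != 0)
  for (c in 1:3)
    out[, , c] <- pmin(255, round(orig255[, , c] + add))
  storage.mode(out) <- "integer"
  out
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask 0/1 matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) write_image_png((mask != 0) + 0, path)
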