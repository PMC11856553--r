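# Synthetic tumour phantoms: a textured elliptical "head" region on a black
# background, optionally containing a brighter compact "tumour" blob whose
# exact pixel set is the ground-truth mask. The generator gives every
# downstream stage (training, attribution, postprocessing, evaluation) a
# fully known ground truth.

#' Phantom generator configuration
#'
#' Defaults emulate a single high-contrast imaging modality on 240x240
#' axial slices: the head fills most of the frame, the tumour is a compact
#' blob a few tens of pixels across whose added intensity clearly exceeds
#' the texture and noise amplitudes, so the tumour/no-tumour classification
#' task is separable by construction.
#'
#' @param size integer (H, W) in pixels.
#' @param head_axes_range pixel range for the head-ellipse semi-axes.
#' @param tumour_radius_range pixel range for the tumour semi-axes; the
#'   maximum (after boundary perturbation) must fit inside the smallest
#'   head axis.
#' @param tumour_contrast intensity added inside the tumour (image scale is
#'   \[0, 1\]).
#' @param noise_sd standard deviation of additive Gaussian noise, clipped to
#'   \[0, 1\] afterwards.
#' @param texture_amplitude peak amplitude of the smooth low-frequency head
#'   texture around the base intensity.
#' @param base_intensity mean head intensity before texture/noise.
#' @param boundary_amp relative amplitude of the sinusoidal radial
#'   perturbation of the tumour boundary (keeps the blob compact but not
#'   perfectly elliptical, so the convex-hull step has visible work to do).
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(size = c(240L, 240L),
                           head_axes_range = c(70, 100),
                           tumour_radius_range = c(12, 28),
                           tumour_contrast = 0.45,
                           noise_sd = 0.05,
                           texture_amplitude = 0.12,
                           base_intensity = 0.35,
                           boundary_amp = 0.15) {
  cfg <- list(size = as.integer(size), head_axes_range = head_axes_range,
              tumour_radius_range = tumour_radius_range,
              tumour_contrast = tumour_contrast, noise_sd = noise_sd,
              texture_amplitude = texture_amplitude,
              base_intensity = base_intensity, boundary_amp = boundary_amp)
  if (length(cfg$size) != 2L || any(cfg$size < 16L))
    stop("size must be (H, W) with H, W >= 16", call. = FALSE)
  if (tumour_contrast <= 0 || noise_sd < 0)
    stop("tumour_contrast must be > 0 and noise_sd >= 0", call. = FALSE)
  if (max(tumour_radius_range) * (1 + boundary_amp) >= min(head_axes_range))
    stop("invalid configuration: tumour cannot fit inside the head ellipse",
         call. = FALSE)
  if (max(head_axes_range) >= min(size) / 2)
    stop("invalid configuration: head ellipse cannot fit inside the image",
         call. = FALSE)
  structure(cfg, class = "phantom_config")
}

# Pixels inside a rotated, radially perturbed ellipse.
# amp = 0 gives the exact ellipse (u/ax)^2 + (v/ay)^2 <= 1.
ellipse_mask <- function(H, W, cx, cy, ax, ay, theta = 0,
                         amp = 0, lobes = 0L, phase = 0) {
  X <- matrix(rep(seq_len(W), each = H), H, W)   # col coordinate
  Y <- matrix(rep(seq_len(H), W), H, W)          # row coordinate
  u <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  v <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  rho <- sqrt((u / ax)^2 + (v / ay)^2)
  if (amp > 0 && lobes > 0L) {
    ang <- atan2(v / ay, u / ax)
    rho <= 1 + amp * sin(lobes * ang + phase)
  } else {
    rho <= 1
  }
}

#' Generate a single phantom slice
#'
#' Deterministic for a fixed (config, with_tumour, seed) triple. The head is
#' a filled ellipse with a smooth low-frequency intensity texture; the
#' tumour (when present) is a randomly oriented ellipse with a small
#' sinusoidal boundary perturbation, placed fully inside the head, with
#' `tumour_contrast` added to its pixels. The mask marks exactly the tumour
#' pixels; label is 1 iff a tumour was drawn.
#'
#' @param config a [phantom_config()].
#' @param with_tumour draw a tumour blob?
#' @param seed integer RNG seed (required).
#' @return a list of class `phantom`: `image` (H x W in \[0,1\]), `mask`
#'   (H x W of 0/1), `label` (0/1), `seed`, and `params` (the sampled head
#'   and tumour geometry, for independent verification).
#' @export
generate_phantom <- function(config = phantom_config(), with_tumour = TRUE,
                             seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(config, "phantom_config"))
  H <- config$size[1]; W <- config$size[2]
  with_rng_seed(seed, {
    cx <- W / 2 + stats::runif(1, -5, 5)
    cy <- H / 2 + stats::runif(1, -5, 5)
    ax <- stats::runif(1, config$head_axes_range[1], config$head_axes_range[2])
    ay <- stats::runif(1, config$head_axes_range[1], config$head_axes_range[2])
    th <- stats::runif(1, 0, pi)
    head <- ellipse_mask(H, W, cx, cy, ax, ay, th)

    # smooth low-frequency texture: three random sinusoidal plane waves
    X <- matrix(rep(seq_len(W), each = H), H, W)
    Y <- matrix(rep(seq_len(H), W), H, W)
    tex <- matrix(0, H, W)
    for (j in 1:3) {
      kx <- stats::runif(1, 0.5, 2) / W
      ky <- stats::runif(1, 0.5, 2) / H
      ph <- stats::runif(1, 0, 2 * pi)
      tex <- tex + sin(2 * pi * (kx * X + ky * Y) + ph)
    }
    tex <- tex / 3 * config$texture_amplitude
    img <- (config$base_intensity + tex) * head

    mask <- matrix(0L, H, W)
    params <- list(head = list(cx = cx, cy = cy, ax = ax, ay = ay, theta = th))
    if (with_tumour) {
      tmax <- config$tumour_radius_range[2] * (1 + config$boundary_amp)
      placed <- FALSE
      for (try in 1:50) {
        tax <- stats::runif(1, config$tumour_radius_range[1],
                            config$tumour_radius_range[2])
        tay <- stats::runif(1, config$tumour_radius_range[1],
                            config$tumour_radius_range[2])
        tth <- stats::runif(1, 0, pi)
        lobes <- sample(3:6, 1)
        phase <- stats::runif(1, 0, 2 * pi)
        # sample the centre inside the head, shrunk so the blob fits
        shrink <- 1 - tmax / min(ax, ay)
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * shrink
        tcx <- cx + rad * ax * cos(ang) * cos(th) - rad * ay * sin(ang) * sin(th)
        tcy <- cy + rad * ax * cos(ang) * sin(th) + rad * ay * sin(ang) * cos(th)
        tum <- ellipse_mask(H, W, tcx, tcy, tax, tay, tth,
                            amp = config$boundary_amp, lobes = lobes,
                            phase = phase)
        if (sum(tum) >= 1 && !any(tum & !head)) {
          mask[tum] <- 1L
          img[tum] <- img[tum] + config$tumour_contrast
          params$tumour <- list(cx = tcx, cy = tcy, ax = tax, ay = tay,
                                theta = tth, amp = config$boundary_amp,
                                lobes = lobes, phase = phase)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place a tumour inside the head; config too tight",
             call. = FALSE)
    }
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = config$noise_sd), H, W)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask,
                   label = as.integer(any(mask == 1L)), seed = as.integer(seed),
                   params = params),
              class = "phantom")
  })
}

#' Generate a phantom dataset
#'
#' Produces `floor(n * tumour_fraction)` tumour slices and the rest
#' tumour-free, in a seed-shuffled order, each generated from its own
#' derived seed. When `dir` is given, images and masks are written as 8-bit
#' grayscale PNGs named `PHANTOM_<id>_slice_<k>_modality_<m>.png` together
#' with a `manifest.csv` (columns: path, label, seed, mask_path).
#'
#' @param config a [phantom_config()].
#' @param n number of phantoms (>= 1).
#' @param tumour_fraction fraction of slices containing a tumour.
#' @param seed master RNG seed; item seeds are derived from it.
#' @param dir optional output directory for PNGs and the manifest.
#' @param modality modality index recorded in filenames.
#' @return list with `phantoms` (list of [generate_phantom()] results) and
#'   `manifest` (data.frame).
#' @export
generate_dataset <- function(config = phantom_config(), n, tumour_fraction = 0.5,
                             seed, dir = NULL, modality = 0L) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n >= 1, tumour_fraction >= 0, tumour_fraction <= 1)
  n <- as.integer(n)
  n_tum <- as.integer(floor(n * tumour_fraction))
  with_rng_seed(seed, {
    labels <- sample(c(rep(1L, n_tum), rep(0L, n - n_tum)))
    item_seeds <- sample.int(.Machine$integer.max - 1L, n)
  })
  phantoms <- vector("list", n)
  path <- character(n); mask_path <- character(n)
  for (i in seq_len(n)) {
    phantoms[[i]] <- generate_phantom(config, with_tumour = labels[i] == 1L,
                                      seed = item_seeds[i])
    base <- sprintf("PHANTOM_%03d_slice_%d_modality_%d", i, i - 1L, modality)
    path[i] <- paste0(base, ".png")
    mask_path[i] <- paste0(base, "_mask.png")
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_image_png(phantoms[[i]]$image, file.path(dir, path[i]))
      write_image_png(phantoms[[i]]$mask, file.path(dir, mask_path[i]))
    }
  }
  manifest <- data.frame(path = path, label = labels, seed = item_seeds,
                         mask_path = mask_path, stringsAsFactors = FALSE)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(phantoms = phantoms, manifest = manifest)
}
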