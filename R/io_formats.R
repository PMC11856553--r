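# Image and volume file handling: 8-bit PNG round-trips, bilinear/nearest
# resizing, and NIfTI-to-axial-PNG slicing.

#' Write a matrix or array as an 8-bit PNG
#'
#' Values are clipped to \[0, 1\] and quantised to 8 bits; binary masks
#' (0/1) therefore come back as 0/255 grayscale. Write-then-read preserves
#' the quantised values exactly.
#'
#' @param image numeric matrix (grayscale) or (H, W, 3) array (RGB) in
#'   \[0, 1\], or an integer array in 0..255.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  v <- image
  if (max(v) > 1) v <- v / 255
  v <- pmin(pmax(v, 0), 1)
  v <- round(v * 255) / 255
  png::writePNG(v, path)
  invisible(path)
}

#' Read a PNG as numeric data in \[0, 1\]
#'
#' @param path PNG file.
#' @return matrix (grayscale) or (H, W, C) array.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  img
}

#' Resize an image or mask
#'
#' Intensity images should use bilinear interpolation; binary masks must use
#' nearest-neighbour so that they remain strictly binary.
#'
#' @param image numeric matrix or (H, W, C) array.
#' @param target integer (H, W) of the output.
#' @param kind `"bilinear"` or `"nearest"`.
#' @return resized matrix/array.
#' @export
resize_image <- function(image, target, kind = c("bilinear", "nearest")) {
  kind <- match.arg(kind)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L))
    stop("target must be positive (H, W)", call. = FALSE)
  filt <- if (kind == "bilinear") "bilinear" else "none"
  if (is.matrix(image)) {
    if (all(dim(image) == target)) return(image)
    out <- EBImage::resize(EBImage::Image(t(image)), w = target[2],
                           h = target[1], filter = filt)
    t(EBImage::imageData(out))
  } else if (length(dim(image)) == 3L) {
    if (all(dim(image)[1:2] == target)) return(image)
    res <- array(0, dim = c(target, dim(image)[3]))
    for (c in seq_len(dim(image)[3]))
      res[, , c] <- resize_image(image[, , c], target, kind)
    res
  } else stop("image must be a matrix or (H, W, C) array", call. = FALSE)
}

#' Slice a NIfTI volume into axial PNGs
#'
#' Reads a 3D or 4D (4th dimension = modality) NIfTI volume, selects one
#' modality, min-max scales intensities to 8 bit per volume (preserving
#' inter-slice contrast), and writes one grayscale PNG per axial index with
#' filenames `<id>_slice_<k>_modality_<m>.png` (k and m 0-based). A
#' constant-valued volume degenerates to all-zero PNGs.
#'
#' @param volume_path path to a `.nii` / `.nii.gz` file.
#' @param modality_index 0-based modality; forced to 0 for 3D volumes.
#' @param output_dir directory for the slice PNGs (created if needed).
#' @param id volume identifier used in filenames; defaults to the file name
#'   without extensions.
#' @param axis array axis treated as axial (default 3, the third spatial
#'   axis of the data array).
#' @return data.frame of slice records: volume_id, slice_index,
#'   modality_index, path.
#' @export
slice_volume <- function(volume_path, modality_index = 0L, output_dir,
                         id = NULL, axis = 3L) {
  if (!file.exists(volume_path))
    stop("cannot read volume: ", volume_path, call. = FALSE)
  arr <- as.array(RNifti::readNifti(volume_path))
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L))
    stop("expected a 3D or 4D NIfTI volume, got ", nd, "D", call. = FALSE)
  if (nd == 3L) {
    modality_index <- 0L
  } else {
    if (modality_index < 0L || modality_index >= dim(arr)[4])
      stop(sprintf("modality_index %d out of range 0..%d", modality_index,
                   dim(arr)[4] - 1L), call. = FALSE)
    arr <- arr[, , , modality_index + 1L]
  }
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3", call. = FALSE)
  rng <- range(arr)
  arr <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else array(0, dim(arr))
  if (is.null(id))
    id <- sub("\\.nii(\\.gz)?$", "", basename(volume_path))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  depth <- dim(arr)[axis]
  paths <- character(depth)
  for (k in seq_len(depth)) {
    sl <- switch(axis,
                 arr[k, , ],
                 arr[, k, ],
                 arr[, , k])
    paths[k] <- file.path(output_dir,
      sprintf("%s_slice_%d_modality_%d.png", id, k - 1L, modality_index))
    write_image_png(t(sl), paths[k])
  }
  data.frame(volume_id = id, slice_index = seq_len(depth) - 1L,
             modality_index = modality_index, path = paths,
             stringsAsFactors = FALSE)
}
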