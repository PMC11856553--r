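# End-to-end orchestration: simulate phantoms, train (or load) the
# classifier, attribute, postprocess, evaluate; plus the method benchmark.
# These functions back the command-line interface in inst/cli/xaiseg.R.

#' Assemble a run configuration
#'
#' Merges defaults, an optional flat key=value config file, and explicit
#' overrides, in that precedence order (overrides win).
#'
#' @param file optional config file with one `key = value` per line;
#'   vector values comma-separated. Keys mirror the fields of
#'   [phantom_config()], [train_config()], [occlusion_config()] and
#'   [postprocess_config()], plus `method`, `n`, `tumour_fraction`, `seed`,
#'   `input_size`.
#' @param ... named overrides.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  defaults <- list(
    # phantom
    size = c(240L, 240L), head_axes_range = c(70, 100),
    tumour_radius_range = c(12, 28), tumour_contrast = 0.45, noise_sd = 0.05,
    # training
    epochs = 12L, batch_size = 16L, lr = 3e-3, input_size = c(64L, 64L),
    val_fraction = 0.2,
    # occlusion
    window = c(16L, 16L), stride = c(8L, 8L), baseline = 0,
    # postprocess
    threshold = 0.35, min_cluster_size = 10L, pad_width = 2L,
    neighbor_kernel = 5L, dilate_kernel = 3L, close_kernel = 5L,
    connectivity = 4L, mode = "faithful", overlay_alpha = 0.7,
    # run
    method = "guided_backprop", n = 40L, tumour_fraction = 0.5, seed = 1L)
  cfg <- defaults
  if (!is.null(file)) {
    for (line in readLines(file, warn = FALSE)) {
      line <- sub("#.*$", "", line)
      if (!grepl("=", line, fixed = TRUE)) next
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      cfg[[key]] <- if (anyNA(num)) parts else num
    }
  }
  dots <- list(...)
  for (k in names(dots)) if (!is.null(dots[[k]])) cfg[[k]] <- dots[[k]]
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), ""), sep = "="), f)
  unname(tools::md5sum(f))
}

log_line <- function(con, stage, ...) {
  msg <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"),
                 stage, paste(..., collapse = " "))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

phantom_cfg_of <- function(cfg)
  phantom_config(size = cfg$size, head_axes_range = cfg$head_axes_range,
                 tumour_radius_range = cfg$tumour_radius_range,
                 tumour_contrast = cfg$tumour_contrast, noise_sd = cfg$noise_sd)

#' Simulate a phantom dataset on disk
#'
#' @param out_dir output directory (images, masks, manifest.csv).
#' @param n number of phantoms.
#' @param tumour_fraction fraction of tumour slices.
#' @param seed RNG seed.
#' @param config a [run_config()] supplying phantom parameters.
#' @return manifest data.frame, invisibly.
#' @export
cmd_simulate <- function(out_dir, n = 20L, tumour_fraction = 0.5, seed = 1L,
                         config = run_config()) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  ds <- generate_dataset(phantom_cfg_of(config), n = n,
                         tumour_fraction = tumour_fraction, seed = seed,
                         dir = out_dir)
  log_line(NULL, "simulate", sprintf("n=%d tumour_fraction=%g seed=%d dir=%s",
                                     n, tumour_fraction, seed, out_dir))
  invisible(ds$manifest)
}

load_manifest_phantoms <- function(data_dir) {
  mf <- utils::read.csv(file.path(data_dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  phantoms <- lapply(seq_len(nrow(mf)), function(i) {
    list(image = read_image_png(file.path(data_dir, mf$path[i])),
         mask = (read_image_png(file.path(data_dir, mf$mask_path[i])) > 0.5) + 0L,
         label = mf$label[i])
  })
  list(manifest = mf, phantoms = phantoms)
}

#' Run the full weak-segmentation pipeline
#'
#' Trains the test classifier on a phantom dataset (or loads a checkpoint),
#' computes the chosen attribution heatmap for the tumour class on every
#' tumour slice, postprocesses each heatmap to a binary mask, and evaluates
#' Dice/IoU against ground truth. Writes heatmap, mask and overlay PNGs, a
#' metrics CSV and a run log (with config hash and seed) under `out_dir`.
#'
#' @param data_dir dataset directory written by [cmd_simulate()].
#' @param out_dir output directory.
#' @param method attribution method name (see [attribution_methods()]).
#' @param config a [run_config()].
#' @param checkpoint optional checkpoint path; trained weights are saved
#'   there (or loaded from there with `train = FALSE`).
#' @param train set `FALSE` to require a checkpoint instead of training.
#' @return metrics data.frame, invisibly.
#' @export
cmd_run <- function(data_dir, out_dir, method = "guided_backprop",
                    config = run_config(), checkpoint = NULL, train = TRUE) {
  if (!method %in% attribution_methods())
    stop("unknown method: ", method, call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logf))
  log_line(logf, "config", sprintf("hash=%s seed=%d method=%s",
                                   config_hash(config), config$seed, method))
  ds <- load_manifest_phantoms(data_dir)

  if (train) {
    t0 <- proc.time()[["elapsed"]]
    handle <- adapt_backbone(
      tiny_cnn_backbone(input_size = config$input_size, seed = config$seed),
      n_classes = 2L)
    tc <- train_config(epochs = config$epochs, batch_size = config$batch_size,
                       lr = config$lr, seed = config$seed,
                       val_fraction = config$val_fraction)
    fit <- train_classifier(handle, ds$phantoms, tc)
    handle <- fit$handle
    utils::write.csv(fit$log, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    if (!is.null(checkpoint)) save_classifier(handle, checkpoint, tc)
    log_line(logf, "train", sprintf("epochs=%d final_val_acc=%.4f wall=%.1fs",
                                    config$epochs,
                                    utils::tail(fit$log$val_acc, 1),
                                    proc.time()[["elapsed"]] - t0))
  } else {
    if (is.null(checkpoint) || !file.exists(checkpoint))
      stop("train = FALSE requires an existing checkpoint", call. = FALSE)
    handle <- load_classifier(checkpoint)
    log_line(logf, "load", sprintf("checkpoint=%s", checkpoint))
  }

  occ <- occlusion_config(window = config$window, stride = config$stride,
                          baseline = config$baseline)
  pp <- postprocess_config(threshold = config$threshold,
                           min_cluster_size = config$min_cluster_size,
                           pad_width = config$pad_width,
                           neighbor_kernel = config$neighbor_kernel,
                           dilate_kernel = config$dilate_kernel,
                           close_kernel = config$close_kernel,
                           connectivity = config$connectivity,
                           mode = config$mode,
                           overlay_alpha = config$overlay_alpha)
  attr_fn <- attribution_registry(handle, target = 1L, occl_config = occ)[[method]]

  tumour_idx <- which(ds$manifest$label == 1L)
  preds <- list(); truths <- list(); ids <- character(0)
  for (i in tumour_idx) {
    ph <- ds$phantoms[[i]]
    t0 <- proc.time()[["elapsed"]]
    x <- resize_image(ph$image, handle$input_size, kind = "bilinear")
    hm <- attr_fn(x)
    hm_full <- resize_image(hm$values, dim(ph$image), kind = "bilinear")
    base <- tools::file_path_sans_ext(ds$manifest$path[i])
    hm_path <- file.path(out_dir, paste0(base, "_heatmap.png"))
    write_image_png(hm_full, hm_path)
    mask <- process_mask(hm_path, pp)
    write_mask_png(mask, file.path(out_dir, paste0(base, "_pred_mask.png")))
    ov <- overlay_mask(ph$image, mask, pp)
    write_image_png(ov, file.path(out_dir, paste0(base, "_overlay.png")))
    preds <- c(preds, list(mask)); truths <- c(truths, list(ph$mask))
    ids <- c(ids, ds$manifest$path[i])
    log_line(logf, "attribute+postprocess",
             sprintf("item=%s wall=%.2fs", ds$manifest$path[i],
                     proc.time()[["elapsed"]] - t0))
  }
  metrics <- evaluate_dataset(preds, truths, ids,
                              file = file.path(out_dir, "metrics.csv"))
  log_line(logf, "evaluate", sprintf("n=%d mean_dice=%.4f mean_iou=%.4f",
                                     nrow(metrics), mean(metrics$dice),
                                     mean(metrics$iou)))
  invisible(metrics)
}

#' Benchmark attribution methods on a phantom
#'
#' @param out_csv optional CSV path for the timing table.
#' @param methods method names to time.
#' @param repeats repetitions per method.
#' @param config a [run_config()].
#' @return timing data.frame, invisibly.
#' @export
cmd_benchmark <- function(out_csv = NULL, methods = attribution_methods(),
                          repeats = 3L, config = run_config()) {
  handle <- adapt_backbone(
    tiny_cnn_backbone(input_size = config$input_size, seed = config$seed),
    n_classes = 2L)
  ph <- generate_phantom(phantom_cfg_of(config), with_tumour = TRUE,
                         seed = config$seed)
  x <- resize_image(ph$image, handle$input_size, kind = "bilinear")
  occ <- occlusion_config(window = config$window, stride = config$stride,
                          baseline = config$baseline)
  tab <- benchmark_methods(handle, x, methods = methods, repeats = repeats,
                           config = occ, file = out_csv)
  log_line(NULL, "benchmark", sprintf("methods=%d repeats=%d", length(methods),
                                      repeats))
  invisible(tab)
}
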