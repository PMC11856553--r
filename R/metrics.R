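# Segmentation agreement metrics: Dice coefficient and IoU/Jaccard with
# their algebraic identity J = D / (2 - D).

#' Evaluate a predicted mask against ground truth
#'
#' Counts true/false positives and negatives over all pixels and derives
#' Dice = 2 tp / (2 tp + fp + fn) and IoU = tp / (tp + fp + fn). When both
#' masks are empty, Dice and IoU are defined as 1 (perfect agreement: the
#' correct prediction for a tumour-free slice is an empty mask).
#'
#' @param predicted 0/1 matrix.
#' @param truth 0/1 matrix of identical shape.
#' @return list of class `metrics_result`: dice, iou, tp, fp, fn, tn.
#' @export
evaluate_masks <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth)))
    stop("predicted and truth masks must have identical shapes", call. = FALSE)
  p <- predicted != 0; t <- truth != 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  iou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
  structure(list(dice = dice, iou = iou, tp = tp, fp = fp, fn = fn, tn = tn),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("Dice %.4f  IoU %.4f  (tp %d fp %d fn %d tn %d)\n",
              x$dice, x$iou, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' IoU implied by a Dice coefficient
#'
#' The two overlap measures obey IoU = Dice / (2 - Dice) exactly, which
#' makes any printed (Dice, IoU) pair internally checkable.
#'
#' @param d Dice coefficient in \[0, 1\].
#' @return the corresponding IoU.
#' @export
iou_from_dice <- function(d) {
  if (!is.numeric(d) || any(d < 0) || any(d > 1))
    stop("d must be in [0, 1]", call. = FALSE)
  d / (2 - d)
}

#' Evaluate many mask pairs into a report table
#'
#' @param predicted list of 0/1 matrices.
#' @param truth list of 0/1 matrices, same length.
#' @param ids identifiers for the report rows.
#' @param file optional CSV output path.
#' @return data.frame (image_id, dice, iou, tp, fp, fn, tn).
#' @export
evaluate_dataset <- function(predicted, truth, ids = seq_along(predicted),
                             file = NULL) {
  stopifnot(length(predicted) == length(truth))
  rows <- lapply(seq_along(predicted), function(i) {
    m <- evaluate_masks(predicted[[i]], truth[[i]])
    data.frame(image_id = ids[i], dice = m$dice, iou = m$iou, tp = m$tp,
               fp = m$fp, fn = m$fn, tn = m$tn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
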