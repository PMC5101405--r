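# OTB-style quantitative evaluation: center-location error, bounding-box
# overlap, precision plot (scored at 20 px) and success plot (AUC).

#' Intersection-over-union of two boxes
#'
#' @param a,b Numeric `c(x, y, w, h)` boxes.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  unname(inter / union)
}

as_trajectory <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "w", "h")])
  if (!is.matrix(x) || ncol(x) != 4L)
    stop("a trajectory is a data frame or matrix with columns x, y, w, h")
  x
}

#' Per-frame center-location error
#'
#' Euclidean distance between predicted and ground-truth box centers.
#'
#' @param pred,gt Trajectories (data frames or matrices with columns
#'   `x, y, w, h`), equal length.
#' @return Numeric vector of distances in pixels.
#' @export
center_error <- function(pred, gt) {
  pred <- as_trajectory(pred); gt <- as_trajectory(gt)
  if (nrow(pred) != nrow(gt)) stop("trajectory lengths differ")
  dx <- (pred[, 1] + pred[, 3] / 2) - (gt[, 1] + gt[, 3] / 2)
  dy <- (pred[, 2] + pred[, 4] / 2) - (gt[, 2] + gt[, 4] / 2)
  sqrt(dx^2 + dy^2)
}

#' Per-frame bounding-box overlap
#'
#' @inheritParams center_error
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
overlap <- function(pred, gt) {
  pred <- as_trajectory(pred); gt <- as_trajectory(gt)
  if (nrow(pred) != nrow(gt)) stop("trajectory lengths differ")
  vapply(seq_len(nrow(pred)),
         function(i) box_iou(pred[i, ], gt[i, ]), numeric(1))
}

#' Precision score and curve
#'
#' Fraction of frames whose center error is within a threshold; the
#' representative score uses 20 px, the curve sweeps 0..50 px.
#'
#' @param errors Center errors from [center_error()].
#' @param threshold Representative threshold in pixels (default 20).
#' @param grid Curve thresholds (default `0:50`).
#' @return List with `score` and a `curve` data frame
#'   (`threshold`, `precision`).
#' @export
precision_score <- function(errors, threshold = 20, grid = 0:50) {
  stopifnot(length(errors) > 0L)
  list(score = mean(errors <= threshold),
       curve = data.frame(
         threshold = grid,
         precision = vapply(grid, function(t) mean(errors <= t), numeric(1))))
}

#' Success plot AUC
#'
#' Success at threshold t is the fraction of frames with IoU strictly
#' above t; the AUC is the mean of success over the standard 21-point
#' threshold grid `seq(0, 1, by = 0.05)`.
#'
#' @param ious Overlaps from [overlap()].
#' @return List with `auc` and a `curve` data frame
#'   (`threshold`, `success`).
#' @export
success_auc <- function(ious) {
  stopifnot(length(ious) > 0L)
  grid <- seq(0, 1, by = 0.05)
  succ <- vapply(grid, function(t) mean(ious > t), numeric(1))
  list(auc = mean(succ), curve = data.frame(threshold = grid,
                                            success = succ))
}

#' Full tracking evaluation report
#'
#' @inheritParams center_error
#' @return List with `mean_center_error`, `precision` (score + curve at
#'   20 px), `success` (AUC + curve), `mean_overlap` and `n_frames`.
#' @export
evaluate_tracking <- function(pred, gt) {
  err <- center_error(pred, gt)
  iou <- overlap(pred, gt)
  list(mean_center_error = mean(err),
       precision = precision_score(err),
       success = success_auc(iou),
       mean_overlap = mean(iou),
       n_frames = length(err))
}
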