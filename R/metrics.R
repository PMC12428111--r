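#' Segmentation evaluation metrics
#'
#' Pixel accuracy, per-class Dice and IoU, and the 95th-percentile symmetric
#' boundary distance (HD95), with macro averaging over the classes present
#' in truth or prediction. Conventions for degenerate classes: Dice is 1
#' when a class is absent from both masks; HD95 is 0 when absent from both
#' and the image diagonal (a penalty) when absent from exactly one.
#'
#' @name metrics
#' @keywords internal
NULL

check_masks <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("`pred` and `truth` must have identical dimensions", call. = FALSE)
  }
  invisible(NULL)
}

#' Fraction of pixels with matching labels
#'
#' @param pred,truth Integer class matrices of equal shape.
#' @return A number in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  check_masks(pred, truth)
  mean(pred == truth)
}

#' Dice overlap for one class
#'
#' `2|A n B| / (|A| + |B|)`; 1 when the class is absent from both masks.
#'
#' @inheritParams pixel_accuracy
#' @param class_id Class label to score.
#' @return A number in `[0, 1]`.
#' @export
dice_score <- function(pred, truth, class_id) {
  check_masks(pred, truth)
  a <- pred == class_id
  b <- truth == class_id
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

iou_score <- function(pred, truth, class_id) {
  a <- pred == class_id
  b <- truth == class_id
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Mean intersection-over-union
#'
#' Per-class IoU averaged (macro) over the classes present in truth or
#' prediction.
#'
#' @inheritParams pixel_accuracy
#' @param include_background Include class 0 in the average (default TRUE).
#' @return A number in `[0, 1]`.
#' @export
mean_iou <- function(pred, truth, include_background = TRUE) {
  check_masks(pred, truth)
  classes <- sort(union(unique(as.integer(pred)), unique(as.integer(truth))))
  if (!include_background) classes <- setdiff(classes, 0L)
  vals <- vapply(classes, function(cl) iou_score(pred, truth, cl), numeric(1))
  mean(vals, na.rm = TRUE)
}

#' 95th-percentile symmetric boundary distance for one class
#'
#' Pools, over both directions, the nearest-neighbour distances between the
#' boundary pixels of the two class supports and returns their 95th
#' percentile (linear interpolation between order statistics). A class
#' absent from both masks scores 0; absent from exactly one scores the
#' image diagonal as a penalty.
#'
#' @inheritParams dice_score
#' @return Distance in pixels (>= 0).
#' @export
hd95 <- function(pred, truth, class_id) {
  check_masks(pred, truth)
  a <- pred == class_id
  b <- truth == class_id
  if (!any(a) && !any(b)) return(0)
  if (!any(a) || !any(b)) return(sqrt(nrow(pred)^2 + ncol(pred)^2))
  ba <- which(support_boundary(a), arr.ind = TRUE)
  bb <- which(support_boundary(b), arr.ind = TRUE)
  d2 <- outer(ba[, 1], bb[, 1], "-")^2 + outer(ba[, 2], bb[, 2], "-")^2
  d_ab <- sqrt(apply(d2, 1, min))
  d_ba <- sqrt(apply(d2, 2, min))
  stats::quantile(c(d_ab, d_ba), probs = 0.95, names = FALSE, type = 7)
}

#' Per-class and mean metrics for a set of predictions
#'
#' Computes accuracy, Dice, IoU and HD95 per class over one or more
#' prediction/truth mask pairs, macro-averaged over images, plus the mean
#' row used in result tables. Background (class 0) is excluded from the
#' Dice/IoU/HD95 means by default.
#'
#' @param pred_masks List of integer matrices (or a single matrix).
#' @param truth_masks List of integer matrices matching `pred_masks`.
#' @param n_classes Number of classes including background.
#' @param include_background Include class 0 in the mean Dice/IoU/HD95.
#' @return A `metrics_report`: list with `per_class` (tibble), `summary`
#'   (one-row tibble: accuracy, dice, miou, hd95), and `n_images`.
#' @export
metrics_report <- function(pred_masks, truth_masks, n_classes,
                           include_background = FALSE) {
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(truth_masks)) truth_masks <- list(truth_masks)
  stopifnot(length(pred_masks) == length(truth_masks))
  classes <- seq_len(n_classes) - 1L
  per_image <- lapply(seq_along(pred_masks), function(i) {
    p <- pred_masks[[i]]; t <- truth_masks[[i]]
    tibble::tibble(
      image = i, class = classes,
      present = vapply(classes, function(cl) any(p == cl) || any(t == cl),
                       logical(1)),
      dice = vapply(classes, function(cl) dice_score(p, t, cl), numeric(1)),
      iou = vapply(classes, function(cl) {
        v <- iou_score(p, t, cl); if (is.na(v)) 1 else v
      }, numeric(1)),
      hd95 = vapply(classes, function(cl) hd95(p, t, cl), numeric(1)))
  })
  per_class <- dplyr::bind_rows(per_image) |>
    dplyr::filter(.data$present) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dice = mean(.data$dice), iou = mean(.data$iou),
                     hd95 = mean(.data$hd95), n_images = dplyr::n(),
                     .groups = "drop")
  acc <- mean(vapply(seq_along(pred_masks), function(i) {
    pixel_accuracy(pred_masks[[i]], truth_masks[[i]])
  }, numeric(1)))
  fg <- if (include_background) per_class else
    dplyr::filter(per_class, .data$class != 0L)
  summary <- tibble::tibble(accuracy = acc, dice = mean(fg$dice),
                            miou = mean(fg$iou), hd95 = mean(fg$hd95))
  structure(list(per_class = per_class, summary = summary,
                 n_images = length(pred_masks),
                 classes_evaluated = per_class$class),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d image(s)\n", x$n_images))
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) x$summary
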