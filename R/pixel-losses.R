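#' Per-pixel losses for probabilistic segmentation
#'
#' Predictions are held as a `C x P` matrix of class probabilities (one
#' column per pixel, columns on the simplex); ground truth as the matching
#' `C x P` one-hot matrix. Per-pixel losses are returned as a
#' `pixel_loss_map`: a list with numeric `losses` (length `P`) and a logical
#' `retained` selection mask of the same length.
#'
#' @name pixel_losses
#' @keywords internal
NULL

PROB_EPS <- 1e-12 # clipping floor applied to probabilities before log()

#' One-hot encode an integer class mask
#'
#' @param mask Integer vector or matrix of class ids in `0:(n_classes-1)`.
#' @param n_classes Total number of classes `C >= 2` (class 0 = background).
#' @return A `C x P` binary matrix with exactly one 1 per column.
#' @export
one_hot_mask <- function(mask, n_classes) {
  v <- as.integer(mask)
  if (anyNA(v) || any(v < 0L) || any(v >= n_classes)) {
    stop("mask values must lie in 0:(n_classes-1)", call. = FALSE)
  }
  y <- matrix(0, nrow = n_classes, ncol = length(v))
  y[cbind(v + 1L, seq_along(v))] <- 1
  y
}

check_prob_map <- function(pred, truth = NULL) {
  if (!is.matrix(pred) || nrow(pred) < 2L) {
    stop("`pred` must be a C x P matrix with C >= 2", call. = FALSE)
  }
  if (!is.null(truth)) {
    if (!is.matrix(truth) || !all(dim(truth) == dim(pred))) {
      stop("`pred` and `truth` must have identical C x P dimensions", call. = FALSE)
    }
  }
  invisible(NULL)
}

pixel_loss_map <- function(losses, retained = rep(TRUE, length(losses))) {
  structure(list(losses = as.numeric(losses), retained = as.logical(retained)),
            class = "pixel_loss_map")
}

#' @export
print.pixel_loss_map <- function(x, ...) {
  cat(sprintf("<pixel_loss_map> P = %d, retained = %d, mean loss = %.4g\n",
              length(x$losses), sum(x$retained), mean(x$losses)))
  invisible(x)
}

#' Per-pixel (weighted) cross-entropy
#'
#' `l_j = -w_c(j) * log(p_c(j),j)` where `c(j)` is the true class of pixel
#' `j`. Probabilities are clipped below at `1e-12` before the logarithm so
#' the loss is always finite.
#'
#' @param pred `C x P` matrix of predicted class probabilities.
#' @param truth `C x P` one-hot matrix.
#' @param class_weights Optional positive per-class weights (length `C`).
#' @return A `pixel_loss_map` with all pixels retained.
#' @export
cross_entropy_per_pixel <- function(pred, truth, class_weights = NULL) {
  check_prob_map(pred, truth)
  p_true <- pmax(colSums(pred * truth), PROB_EPS)
  l <- -log(p_true)
  if (!is.null(class_weights)) {
    stopifnot(length(class_weights) == nrow(pred), all(class_weights > 0))
    l <- l * class_weights[max.col(t(truth))]
  }
  pixel_loss_map(l)
}

#' Per-pixel continuous-Dice overlap terms for one class
#'
#' For class `c`, `rho_j = p_cj * y_cj / (sum_j p_cj^2 + sum_j y_cj^2)`: the
#' per-pixel, continuous (hence rankable) contributions whose sum over the
#' image is the class's continuous-Dice overlap. A class absent from both
#' prediction and truth (zero denominator) yields all-zero terms.
#'
#' @inheritParams cross_entropy_per_pixel
#' @param class_index 1-based class row index.
#' @return Numeric vector of length `P`, non-negative.
#' @export
continuous_dice_rho <- function(pred, truth, class_index) {
  check_prob_map(pred, truth)
  p <- pred[class_index, ]
  y <- truth[class_index, ]
  denom <- sum(p^2) + sum(y^2)
  if (denom <= 0) return(numeric(length(p)))
  p * y / denom
}

#' Continuous-Dice loss over all classes
#'
#' `(1/C') * sum_c w_c * (1 - dice_factor * sum_j rho_cj)` over the classes
#' `C'` present in truth or prediction. With `dice_factor = 1` a perfect
#' one-hot prediction scores 0.5 per class (the overlap sum saturates at 1/2
#' because the denominator counts both squared sums); `dice_factor = 2`
#' rescales so a perfect prediction scores 0, the usual soft-Dice
#' convention.
#'
#' @inheritParams cross_entropy_per_pixel
#' @param dice_factor Multiplier on the overlap sum; 1 for the verbatim
#'   form, 2 (default) for the zero-minimum convention.
#' @return List with `loss` (scalar), `per_class` (named numeric), and
#'   `rho` (`C x P` matrix of per-pixel overlap terms).
#' @export
continuous_dice_loss <- function(pred, truth, dice_factor = 2, class_weights = NULL) {
  check_prob_map(pred, truth)
  C <- nrow(pred)
  if (is.null(class_weights)) class_weights <- rep(1, C)
  rho <- matrix(0, C, ncol(pred))
  present <- logical(C)
  per_class <- rep(NA_real_, C)
  for (cc in seq_len(C)) {
    present[cc] <- sum(truth[cc, ]) > 0 || sum(pred[cc, ]^2) > 0
    rho[cc, ] <- continuous_dice_rho(pred, truth, cc)
    if (present[cc]) {
      per_class[cc] <- class_weights[cc] * (1 - dice_factor * sum(rho[cc, ]))
    }
  }
  if (!any(present)) stop("no class present in truth or prediction", call. = FALSE)
  list(loss = mean(per_class[present]), per_class = per_class, rho = rho)
}

#' Combined cross-entropy + continuous-Dice per-pixel loss
#'
#' `l_j = lambda_ce * CE_j + lambda_dc * (1 - dice_factor * rho_j)` with the
#' overlap term `rho_j` evaluated at the true class of pixel `j`. This is
#' the rankable per-pixel objective that the image- and pixel-level
#' selection strategies operate on.
#'
#' @inheritParams cross_entropy_per_pixel
#' @inheritParams continuous_dice_loss
#' @param weights A [loss_weights()] object.
#' @return A `pixel_loss_map` (all pixels retained).
#' @export
combined_pixel_loss <- function(pred, truth, weights = loss_weights(),
                                dice_factor = 2) {
  check_prob_map(pred, truth)
  ce <- if (weights$lambda_ce > 0) {
    cross_entropy_per_pixel(pred, truth, weights$class_weights)$losses
  } else numeric(ncol(pred))
  dc <- if (weights$lambda_dc > 0) {
    rho <- vapply(seq_len(nrow(pred)), function(cc) {
      continuous_dice_rho(pred, truth, cc)
    }, numeric(ncol(pred)))
    rho_true <- rowSums(t(truth) * rho) # rho at each pixel's true class
    1 - dice_factor * rho_true
  } else numeric(ncol(pred))
  pixel_loss_map(weights$lambda_ce * ce + weights$lambda_dc * dc)
}

#' Loss-term weights
#'
#' @param lambda_ce Non-negative weight on the cross-entropy term.
#' @param lambda_dc Non-negative weight on the continuous-Dice term.
#' @param class_weights Optional positive per-class weights applied inside
#'   the cross-entropy (e.g. to upweight small or rare structures).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_ce = 0.3, lambda_dc = 0.7, class_weights = NULL) {
  if (lambda_ce < 0 || lambda_dc < 0 || lambda_ce + lambda_dc <= 0) {
    stop("lambda weights must be non-negative and not both zero", call. = FALSE)
  }
  structure(list(lambda_ce = lambda_ce, lambda_dc = lambda_dc,
                 class_weights = class_weights),
            class = "loss_weights")
}

#' "Bottom all but sigma" pixel filter
#'
#' Retains the pixels whose loss does not exceed the within-image mean plus
#' one (population) standard deviation of the pixel losses. The comparison
#' is non-strict, so a constant loss map retains every pixel; at least one
#' pixel is always retained and the retained-set mean never exceeds the full
#' mean.
#'
#' @param pl A `pixel_loss_map` (or bare numeric vector of losses).
#' @return A `pixel_loss_map` with the `retained` mask set.
#' @examples
#' bottom_all_but_sigma(c(1, 1, 1, 10))$retained # TRUE TRUE TRUE FALSE
#' @export
bottom_all_but_sigma <- function(pl) {
  if (!inherits(pl, "pixel_loss_map")) pl <- pixel_loss_map(pl)
  l <- pl$losses
  m <- mean(l)
  sigma <- sqrt(mean((l - m)^2)) # population sd
  pixel_loss_map(l, retained = l <= m + sigma)
}

#' Top-k pixel filter
#'
#' Retains the `max(1, ceiling(fraction * P))` largest pixel losses; ties
#' are broken stably in pixel-index order.
#'
#' @inheritParams bottom_all_but_sigma
#' @param fraction Fraction of pixels to keep, in (0, 1].
#' @return A `pixel_loss_map` with the `retained` mask set.
#' @export
top_k_pixels <- function(pl, fraction = 0.10) {
  if (!inherits(pl, "pixel_loss_map")) pl <- pixel_loss_map(pl)
  if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  l <- pl$losses
  count <- max(1L, ceiling(fraction * length(l)))
  o <- order(-l, seq_along(l), method = "radix") # stable among ties
  retained <- logical(length(l))
  retained[o[seq_len(count)]] <- TRUE
  pixel_loss_map(l, retained)
}
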