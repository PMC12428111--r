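#' Rank-based aggregation of individual losses
#'
#' A training objective over a set of individual (per-instance) losses can be
#' built from their *ranks* rather than from the plain mean: the mean of the
#' `k` largest losses emphasises hard examples, the mean of a lower rank
#' window de-emphasises likely mislabeled ones. These helpers operate on a
#' plain numeric vector of non-negative finite losses and treat its ascending
#' sort order as the rank scale (rank 1 = smallest, rank `N` = largest).
#'
#' @name rank_aggregation
#' @keywords internal
NULL

# Shared validation for a vector of individual losses.
check_losses <- function(values, arg = "values") {
  if (length(values) < 1L) {
    stop(sprintf("`%s` must contain at least one loss value", arg), call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop(sprintf("`%s` must be finite numeric values", arg), call. = FALSE)
  }
  if (any(values < 0)) {
    stop(sprintf("`%s` must be non-negative", arg), call. = FALSE)
  }
  invisible(as.numeric(values))
}

check_window <- function(i0, k, n) {
  if (length(i0) != 1L || length(k) != 1L || !is.finite(i0) || !is.finite(k)) {
    stop("`i0` and `k` must be finite scalars", call. = FALSE)
  }
  if (k < 1 || i0 < 1 || i0 + k - 1 > n) {
    stop(sprintf("rank window [%s, %s] is invalid for %d losses", i0, i0 + k - 1, n),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Mean of all individual losses (empirical risk)
#'
#' @param values Numeric vector of non-negative finite individual losses.
#' @return The arithmetic mean, a length-one numeric.
#' @examples
#' average_loss(c(1, 2, 3, 4)) # 2.5
#' @export
average_loss <- function(values) {
  check_losses(values)
  mean(values)
}

#' Largest individual loss
#'
#' Equivalent to [average_top_k()] with `k = 1`.
#'
#' @inheritParams average_loss
#' @return The maximum loss value.
#' @export
maximum_loss <- function(values) {
  check_losses(values)
  max(values)
}

#' Mean of the k largest individual losses
#'
#' Interpolates between the maximum loss (`k = 1`) and the plain mean
#' (`k = N`), and is non-increasing in `k`.
#'
#' @inheritParams average_loss
#' @param k Number of top-ranked losses to average, `1 <= k <= length(values)`.
#' @return Mean of the `k` largest values.
#' @examples
#' average_top_k(c(1, 2, 3, 4), 2) # 3.5
#' @export
average_top_k <- function(values, k) {
  check_losses(values)
  n <- length(values)
  check_window(n - k + 1, k, n)
  mean(sort(values, method = "radix")[(n - k + 1):n])
}

#' Mean of an arbitrary rank window of losses
#'
#' Averages the losses at ascending ranks `i0, ..., i0 + k - 1` (1-based).
#' `i0 = N - k + 1` recovers [average_top_k()]; `i0 = 1` is the "average
#' bottom-k".
#'
#' @inheritParams average_loss
#' @param i0 First rank of the window (1-based, on the ascending sort).
#' @param k Window width in ranks.
#' @return Mean of the selected losses.
#' @examples
#' select_average(c(1, 2, 3, 4, 5), i0 = 2, k = 2) # 2.5
#' @export
select_average <- function(values, i0, k) {
  check_losses(values)
  check_window(i0, k, length(values))
  mean(sort(values, method = "radix")[i0:(i0 + k - 1)])
}

#' Sigmoid approximation of the step indicator I(i >= k)
#'
#' `1 / (1 + exp(-alpha * (i - k)))`, computed in a branch-safe form so that
#' arbitrarily large `|alpha * (i - k)|` saturates to 0 or 1 without overflow.
#' Larger `alpha` gives a sharper step.
#'
#' @param i Evaluation point(s), numeric.
#' @param k Step location.
#' @param alpha Sharpness, must be positive.
#' @return Values in (0, 1), same length as `i`.
#' @examples
#' sigmoid_indicator(6, 5, alpha = 1) # ~0.731
#' @export
sigmoid_indicator <- function(i, k, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a positive finite scalar", call. = FALSE)
  }
  x <- alpha * (i - k)
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  out
}

#' Smooth boxcar selector over a rank window
#'
#' Product of a rising and a falling sigmoid,
#' `S_alpha(i, i0) * S_alpha(-i, -(i0 + k))`, approximating the indicator of
#' the half-open rank window `[i0, i0 + k)`. At the rising edge `i = i0` the
#' value tends to 0.5 when the window is wide relative to `1/alpha`.
#'
#' @inheritParams sigmoid_indicator
#' @param i0 Window start.
#' @param k Window width (must be positive).
#' @return Values in (0, 1), same length as `i`.
#' @examples
#' boxcar_selector(10, i0 = 5, k = 10, alpha = 20) # ~1
#' @export
boxcar_selector <- function(i, i0, k, alpha) {
  if (any(k <= 0)) stop("`k` must be positive", call. = FALSE)
  sigmoid_indicator(i, i0, alpha) * sigmoid_indicator(-i, -(i0 + k), alpha)
}

# Selector weight for integer ranks: the boxcar with both edges shifted by
# half a rank so the integer ranks i0 .. i0+k-1 sit strictly inside the
# window. Without the shift the edge ranks carry weight 0.5 and the smoothed
# mean cannot converge to the exact windowed mean as alpha grows.
rank_window_weight <- function(i, i0, k, alpha) {
  if (!is.finite(alpha)) {
    # sharp-indicator sentinel (alpha = Inf): exact membership
    return(as.numeric(i >= i0 & i <= i0 + k - 1))
  }
  boxcar_selector(i, i0 - 0.5, k, alpha)
}

#' Selector configuration for smoothed rank-window aggregation
#'
#' @param i0 First rank of the window (1-based).
#' @param k Window width in ranks.
#' @param alpha Sigmoid sharpness (> 0), or `Inf` for the exact indicator.
#' @param normalization How the weighted sum is normalised:
#'   `"effective_weight"` (default) divides by the total selector weight so
#'   the result is a weighted mean that converges to [select_average()] as
#'   `alpha` grows; `"paper_N"` divides by the number of losses `N`;
#'   `"paper_k"` divides by the window width `k`.
#' @return A `selector_config` list.
#' @export
selector_config <- function(i0, k, alpha = 20,
                            normalization = c("effective_weight", "paper_N", "paper_k")) {
  normalization <- match.arg(normalization)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("`alpha` must be positive (possibly Inf)", call. = FALSE)
  }
  structure(list(i0 = i0, k = k, alpha = alpha, normalization = normalization),
            class = "selector_config")
}

#' Smoothed windowed mean of ranked losses
#'
#' Sorts the losses ascending and forms `sum_i zeta(i) * l[i] / Z`, where
#' `zeta` is the smooth boxcar selector over the configured rank window
#' (evaluated with half-rank-centred edges, see Details) and the normaliser
#' `Z` is chosen by `sel$normalization`.
#'
#' @details With `normalization = "effective_weight"` the result is a
#' weighted mean and converges to [select_average()] in the sharp limit
#' `alpha -> Inf`; with `"paper_N"` the weighted sum is divided by the total
#' number of losses, the form natural when the selector weights play the role
#' of soft inclusion indicators in a full-sum objective.
#'
#' @inheritParams average_loss
#' @param sel A [selector_config()].
#' @return Length-one numeric.
#' @examples
#' smoothed_select(c(1, 2, 3, 4, 5), selector_config(i0 = 4, k = 2, alpha = 50))
#' @export
smoothed_select <- function(values, sel) {
  stopifnot(inherits(sel, "selector_config"))
  check_losses(values)
  n <- length(values)
  check_window(sel$i0, sel$k, n)
  l <- sort(values, method = "radix")
  w <- rank_window_weight(seq_len(n), sel$i0, sel$k, sel$alpha)
  z <- switch(sel$normalization,
              effective_weight = sum(w),
              paper_N = n,
              paper_k = sel$k)
  if (z <= .Machine$double.eps) {
    stop("selector weights vanish numerically for this window/alpha", call. = FALSE)
  }
  sum(w * l) / z
}

#' Incremental insertion into a sorted loss structure
#'
#' Merges a batch of new loss values into an already-ascending state, as done
#' when per-image losses are accumulated over an epoch so images can be
#' ranked without re-sorting from scratch. Ties are resolved by placing new
#' values after existing equal values (and within the batch, in batch order).
#'
#' @param sorted_state Ascending numeric vector (may be empty).
#' @param batch Numeric vector of new values.
#' @return A list with `merged` (ascending, a permutation of the union) and
#'   `ranks` (1-based rank of each batch element in `merged`, in batch order).
#' @examples
#' incremental_sorted_insert(c(1, 3, 5), c(2, 4))
#' @export
incremental_sorted_insert <- function(sorted_state, batch) {
  if (anyNA(sorted_state) || any(!is.finite(sorted_state)) ||
      anyNA(batch) || any(!is.finite(batch))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (length(sorted_state) && is.unsorted(sorted_state)) {
    stop("`sorted_state` must be ascending", call. = FALSE)
  }
  all_vals <- c(as.numeric(sorted_state), as.numeric(batch))
  o <- order(all_vals, method = "radix") # stable: state before batch on ties
  ranks <- integer(length(batch))
  ranks[o[o > length(sorted_state)] - length(sorted_state)] <-
    which(o > length(sorted_state))
  list(merged = all_vals[o], ranks = ranks)
}
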