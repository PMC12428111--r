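#' Image/pixel loss-selection envelope
#'
#' The training objective is a nested aggregation: per-pixel losses are
#' filtered within each image (all pixels / top-k / "bottom all but sigma"),
#' reduced to one scalar per image, and the per-image scalars are then
#' rank-weighted across the epoch (all images / average top-k / a window
#' that shrinks over epochs), optionally with sigmoid-smoothed selector
#' weights instead of hard indicators.
#'
#' @name envelope
#' @keywords internal
NULL

IMAGE_STRATEGIES <- c(erm = "erm", atk = "atk", atk_dec = "atk_dec")
SMOOTHINGS <- c(none = "none", sm = "sm", sm_inc = "sm_inc")
PIXEL_STRATEGIES <- c(all = "all", tk = "tk", bsigma = "bsigma")

#' Training strategy configuration
#'
#' @param image_strategy Image-level selection: `"erm"` (all images),
#'   `"atk"` (fixed top 10% window from the second epoch on), or
#'   `"atk_dec"` (window shrinking linearly from all images to the top
#'   `final_k_fraction` over the schedule).
#' @param smoothing Selector smoothing at image level: `"none"` (hard
#'   indicator), `"sm"` (sigmoid selector at fixed `alpha_start`), or
#'   `"sm_inc"` (alpha decreasing linearly from `alpha_start` to
#'   `alpha_end`, i.e. smoothing increases over training).
#' @param pixel_strategy Pixel-level selection within each image: `"all"`,
#'   `"tk"` (top `tk_fraction` of pixel losses), or `"bsigma"` (retain
#'   pixels with loss <= mean + population sd).
#' @param atk_fraction Window fraction for `"atk"` (default 0.10).
#' @param final_k_fraction Final window fraction for `"atk_dec"` (default 0.05).
#' @param tk_fraction Pixel fraction for pixel `"tk"` (default 0.10).
#' @param alpha_start,alpha_end Selector sharpness schedule endpoints
#'   (defaults 20 and 1).
#' @param pixel_warmup_epochs Number of initial epochs during which the
#'   pixel filter is held at `"all"` before the configured `pixel_strategy`
#'   activates. Loss-rank-based selection is only meaningful once per-pixel
#'   losses are informative; from a random initialisation every foreground
#'   pixel scores a high loss, so filtering from epoch 0 discards exactly
#'   the pixels the model still has to learn and locks in a trivial
#'   background predictor. `NULL` (default) uses a third of the schedule,
#'   mirroring the warmup built into the image-level selection.
#' @param total_epochs Number of training epochs.
#' @param weights A [loss_weights()] object.
#' @param normalization Passed to the image-level weighted aggregation, see
#'   [selector_config()].
#' @param seed Integer seed controlling epoch shuffling.
#' @return A `strategy_config` list.
#' @export
strategy_config <- function(image_strategy = c("erm", "atk", "atk_dec"),
                            smoothing = c("none", "sm", "sm_inc"),
                            pixel_strategy = c("all", "tk", "bsigma"),
                            atk_fraction = 0.10,
                            final_k_fraction = 0.05,
                            tk_fraction = 0.10,
                            alpha_start = 20,
                            alpha_end = 1,
                            pixel_warmup_epochs = NULL,
                            total_epochs = 30L,
                            weights = loss_weights(),
                            normalization = "effective_weight",
                            seed = 1L) {
  image_strategy <- match.arg(image_strategy)
  smoothing <- match.arg(smoothing)
  pixel_strategy <- match.arg(pixel_strategy)
  stopifnot(atk_fraction > 0, atk_fraction <= 1,
            final_k_fraction > 0, final_k_fraction <= 1,
            tk_fraction > 0, tk_fraction <= 1,
            alpha_start >= alpha_end, alpha_end > 0,
            total_epochs >= 1)
  if (is.null(pixel_warmup_epochs)) {
    pixel_warmup_epochs <- ceiling(total_epochs / 3)
  }
  stopifnot(pixel_warmup_epochs >= 0)
  structure(list(image_strategy = image_strategy, smoothing = smoothing,
                 pixel_strategy = pixel_strategy,
                 atk_fraction = atk_fraction,
                 final_k_fraction = final_k_fraction,
                 tk_fraction = tk_fraction,
                 alpha_start = alpha_start, alpha_end = alpha_end,
                 pixel_warmup_epochs = as.integer(pixel_warmup_epochs),
                 total_epochs = as.integer(total_epochs),
                 weights = weights, normalization = normalization,
                 seed = as.integer(seed)),
            class = "strategy_config")
}

#' @export
print.strategy_config <- function(x, ...) {
  cat(sprintf("<strategy_config> image: %s | smoothing: %s | pixels: %s | epochs: %d\n",
              x$image_strategy, x$smoothing, x$pixel_strategy, x$total_epochs))
  invisible(x)
}

#' Image-selection window schedule
#'
#' Returns the rank window `(k, i0)` over `I` ranked per-image losses for a
#' 0-based epoch index. `"erm"` always uses the full window. `"atk"` uses
#' the full window in the first epoch (losses must exist before they can be
#' ranked) and a fixed top-`atk_fraction` window afterwards. `"atk_dec"`
#' shrinks the window linearly from all images to the top
#' `final_k_fraction` at the last epoch. The window always has `i0 = I - k + 1`
#' (top of the ranking) and is valid for `I`.
#'
#' @param epoch 0-based epoch index (`0 <= epoch < total_epochs`).
#' @param cfg A [strategy_config()].
#' @param n_images Number of ranked images `I`.
#' @return List with integer `k` and `i0`.
#' @export
schedule_k <- function(epoch, cfg, n_images) {
  stopifnot(inherits(cfg, "strategy_config"))
  if (n_images < 1) stop("`n_images` must be >= 1", call. = FALSE)
  stopifnot(epoch >= 0, epoch < cfg$total_epochs)
  I <- as.integer(n_images)
  k <- switch(cfg$image_strategy,
    erm = I,
    atk = if (epoch == 0) I else max(1L, as.integer(ceiling(cfg$atk_fraction * I))),
    atk_dec = {
      k_final <- max(1L, as.integer(ceiling(cfg$final_k_fraction * I)))
      if (cfg$total_epochs == 1L) I
      else {
        t <- epoch / (cfg$total_epochs - 1)
        max(k_final, min(I, as.integer(round(I + (k_final - I) * t))))
      }
    })
  list(k = k, i0 = I - k + 1L)
}

#' Selector sharpness schedule
#'
#' `"none"` returns `Inf` (exact indicator); `"sm"` keeps alpha fixed at
#' `alpha_start`; `"sm_inc"` decreases alpha linearly from `alpha_start` to
#' `alpha_end` over the epochs (smaller alpha = smoother selector).
#'
#' @inheritParams schedule_k
#' @return Length-one numeric (possibly `Inf`).
#' @export
schedule_alpha <- function(epoch, cfg) {
  stopifnot(inherits(cfg, "strategy_config"), epoch >= 0, epoch < cfg$total_epochs)
  switch(cfg$smoothing,
    none = Inf,
    sm = cfg$alpha_start,
    sm_inc = {
      if (cfg$total_epochs == 1L) cfg$alpha_start
      else cfg$alpha_start +
        (cfg$alpha_end - cfg$alpha_start) * epoch / (cfg$total_epochs - 1)
    })
}

#' Per-image scalar loss after pixel-level selection
#'
#' Applies the configured pixel filter to the per-pixel losses of one image
#' and returns the mean of the retained losses, plus the retention mask.
#'
#' @param pl A `pixel_loss_map` (or numeric vector of pixel losses).
#' @param cfg A [strategy_config()].
#' @param epoch Optional 0-based epoch index; when given and still inside
#'   `cfg$pixel_warmup_epochs`, the filter is held at `"all"`.
#' @return List with `loss` (scalar) and `retained` (logical mask).
#' @export
image_loss <- function(pl, cfg, epoch = NULL) {
  if (!inherits(pl, "pixel_loss_map")) pl <- pixel_loss_map(pl)
  strategy <- cfg$pixel_strategy
  if (!is.null(epoch) && epoch < (cfg$pixel_warmup_epochs %||% 0L)) {
    strategy <- "all"
  }
  filtered <- switch(strategy,
    all = pl,
    tk = top_k_pixels(pl, cfg$tk_fraction),
    bsigma = bottom_all_but_sigma(pl))
  list(loss = mean(filtered$losses[filtered$retained]),
       retained = filtered$retained)
}

#' Epoch-persistent rank state
#'
#' Per-image losses accumulated over the current epoch, kept sorted so each
#' new batch can be ranked by incremental insertion instead of a full
#' re-sort. `epoch_reset()` clears it at every epoch boundary.
#'
#' @return An `epoch_rank_state` with empty `values` and `ids`.
#' @export
epoch_reset <- function() {
  structure(list(values = numeric(0), ids = integer(0)),
            class = "epoch_rank_state")
}

#' Images selected by a rank window of the epoch state
#'
#' @param state An `epoch_rank_state`.
#' @param i0,k Rank window (1-based start, width).
#' @return Integer ids of the images whose ranks fall in `[i0, i0 + k - 1]`.
#' @export
selected_images <- function(state, i0, k) {
  stopifnot(inherits(state, "epoch_rank_state"))
  n <- length(state$values)
  lo <- max(1L, as.integer(i0))
  hi <- min(n, as.integer(i0 + k - 1))
  if (hi < lo) return(integer(0))
  sort(state$ids[lo:hi])
}

#' Rank-weighted aggregation of a batch of per-image losses
#'
#' Each batch image is ranked by inserting its scalar loss into the
#' epoch-persistent sorted state; when the state holds only part of the `I`
#' images seen per epoch, ranks are extrapolated to the full scale by
#' `r * I / |state|`. The image weight is the smooth selector
#' `zeta_alpha(r, i0, k)` (half-rank-centred; hard indicator when
#' `alpha = Inf`). The batch loss is the weighted sum divided by the
#' normaliser chosen in `cfg$normalization`. A fresh (empty) state carries
#' no ranking information, so its first batch is weighted uniformly. If all
#' selector weights vanish numerically the batch falls back to uniform
#' weights (flagged in the result) so no batch goes gradient-dead.
#'
#' @param losses Numeric vector of per-image scalar losses for the batch.
#' @param ids Integer image ids matching `losses`.
#' @param state An `epoch_rank_state` from earlier batches of this epoch.
#' @param epoch 0-based epoch index.
#' @param cfg A [strategy_config()].
#' @param n_images Total images per epoch `I`.
#' @return List with `loss` (scalar), `weights` (per batch image, in [0,1]),
#'   `normalizer`, `ranks` (extrapolated), `state` (updated), and
#'   `uniform_fallback` (logical).
#' @export
nested_loss <- function(losses, ids, state, epoch, cfg, n_images) {
  stopifnot(inherits(state, "epoch_rank_state"), length(losses) == length(ids))
  check_losses(losses, "losses")
  win <- schedule_k(epoch, cfg, n_images)
  alpha <- schedule_alpha(epoch, cfg)
  fresh <- length(state$values) == 0L

  ins <- incremental_sorted_insert(state$values, losses)
  new_ids <- c(state$ids, as.integer(ids))[order(c(state$values, losses),
                                                 method = "radix")]
  state <- structure(list(values = ins$merged, ids = new_ids),
                     class = "epoch_rank_state")

  uniform_fallback <- FALSE
  if (cfg$image_strategy == "erm" || fresh) {
    w <- rep(1, length(losses))
  } else {
    scale <- n_images / length(ins$merged)
    r <- ins$ranks * scale
    w <- rank_window_weight(r, win$i0, win$k, alpha)
    if (sum(w) <= .Machine$double.eps) {
      w <- rep(1, length(losses))
      uniform_fallback <- TRUE
    }
  }
  z <- switch(cfg$normalization,
              effective_weight = sum(w),
              paper_N = n_images,
              paper_k = win$k)
  list(loss = sum(w * losses) / z, weights = w, normalizer = z,
       ranks = ins$ranks, state = state, uniform_fallback = uniform_fallback)
}
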