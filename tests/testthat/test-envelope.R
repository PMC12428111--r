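test_that("image-window schedule follows the strategy definitions", {
  cfg_atk <- fast_strategy("atk", total_epochs = 10)
  cfg_dec <- fast_strategy("atk_dec", total_epochs = 10)
  cfg_erm <- fast_strategy("erm", total_epochs = 10)

  expect_equal(schedule_k(0, cfg_erm, 100), list(k = 100L, i0 = 1L))
  expect_equal(schedule_k(7, cfg_erm, 100), list(k = 100L, i0 = 1L))
  # first epoch ranks nothing: full window; then fixed top-10%
  expect_equal(schedule_k(0, cfg_atk, 100), list(k = 100L, i0 = 1L))
  expect_equal(schedule_k(1, cfg_atk, 100), list(k = 10L, i0 = 91L))
  expect_equal(schedule_k(9, cfg_atk, 100), list(k = 10L, i0 = 91L))
  # decreasing window: all images at epoch 0 down to top 5% at the end
  expect_equal(schedule_k(0, cfg_dec, 100), list(k = 100L, i0 = 1L))
  cfg_dec30 <- fast_strategy("atk_dec", total_epochs = 30)
  expect_equal(schedule_k(29, cfg_dec30, 100), list(k = 5L, i0 = 96L))

  # windows always valid, width >= 1, for awkward image counts
  for (I in c(1, 2, 7, 13)) {
    for (e in 0:9) {
      w <- schedule_k(e, cfg_dec, I)
      expect_gte(w$i0, 1); expect_gte(w$k, 1)
      expect_lte(w$i0 + w$k - 1, I)
    }
  }
  expect_error(schedule_k(0, cfg_atk, 0), ">= 1")
})

test_that("alpha schedule is fixed, decreasing, or the sharp sentinel", {
  cfg_none <- fast_strategy(smoothing = "none", total_epochs = 10)
  cfg_sm <- fast_strategy(smoothing = "sm", total_epochs = 10)
  cfg_inc <- fast_strategy(smoothing = "sm_inc", total_epochs = 31)

  expect_identical(schedule_alpha(3, cfg_none), Inf)
  expect_equal(schedule_alpha(0, cfg_sm), 20)
  expect_equal(schedule_alpha(9, cfg_sm), 20)
  expect_equal(schedule_alpha(0, cfg_inc), 20)
  expect_equal(schedule_alpha(30, cfg_inc), 1)
  expect_equal(schedule_alpha(15, cfg_inc), 10.5) # midpoint, odd-length schedule
  a <- vapply(0:30, schedule_alpha, numeric(1), cfg = cfg_inc)
  expect_true(all(diff(a) < 0))
})

test_that("per-image loss applies the configured pixel filter", {
  expect_equal(image_loss(c(1, 2, 3), fast_strategy(pixel_strategy = "all"))$loss, 2)
  expect_equal(image_loss(c(1, 1, 1, 10),
                          fast_strategy(pixel_strategy = "bsigma"))$loss, 1)
  cfg <- fast_strategy(pixel_strategy = "tk", tk_fraction = 0.1)
  expect_equal(image_loss(1:10, cfg)$loss, 10)
  # during warmup epochs the filter is held at "all"
  cfg_w <- fast_strategy(pixel_strategy = "bsigma", total_epochs = 9,
                         pixel_warmup_epochs = 3)
  expect_equal(image_loss(c(1, 1, 1, 10), cfg_w, epoch = 0)$loss, 3.25)
  expect_equal(image_loss(c(1, 1, 1, 10), cfg_w, epoch = 3)$loss, 1)
})

test_that("nested loss reduces to the batch mean under ERM, in any order", {
  cfg <- fast_strategy("erm", "none", "all")
  losses <- c(0.9, 0.1, 0.5, 0.7)
  r1 <- nested_loss(losses, 1:4, epoch_reset(), 0, cfg, 4)
  expect_equal(r1$loss, mean(losses))
  expect_equal(r1$weights, rep(1, 4))
  perm <- c(3, 1, 4, 2)
  r2 <- nested_loss(losses[perm], perm, epoch_reset(), 0, cfg, 4)
  expect_equal(r2$loss, r1$loss)
})

test_that("sharp top-1 selection returns the maximum-loss image", {
  cfg <- strategy_config("atk", "none", "all", atk_fraction = 1e-9,
                         total_epochs = 5)
  # pre-seed the epoch state so ranks exist, then rank a batch
  st <- nested_loss(c(0.2, 0.4), c(1, 2), epoch_reset(), 1, cfg, 5)$state
  res <- nested_loss(c(0.9, 0.1, 0.6), c(3, 4, 5), st, 1, cfg, 5)
  expect_equal(res$loss, 0.9)
  expect_equal(res$weights, c(1, 0, 0))
})

test_that("wide smoothed windows reproduce the batch mean", {
  cfg <- strategy_config("atk", "sm", "all", atk_fraction = 1,
                         total_epochs = 5, alpha_start = 20, alpha_end = 1)
  st <- nested_loss(c(0.31, 0.62), c(1, 2), epoch_reset(), 1, cfg, 6)$state
  losses <- c(0.9, 0.15, 0.55, 0.72)
  res <- nested_loss(losses, 3:6, st, 1, cfg, 6)
  # the extreme ranks sit half a rank inside the selector edges, so their
  # weights are 1 - 5e-5 at alpha = 20; the weighted mean matches to ~1e-5
  expect_equal(res$loss, mean(losses), tolerance = 1e-5)
})

test_that("weights are in [0,1]; sharp selection is binary with k survivors", {
  cfg <- strategy_config("atk", "none", "all", atk_fraction = 0.25,
                         total_epochs = 3, seed = 5)
  set.seed(5)
  losses <- runif(20)
  state <- epoch_reset()
  all_w <- c()
  for (i in seq(1, 20, by = 5)) {
    res <- nested_loss(losses[i:(i + 4)], i:(i + 4), state, 1, cfg, 20)
    state <- res$state
    all_w <- c(all_w, res$weights)
  }
  expect_true(all(all_w >= 0 & all_w <= 1))
  expect_true(all(all_w %in% c(0, 1)))
  # once the state is complete, exactly k images sit in the window
  expect_length(selected_images(state, 16, 5), 5)
})

test_that("end-of-epoch incremental selection equals offline sorting", {
  set.seed(23)
  losses <- runif(40) # frozen per-image losses, one-image batches
  cfg <- strategy_config("atk", "none", "all", atk_fraction = 0.1,
                         total_epochs = 3)
  state <- epoch_reset()
  for (i in seq_along(losses)) {
    state <- nested_loss(losses[i], i, state, 1, cfg, 40)$state
  }
  w <- schedule_k(1, cfg, 40)
  incremental_sel <- selected_images(state, w$i0, w$k)
  offline_sel <- sort(order(losses)[w$i0:(w$i0 + w$k - 1)])
  expect_identical(incremental_sel, offline_sel)
})

test_that("epoch reset clears ranking information", {
  st <- epoch_reset()
  expect_length(st$values, 0)
  cfg <- strategy_config("atk", "none", "all", total_epochs = 4)
  # fresh state: uniform weights regardless of strategy
  res <- nested_loss(c(0.9, 0.1), c(1, 2), epoch_reset(), 2, cfg, 10)
  expect_equal(res$weights, c(1, 1))
  # determinism: identical inputs give identical results
  r1 <- nested_loss(c(0.3, 0.8), c(1, 2), epoch_reset(), 0, cfg, 2)
  r2 <- nested_loss(c(0.3, 0.8), c(1, 2), epoch_reset(), 0, cfg, 2)
  expect_identical(r1$loss, r2$loss)
})

test_that("training loss is differentiable with selection held fixed", {
  # finite-difference check of the analytic gradient on a toy image
  set.seed(29)
  C <- 3; P <- 18
  z <- matrix(rnorm(C * P), C, P)
  y <- one_hot_mask(sample(0:2, P, replace = TRUE), C)
  retained <- runif(P) > 0.3
  w <- loss_weights(0.3, 0.7)
  f <- function(z) {
    p <- segrankloss:::softmax_cols(z)
    pl <- combined_pixel_loss(p, y, w, 2)
    mean(pl$losses[retained])
  }
  g <- segrankloss:::loss_gradient_logits(segrankloss:::softmax_cols(z), y,
                                          retained, w, 2)
  eps <- 1e-6
  for (probe in 1:15) {
    i <- sample(C, 1); j <- sample(P, 1)
    zp <- z; zp[i, j] <- zp[i, j] + eps
    zm <- z; zm[i, j] <- zm[i, j] - eps
    expect_equal(g[i, j], (f(zp) - f(zm)) / (2 * eps), tolerance = 1e-5)
  }
})
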