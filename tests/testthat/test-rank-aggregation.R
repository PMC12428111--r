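test_that("windowed averages reproduce closed-form values and reject bad input", {
  expect_equal(average_loss(c(1, 2, 3, 4)), 2.5)
  expect_equal(average_loss(rep(3.7, 11)), 3.7)
  expect_equal(maximum_loss(c(1, 2, 3, 4)), 4)
  expect_equal(maximum_loss(5), 5)
  expect_equal(average_top_k(c(1, 2, 3, 4), 2), 3.5)
  expect_equal(average_top_k(c(1, 2, 3, 4), 1), 4)
  expect_equal(select_average(c(1, 2, 3, 4, 5), i0 = 2, k = 2), 2.5)
  expect_equal(select_average(c(1, 2, 3, 4, 5), i0 = 1, k = 5), 3)

  expect_error(average_loss(numeric(0)), "at least one")
  expect_error(maximum_loss(numeric(0)), "at least one")
  expect_error(average_loss(c(1, NA)), "finite")
  expect_error(average_top_k(1:4, 5), "window")
  expect_error(average_top_k(1:4, 0), "window")
  expect_error(select_average(1:4, i0 = 3, k = 3), "window")
})

test_that("top-k interpolates between maximum and mean, monotonically", {
  set.seed(11)
  for (rep in 1:50) {
    x <- random_losses(sample(1:50, 1))
    n <- length(x)
    expect_equal(average_top_k(x, n), average_loss(x))
    expect_equal(average_top_k(x, 1), maximum_loss(x))
    expect_equal(select_average(x, i0 = 1, k = n), average_loss(x))
    vals <- vapply(seq_len(n), function(k) average_top_k(x, k), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
    expect_true(all(maximum_loss(x) >= vals & vals >= average_loss(x) - 1e-12))
  }
})

test_that("select_average matches the sort-slice-mean oracle on random windows", {
  set.seed(21)
  for (rep in 1:1000) {
    x <- random_losses(sample(1:50, 1))
    n <- length(x)
    k <- sample(n, 1)
    i0 <- sample(n - k + 1, 1)
    oracle <- mean(sort(x)[i0:(i0 + k - 1)])
    expect_equal(select_average(x, i0, k), oracle)
    if (i0 == n - k + 1) expect_equal(select_average(x, i0, k), average_top_k(x, k))
  }
})

test_that("sigmoid indicator has the closed form, saturates, and is monotone", {
  expect_equal(sigmoid_indicator(5, 5, 3), 0.5)
  expect_equal(sigmoid_indicator(6, 5, 1), 1 / (1 + exp(-1)))
  expect_lt(abs(sigmoid_indicator(6, 5, 20) - 1), 1e-8)
  # extreme arguments saturate without overflow
  expect_equal(sigmoid_indicator(1e4, 0, 1e4), 1)
  expect_equal(sigmoid_indicator(-1e4, 0, 1e4), 0)
  expect_true(all(is.finite(sigmoid_indicator(seq(-1e4, 1e4, by = 97), 0, 100))))
  xs <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(sigmoid_indicator(xs, 0, 2)) > 0))
  expect_error(sigmoid_indicator(1, 1, 0), "positive")
  expect_error(sigmoid_indicator(1, 1, -2), "positive")
})

test_that("boxcar selector approximates the rank-window indicator", {
  expect_lt(abs(boxcar_selector(10, 5, 10, 20) - 1), 1e-8)
  expect_lt(boxcar_selector(0, 5, 10, 20), 1e-8)
  expect_equal(boxcar_selector(5, 5, 10, 20), 0.5, tolerance = 1e-8)
  # within 1e-8 of the indicator at integer ranks >= 1 from both edges
  i0 <- 5; k <- 10
  for (i in 1:30) {
    if (abs(i - i0) >= 1 && abs(i - (i0 + k)) >= 1) {
      expect_lt(abs(boxcar_selector(i, i0, k, 20) - (i >= i0 && i < i0 + k)), 1e-8)
    }
  }
  # bounded in [0,1] (saturating, never non-finite) and unimodal with the
  # maximum inside the window; strict interior at moderate sharpness
  set.seed(3)
  for (rep in 1:25) {
    i0 <- runif(1, 1, 20); k <- runif(1, 2, 15); a <- runif(1, 0.5, 30)
    xs <- seq(i0 - 10, i0 + k + 10, length.out = 400)
    z <- boxcar_selector(xs, i0, k, a)
    expect_true(all(is.finite(z) & z >= 0 & z <= 1))
    imax <- which.max(z)
    peak <- xs[imax]
    expect_true(all(diff(z[1:imax]) >= -1e-12))          # rises to the peak
    expect_true(all(diff(z[imax:length(z)]) <= 1e-12))   # falls after it
    expect_gt(peak, i0); expect_lt(peak, i0 + k)
  }
  z_mid <- boxcar_selector(seq(1, 12, by = 0.5), 4, 5, 2)
  expect_true(all(z_mid > 0 & z_mid < 1))
})

test_that("smoothed windowed mean converges to the exact windowed mean", {
  expect_equal(smoothed_select(c(1, 2, 3, 4, 5), selector_config(4, 2, alpha = 50)),
               4.5, tolerance = 1e-6)
  expect_equal(smoothed_select(rep(2.5, 8), selector_config(3, 4, alpha = 5)), 2.5)
  x <- c(0.3, 1.2, 2.2, 3.1, 4.4, 5.0)
  expect_equal(smoothed_select(x, selector_config(1, 6, alpha = 50,
                                                  normalization = "paper_N")),
               average_loss(x), tolerance = 1e-6)
  set.seed(31)
  for (rep in 1:40) {
    x <- sort(random_losses(sample(5:30, 1)))
    x <- x + seq_along(x) * 1e-3 # keep windows clear of ties
    n <- length(x)
    k <- sample(n, 1); i0 <- sample(n - k + 1, 1)
    expect_equal(smoothed_select(x, selector_config(i0, k, alpha = 100)),
                 select_average(x, i0, k), tolerance = 1e-6)
  }
})

test_that("smooth aggregators are continuous in their real arguments", {
  # finite-difference continuity: small input change, small output change
  for (x0 in c(-3.3, 0, 4.7, 15)) {
    h <- 1e-6
    expect_lt(abs(sigmoid_indicator(x0 + h, 5, 7) - sigmoid_indicator(x0, 5, 7)),
              10 * h * 7)
    expect_lt(abs(boxcar_selector(x0 + h, 2, 6, 9) - boxcar_selector(x0, 2, 6, 9)),
              20 * h * 9)
  }
})

test_that("incremental sorted insertion equals a full sort with stable ranks", {
  res <- incremental_sorted_insert(c(1, 3, 5), c(2, 4))
  expect_equal(res$merged, 1:5)
  expect_equal(res$ranks, c(2L, 4L))
  expect_equal(incremental_sorted_insert(numeric(0), c(3, 1, 2))$merged, 1:3)
  expect_error(incremental_sorted_insert(c(1, Inf), 2), "finite")
  expect_error(incremental_sorted_insert(c(3, 1), 2), "ascending")

  # ties insert after existing equal values
  res <- incremental_sorted_insert(c(1, 2, 2, 3), 2)
  expect_equal(res$ranks, 4L)

  # arbitrary batch partitions agree with one full sort
  set.seed(41)
  for (rep in 1:20) {
    draws <- round(runif(1000, 0, 50), 2)
    state <- numeric(0)
    i <- 1
    while (i <= length(draws)) {
      b <- sample(1:40, 1)
      batch <- draws[i:min(i + b - 1, length(draws))]
      res <- incremental_sorted_insert(state, batch)
      state <- res$merged
      i <- i + b
    }
    expect_identical(state, sort(draws))
  }
})
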