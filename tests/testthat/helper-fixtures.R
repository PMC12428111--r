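# Small fixtures shared across tests; everything is generated in code.

# Two-class, two-pixel probability map: the worked continuous-Dice example.
two_pixel_maps <- function() {
  list(pred = rbind(c(0.8, 0.2), c(0.2, 0.8)),
       truth = rbind(c(1, 0), c(0, 1)))
}

random_prob_map <- function(n_classes, n_pixels) {
  z <- matrix(stats::rexp(n_classes * n_pixels), n_classes, n_pixels)
  sweep(z, 2, colSums(z), "/")
}

random_losses <- function(n, max_val = 10) stats::runif(n, 0, max_val)

tiny_dataset <- function(n_images = 6, seed = 42, ...) {
  generate_dataset(synthetic_config(n_images = n_images, height = 32,
                                    width = 32, seed = seed, ...))
}

fast_strategy <- function(image_strategy = "erm", smoothing = "none",
                          pixel_strategy = "all", total_epochs = 4, ...) {
  strategy_config(image_strategy, smoothing, pixel_strategy,
                  total_epochs = total_epochs, ...)
}
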