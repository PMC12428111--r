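#' Synthetic segmentation data with boundary-noisy annotations
#'
#' Emulates the annotation regime of expert-labeled medical images:
#' image-level class labels are accurate, while pixel masks are imprecise
#' near region boundaries (annotation tools favour simplified contours).
#' Images are textured grayscale grids with elliptical foreground objects;
#' the training mask is the clean mask corrupted by bounded, randomized
#' morphological displacement of region boundaries, and the exact set of
#' corrupted pixels is recorded so filter behaviour can be audited.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Synthetic dataset configuration
#'
#' @param n_images Number of images.
#' @param height,width Image dimensions in pixels (>= 16).
#' @param n_classes Number of classes including background (class 0).
#' @param objects_per_image Integer range (length-2) of foreground objects
#'   per image.
#' @param boundary_noise_px Maximum inward/outward boundary displacement of
#'   the training annotation, in pixels (0 = clean annotations).
#' @param noise_fraction Fraction of boundary-band pixels eligible for
#'   perturbation, in `[0, 1]`.
#' @param hard_fraction Fraction of low-contrast "hard" images.
#' @param homogenize If `TRUE`, region interiors are blurred using the
#'   annotated (noisy) mask as the blending boundary, after which the
#'   annotation is treated as the effective ground truth (the control
#'   condition in which pixel labels are correct by construction).
#' @param blur_radius Gaussian sigma (pixels) for homogenization.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_images = 60L, height = 64L, width = 64L,
                             n_classes = 3L, objects_per_image = c(1L, 2L),
                             boundary_noise_px = 3L, noise_fraction = 0.30,
                             hard_fraction = 0.20, homogenize = FALSE,
                             blur_radius = 4, seed = 1L) {
  stopifnot(n_images >= 1, height >= 16, width >= 16, n_classes >= 2,
            length(objects_per_image) == 2, objects_per_image[1] >= 1,
            boundary_noise_px >= 0, boundary_noise_px < min(height, width) / 4,
            noise_fraction >= 0, noise_fraction <= 1,
            hard_fraction >= 0, hard_fraction <= 1, blur_radius > 0)
  structure(list(n_images = as.integer(n_images), height = as.integer(height),
                 width = as.integer(width), n_classes = as.integer(n_classes),
                 objects_per_image = as.integer(objects_per_image),
                 boundary_noise_px = as.integer(boundary_noise_px),
                 noise_fraction = noise_fraction, hard_fraction = hard_fraction,
                 homogenize = homogenize, blur_radius = blur_radius,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Separable Gaussian blur with replicate padding; works for any image size.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  blur_cols <- function(m) {
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(kern)) {
      out <- out + kern[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_cols(t(blur_cols(x))))
}

disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")

binary_dilate <- function(b, r) {
  if (r < 1) return(b)
  EBImage::dilate(b * 1, disc_brush(r)) > 0.5
}

binary_erode <- function(b, r) {
  if (r < 1) return(b)
  EBImage::erode(b * 1, disc_brush(r)) > 0.5
}

# Pixels of the support adjacent (4-connectivity, or image border) to outside.
support_boundary <- function(b) {
  n <- nrow(b); m <- ncol(b)
  pad <- matrix(FALSE, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- b
  inner <- pad[2:(n + 1L), 2:(m + 1L)] &
    pad[1:n, 2:(m + 1L)] & pad[3:(n + 2L), 2:(m + 1L)] &
    pad[2:(n + 1L), 1:m] & pad[2:(n + 1L), 3:(m + 2L)]
  b & !inner
}

#' Randomized morphological boundary perturbation of a label map
#'
#' For each foreground class, a randomly chosen subset (`fraction`) of the
#' boundary band is displaced inward or outward by up to `noise_px` pixels,
#' via erosion/dilation of the class support modulated by smooth random
#' fields (so displacement direction varies smoothly along the contour,
#' emulating an annotator's simplified curve). The result is always a valid
#' one-class-per-pixel label map, and pixels farther than `noise_px` from
#' any clean boundary are untouched. Uses the current RNG state.
#'
#' @param mask Integer matrix of class ids (0 = background).
#' @param noise_px Maximum displacement (>= 1).
#' @param fraction Fraction of the boundary band eligible, in `[0, 1]`.
#' @return An integer matrix of the same shape.
#' @export
perturb_boundaries <- function(mask, noise_px, fraction) {
  stopifnot(noise_px >= 1)
  if (fraction <= 0) return(mask)
  out <- mask
  for (cls in setdiff(sort(unique(as.integer(mask))), 0L)) {
    b <- mask == cls
    if (all(b) || !any(b)) next # no boundary to displace
    d_out <- sample.int(noise_px, 1L)
    d_in <- sample.int(noise_px, 1L)
    direction <- gaussian_blur(matrix(stats::rnorm(length(b)), nrow(b)), 6)
    pick <- gaussian_blur(matrix(stats::rnorm(length(b)), nrow(b)), 4)
    outer_band <- binary_dilate(b, d_out) & !b
    inner_band <- b & !binary_erode(b, d_in)
    band <- outer_band | inner_band
    if (!any(band)) next
    if (fraction >= 1) {
      selected <- band
    } else {
      thr <- stats::quantile(pick[band], probs = 1 - fraction, names = FALSE)
      selected <- band & (pick >= thr)
    }
    add <- outer_band & selected & (direction > 0)
    remove <- inner_band & selected & (direction <= 0)
    out[add] <- cls
    out[remove] <- 0L
  }
  out
}

#' Blur annotated region interiors (homogenization control)
#'
#' Replaces the pixels inside each annotated (noisy-mask) foreground region
#' with a heavily smoothed version of themselves. The blur is computed with
#' the annotated mask as the blending boundary (mask-normalised
#' convolution), so background pixels are bit-identical before and after.
#'
#' @param sample A `seg_sample` (list with `image` and `noisy_mask`).
#' @param blur_radius Gaussian sigma in pixels; 0 leaves the image unchanged.
#' @return The sample with a modified `image`.
#' @export
homogenize_regions <- function(sample, blur_radius) {
  if (blur_radius <= 0) return(sample)
  img <- sample$image
  for (cls in setdiff(sort(unique(as.integer(sample$noisy_mask))), 0L)) {
    ind <- (sample$noisy_mask == cls) * 1
    if (!any(ind > 0)) next
    num <- gaussian_blur(img * ind, blur_radius)
    den <- gaussian_blur(ind, blur_radius)
    inside <- ind > 0
    img[inside] <- num[inside] / pmax(den[inside], 1e-9)
  }
  sample$image <- img
  sample
}

place_objects <- function(cfg, is_hard) {
  h <- cfg$height; w <- cfg$width
  mask <- matrix(0L, h, w)
  n_obj <- if (cfg$objects_per_image[1] == cfg$objects_per_image[2]) {
    cfg$objects_per_image[1]
  } else {
    sample(seq(cfg$objects_per_image[1], cfg$objects_per_image[2]), 1L)
  }
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  for (o in seq_len(n_obj)) {
    cls <- sample(seq_len(cfg$n_classes - 1L), 1L)
    placed <- FALSE
    for (try in 1:25) {
      a <- stats::runif(1, 0.12, 0.28) * min(h, w)
      b <- stats::runif(1, 0.12, 0.28) * min(h, w)
      cy <- stats::runif(1, a + 2, h - a - 2)
      cx <- stats::runif(1, b + 2, w - b - 2)
      th <- stats::runif(1, 0, pi)
      dy <- rows - cy; dx <- cols - cx
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      if (sum(inside & mask == 0L) > 0.6 * sum(inside)) {
        mask[inside] <- cls
        placed <- TRUE
        break
      }
    }
    if (!placed && o == 1L) {
      stop("could not place any object; frame too small for configuration",
           call. = FALSE)
    }
  }
  mask
}

render_image <- function(mask, cfg, is_hard) {
  h <- nrow(mask); w <- ncol(mask)
  contrast <- if (is_hard) 0.65 else 1.0
  base <- 0.30
  # class mean intensities spread above background, compressed on hard images
  means <- base + contrast * seq(0.25, 0.55, length.out = cfg$n_classes - 1L)
  img <- matrix(base, h, w)
  for (cls in seq_len(cfg$n_classes - 1L)) img[mask == cls] <- means[cls]
  texture <- gaussian_blur(matrix(stats::rnorm(h * w, sd = 1), h, w), 2)
  img <- img + 0.06 * texture + matrix(stats::rnorm(h * w, sd = 0.02), h, w)
  img <- pmin(pmax(img, 0), 1)
  round(img * 255) / 255 # 8-bit grid so the PNG external format is lossless
}

#' Generate a synthetic boundary-noisy segmentation dataset
#'
#' Produces `cfg$n_images` samples, each holding the rendered image, the
#' clean ground-truth mask, the boundary-perturbed training annotation, the
#' recorded set of corrupted pixels, and the image-level class labels
#' (always derived from the clean mask: image-level annotation is assumed
#' accurate). With `cfg$homogenize = TRUE` the homogenization control is
#' applied: region interiors are blurred along the annotated mask and the
#' annotation becomes the effective ground truth (no corrupted pixels).
#'
#' @param cfg A [synthetic_config()].
#' @return A `seg_dataset`: list with `samples`, a `manifest` tibble
#'   (per-image class pixel counts and corruption rate), and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  hard <- stats::runif(cfg$n_images) < cfg$hard_fraction
  samples <- vector("list", cfg$n_images)
  for (i in seq_len(cfg$n_images)) {
    clean <- tryCatch(place_objects(cfg, hard[i]),
                      error = function(e) stop(sprintf("image %d: %s", i,
                                                       conditionMessage(e)),
                                               call. = FALSE))
    noisy <- if (cfg$boundary_noise_px >= 1 && cfg$noise_fraction > 0) {
      perturb_boundaries(clean, cfg$boundary_noise_px, cfg$noise_fraction)
    } else clean
    img <- render_image(clean, cfg, hard[i])
    s <- structure(list(id = i, image = img, clean_mask = clean,
                        noisy_mask = noisy, corrupted = noisy != clean,
                        image_labels = sort(unique(as.integer(clean))),
                        is_hard = hard[i]),
                   class = "seg_sample")
    if (cfg$homogenize) {
      s <- homogenize_regions(s, cfg$blur_radius)
      s$image <- round(s$image * 255) / 255
      s$clean_mask <- s$noisy_mask # annotation is now correct by construction
      s$corrupted <- matrix(FALSE, cfg$height, cfg$width)
    }
    samples[[i]] <- s
  }
  manifest <- dplyr::bind_rows(lapply(samples, function(s) {
    counts <- vapply(seq_len(cfg$n_classes) - 1L,
                     function(cl) sum(s$clean_mask == cl), integer(1))
    tibble::tibble(
      id = s$id, is_hard = s$is_hard,
      image_labels = paste(s$image_labels, collapse = ","),
      corruption_rate = mean(s$corrupted),
      !!!stats::setNames(as.list(counts),
                         paste0("px_class_", seq_len(cfg$n_classes) - 1L)))
  }))
  structure(list(samples = samples, manifest = manifest, config = cfg),
            class = "seg_dataset")
}

#' @export
print.seg_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<seg_dataset> %d images, %dx%d, %d classes, noise %dpx @ %.0f%%%s\n",
              cfg$n_images, cfg$height, cfg$width, cfg$n_classes,
              cfg$boundary_noise_px, 100 * cfg$noise_fraction,
              if (cfg$homogenize) ", homogenized" else ""))
  invisible(x)
}

#' Write a dataset to disk as PNG rasters plus a JSON manifest
#'
#' Images are written as 8-bit grayscale PNG, masks as single-channel
#' indexed PNG (pixel value = class id), and `manifest.json` records files,
#' configuration, per-image labels and corruption statistics.
#'
#' @param data A `seg_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "seg_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(data$samples, function(s) {
    img_file <- sprintf("image_%03d.png", s$id)
    clean_file <- sprintf("clean_%03d.png", s$id)
    noisy_file <- sprintf("noisy_%03d.png", s$id)
    png::writePNG(s$image, file.path(dir, img_file))
    png::writePNG(s$clean_mask / 255, file.path(dir, clean_file))
    png::writePNG(s$noisy_mask / 255, file.path(dir, noisy_file))
    list(id = s$id, image = img_file, clean_mask = clean_file,
         noisy_mask = noisy_file, is_hard = s$is_hard,
         image_labels = s$image_labels, corruption_rate = mean(s$corrupted))
  })
  jsonlite::write_json(
    list(config = unclass(data$config), images = entries),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates that rasters agree in shape and that mask class ids lie within
#' the configured range.
#'
#' @param dir Directory containing the PNGs and `manifest.json`.
#' @return A `seg_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg <- do.call(synthetic_config, man$config[names(man$config) != "objects_per_image"] |>
                   c(list(objects_per_image = unlist(man$config$objects_per_image))))
  samples <- lapply(man$images, function(e) {
    img <- png::readPNG(file.path(dir, e$image))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    clean <- round(png::readPNG(file.path(dir, e$clean_mask)) * 255)
    noisy <- round(png::readPNG(file.path(dir, e$noisy_mask)) * 255)
    storage.mode(clean) <- "integer"
    storage.mode(noisy) <- "integer"
    if (!all(dim(img) == dim(clean)) || !all(dim(img) == dim(noisy))) {
      stop(sprintf("raster shapes disagree for image %d", e$id), call. = FALSE)
    }
    if (max(clean) >= cfg$n_classes || max(noisy) >= cfg$n_classes) {
      stop(sprintf("class id out of range for image %d", e$id), call. = FALSE)
    }
    structure(list(id = e$id, image = img, clean_mask = clean,
                   noisy_mask = noisy, corrupted = noisy != clean,
                   image_labels = unlist(e$image_labels),
                   is_hard = isTRUE(e$is_hard)),
              class = "seg_sample")
  })
  manifest <- dplyr::bind_rows(lapply(samples, function(s) {
    counts <- vapply(seq_len(cfg$n_classes) - 1L,
                     function(cl) sum(s$clean_mask == cl), integer(1))
    tibble::tibble(
      id = s$id, is_hard = s$is_hard,
      image_labels = paste(s$image_labels, collapse = ","),
      corruption_rate = mean(s$corrupted),
      !!!stats::setNames(as.list(counts),
                         paste0("px_class_", seq_len(cfg$n_classes) - 1L)))
  }))
  structure(list(samples = samples, manifest = manifest, config = cfg),
            class = "seg_dataset")
}

#' Plot a synthetic sample
#'
#' Panels for the image, the clean mask and the training annotation.
#'
#' @param sample A `seg_sample`.
#' @return A ggplot object.
#' @export
plot_sample <- function(sample) {
  as_df <- function(m, what) {
    tibble::tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                   value = as.vector(m), panel = what)
  }
  df <- dplyr::bind_rows(as_df(sample$image, "image"),
                         as_df(sample$clean_mask / max(1, max(sample$clean_mask)),
                               "clean mask"),
                         as_df(sample$noisy_mask / max(1, max(sample$noisy_mask)),
                               "annotation"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
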