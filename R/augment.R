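#' Augmentation configuration
#'
#' Per-operator enable probabilities and parameter ranges for the
#' conventional augmentations applied jointly to image/mask pairs, plus
#' the synthetic fraction bounds used when mixing real and synthetic
#' samples into training batches (10-50% synthetic by default).
#'
#' @param p_crop,p_rotate,p_translate,p_stretch,p_equalize,p_invert,p_blur,p_noise,p_channel_swap
#'   per-operator application probabilities in `[0, 1]` (default 0.5).
#' @param crop_fraction random-crop side as a fraction of the canvas.
#' @param rotate_degrees maximum rotation magnitude (degrees; the angle is
#'   drawn uniformly in `[-rotate_degrees, rotate_degrees]`).
#' @param translate_fraction maximum translation as a canvas fraction.
#' @param stretch_percentiles contrast-stretch anchor percentiles.
#' @param blur_sigma range of Gaussian blur sigma.
#' @param noise_sd range of additive noise standard deviation.
#' @param synthetic_fraction batch-mixing bounds in `[0, 1]`, ordered.
#' @param min_object_px boundary-clipped objects smaller than this are
#'   dropped.
#' @return an `augment_config` list.
#' @export
augment_config <- function(p_crop = 0.5, p_rotate = 0.5, p_translate = 0.5,
                           p_stretch = 0.5, p_equalize = 0.5, p_invert = 0.5,
                           p_blur = 0.5, p_noise = 0.5, p_channel_swap = 0.5,
                           crop_fraction = 0.8, rotate_degrees = 180,
                           translate_fraction = 0.2,
                           stretch_percentiles = c(0.01, 0.99),
                           blur_sigma = c(0.5, 2), noise_sd = c(0.01, 0.05),
                           synthetic_fraction = c(0.10, 0.50),
                           min_object_px = 4) {
  probs <- c(p_crop, p_rotate, p_translate, p_stretch, p_equalize,
             p_invert, p_blur, p_noise, p_channel_swap)
  stopifnot(all(probs >= 0 & probs <= 1))
  stopifnot(length(synthetic_fraction) == 2,
            synthetic_fraction[1] <= synthetic_fraction[2],
            all(synthetic_fraction >= 0 & synthetic_fraction <= 1))
  stopifnot(crop_fraction > 0, crop_fraction <= 1)
  structure(
    list(p_crop = p_crop, p_rotate = p_rotate, p_translate = p_translate,
         p_stretch = p_stretch, p_equalize = p_equalize, p_invert = p_invert,
         p_blur = p_blur, p_noise = p_noise, p_channel_swap = p_channel_swap,
         crop_fraction = crop_fraction, rotate_degrees = rotate_degrees,
         translate_fraction = translate_fraction,
         stretch_percentiles = stretch_percentiles,
         blur_sigma = blur_sigma, noise_sd = noise_sd,
         synthetic_fraction = synthetic_fraction,
         min_object_px = min_object_px),
    class = "augment_config"
  )
}

#' Randomly augment an image/mask pair
#'
#' Geometric operators (crop, rotation, translation) are applied
#' identically to the image and the mask — the mask with
#' nearest-neighbour resampling, so labels are preserved and never mixed.
#' Intensity operators (contrast stretch, equalization, inversion, blur,
#' noise; channel swap is a no-op on grayscale) touch the image only.
#' Each operator fires independently with its configured probability.
#' Objects reduced below `min_object_px` pixels by cropping or rotation
#' are dropped; no operation ever invents a label.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param s an [instance_set()] on the same canvas.
#' @param cfg an [augment_config()].
#' @param seed integer seed; the output is a pure function of the inputs
#'   and the seed.
#' @return a list with elements `image` and `instances`.
#' @export
augment_sample <- function(image, s, cfg = augment_config(), seed) {
  stopifnot(inherits(s, "instance_set"), inherits(cfg, "augment_config"))
  validate_same_canvas(image, s)
  withr::local_seed(seed)
  lab <- as_label_matrix(s)

  if (stats::runif(1) < cfg$p_crop) {
    side <- pmax(c(8L, 8L), as.integer(round(dim(image) * cfg$crop_fraction)))
    if (any(side > dim(image)))
      stop("crop larger than the canvas", call. = FALSE)
    r0 <- sample.int(nrow(image) - side[1] + 1L, 1)
    c0 <- sample.int(ncol(image) - side[2] + 1L, 1)
    image <- image[r0:(r0 + side[1] - 1L), c0:(c0 + side[2] - 1L)]
    lab <- lab[r0:(r0 + side[1] - 1L), c0:(c0 + side[2] - 1L)]
  }
  if (stats::runif(1) < cfg$p_rotate) {
    ang <- stats::runif(1, -cfg$rotate_degrees, cfg$rotate_degrees)
    rot <- rotate_pair(image, lab, ang)
    image <- rot$image; lab <- rot$lab
  }
  if (stats::runif(1) < cfg$p_translate) {
    sh <- round(stats::runif(2, -cfg$translate_fraction, cfg$translate_fraction) *
                  dim(image))
    image <- shift_matrix(image, sh, fill = 0)
    lab <- shift_matrix(lab, sh, fill = 0L)
  }
  if (stats::runif(1) < cfg$p_stretch) {
    q <- stats::quantile(image, cfg$stretch_percentiles, names = FALSE)
    if (q[2] > q[1]) image <- pmin(pmax((image - q[1]) / (q[2] - q[1]), 0), 1)
  }
  if (stats::runif(1) < cfg$p_equalize) {
    image <- matrix(stats::ecdf(image)(image), nrow(image), ncol(image))
  }
  if (stats::runif(1) < cfg$p_invert) image <- 1 - image
  if (stats::runif(1) < cfg$p_blur) {
    image <- as.matrix(EBImage::gblur(image, stats::runif(1, cfg$blur_sigma[1],
                                                          cfg$blur_sigma[2])))
  }
  if (stats::runif(1) < cfg$p_noise) {
    image <- image + stats::rnorm(length(image), 0,
                                  stats::runif(1, cfg$noise_sd[1], cfg$noise_sd[2]))
  }
  # channel swap: defined for RGB input; a grayscale matrix is unchanged
  invisible(stats::runif(1))

  image[image < 0] <- 0; image[image > 1] <- 1
  out <- as_instance_set(lab)
  out <- keep_objects(out, lengths(out$objects) >= cfg$min_object_px)
  list(image = image, instances = out)
}

# rotate image (bilinear) and labels (nearest) with identical geometry,
# so the pair stays aligned; exact (lossless) for multiples of 90 degrees
rotate_pair <- function(image, lab, ang) {
  a <- ((ang %% 360) + 360) %% 360
  if (isTRUE(all.equal(a %% 90, 0))) {
    k <- as.integer(round(a / 90)) %% 4L
    for (i in seq_len(k)) {
      image <- t(image)[, rev(seq_len(nrow(image))), drop = FALSE]
      lab <- t(lab)[, rev(seq_len(nrow(lab))), drop = FALSE]
    }
    return(list(image = image, lab = lab))
  }
  dm <- dim(image)
  rot_img <- as.matrix(EBImage::rotate(image, ang, output.dim = dm,
                                       filter = "bilinear", bg.col = 0))
  rot_lab <- as.matrix(EBImage::rotate(lab, ang, output.dim = dm,
                                       filter = "none", bg.col = 0))
  storage.mode(rot_lab) <- "integer"
  list(image = rot_img, lab = rot_lab)
}

shift_matrix <- function(m, sh, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - sh[1]
  src_c <- seq_len(ncol(m)) - sh[2]
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Mix real and synthetic samples into training batches
#'
#' Every batch contains a random fraction of synthetic samples drawn
#' uniformly from `fraction_range` (10-50% by default); the synthetic
#' count is `round(batch * u)`.
#'
#' @param real,synthetic lists (or tibbles) of samples.
#' @param fraction_range synthetic-fraction bounds.
#' @param batch batch size.
#' @param n_batches number of batches to draw.
#' @param seed integer seed.
#' @return a tibble with one row per batch: `batch`, `n_synthetic`,
#'   `n_real`, and a list-column `members` of
#'   `tibble(source, index)` compositions.
#' @export
mix_batch <- function(real, synthetic, fraction_range = c(0.10, 0.50),
                      batch, n_batches = 1, seed) {
  stopifnot(length(fraction_range) == 2,
            fraction_range[1] <= fraction_range[2])
  n_real <- if (is.data.frame(real)) nrow(real) else length(real)
  n_syn <- if (is.data.frame(synthetic)) nrow(synthetic) else length(synthetic)
  if (n_syn == 0 && fraction_range[1] > 0)
    stop("no synthetic samples but a positive synthetic fraction", call. = FALSE)
  if (n_real == 0 && batch > 0)
    stop("no real samples to build batches from", call. = FALSE)
  withr::local_seed(seed)
  purrr::map_dfr(seq_len(n_batches), function(bi) {
    u <- stats::runif(1, fraction_range[1], fraction_range[2])
    k <- min(as.integer(round(batch * u)), batch)
    kr <- batch - k
    members <- tibble::tibble(
      source = c(rep("synthetic", k), rep("real", kr)),
      index = c(
        if (k > 0) sample.int(n_syn, k, replace = k > n_syn) else integer(),
        if (kr > 0) sample.int(n_real, kr, replace = kr > n_real) else integer()
      )
    )
    tibble::tibble(batch = bi, n_synthetic = k, n_real = kr,
                   members = list(members))
  })
}
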