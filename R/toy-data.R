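#' Generate a deterministic toy microscopy dataset
#'
#' Produces labelled fixture images for exercising the pipeline without any
#' real data: non-overlapping blob-shaped nuclei (perturbed ellipses) placed
#' uniformly at random on a constant background, rendered as a smoothed
#' foreground/background intensity image with additive Gaussian noise. The
#' ground truth is exact by construction and the whole output is a pure
#' function of `seed`.
#'
#' Two "styles" can be emulated by swapping `fg` and `bg` (bright nuclei on
#' dark background vs. the inverse), which is what the style-clustering
#' fixtures use.
#'
#' @param n_images number of image/mask pairs.
#' @param objects_per_image inclusive integer range `c(lo, hi)` of object
#'   counts per image.
#' @param diameter inclusive range `c(lo, hi)` of nominal equivalent
#'   diameters in pixels.
#' @param canvas canvas `c(height, width)` in pixels.
#' @param seed integer seed (required: fixtures must be reproducible).
#' @param fg,bg mean foreground / background intensity in `[0, 1]`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param blur_sigma Gaussian smoothing sigma applied before noise.
#' @param eccentricity,irregularity shape parameters passed to
#'   [simulate_shape()].
#' @param margin minimum empty pixels kept between objects.
#' @param max_tries placement retries per object before giving up.
#' @return a tibble with one row per image: `id`, list-columns `image`
#'   (numeric matrix in `[0, 1]`) and `instances` (an [instance_set()]), and
#'   `n_objects`.
#' @examples
#' d <- make_toy_dataset(1, objects_per_image = c(5, 5), seed = 7)
#' d$n_objects
#' @export
make_toy_dataset <- function(n_images = 1,
                             objects_per_image = c(8, 15),
                             diameter = c(16, 24),
                             canvas = c(128, 128),
                             seed,
                             fg = 0.8, bg = 0.15,
                             noise_sd = 0.03,
                             blur_sigma = 1,
                             eccentricity = 0.4,
                             irregularity = 0.15,
                             margin = 2,
                             max_tries = 1000) {
  stopifnot(n_images >= 0, length(objects_per_image) == 2, length(diameter) == 2)
  if (any(objects_per_image < 0) || any(diameter <= 0))
    stop("ranges must be non-negative", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  withr::local_seed(seed)

  rows <- purrr::map(seq_len(n_images), function(i) {
    n_obj <- if (objects_per_image[1] == objects_per_image[2]) {
      objects_per_image[1]
    } else {
      sample(objects_per_image[1]:objects_per_image[2], 1)
    }
    s <- place_toy_objects(n_obj, diameter, canvas, eccentricity,
                           irregularity, margin, max_tries)
    img <- render_toy_image(s, fg, bg, noise_sd, blur_sigma)
    list(id = sprintf("toy_%03d", i), image = img, instances = s)
  })
  tibble::tibble(
    id = purrr::map_chr(rows, "id"),
    image = purrr::map(rows, "image"),
    instances = purrr::map(rows, "instances"),
    n_objects = purrr::map_int(rows, ~ n_objects(.x$instances))
  )
}

place_toy_objects <- function(n_obj, diameter, canvas, eccentricity,
                              irregularity, margin, max_tries) {
  occupied <- matrix(FALSE, canvas[1], canvas[2])
  objects <- vector("list", n_obj)
  for (i in seq_len(n_obj)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      d <- stats::runif(1, diameter[1], diameter[2])
      patch <- simulate_shape(d,
        eccentricity = stats::runif(1, 0, eccentricity),
        irregularity = irregularity
      )
      fr <- canvas[1] - nrow(patch) + 1L
      fc <- canvas[2] - ncol(patch) + 1L
      if (fr < 1 || fc < 1) next
      at <- c(sample.int(fr, 1), sample.int(fc, 1))
      px <- place_patch(patch, at, canvas)
      if (!any(occupied[px])) {
        # mark the object grown by `margin` as occupied so later objects
        # keep their distance
        occupied[place_patch_clipped(grow_patch(patch, margin),
                                     at - margin, canvas)] <- TRUE
        objects[[i]] <- px
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place object ", i, " after ", max_tries,
           " tries; canvas too crowded", call. = FALSE)
    }
  }
  if (!n_obj) return(empty_instance_set(canvas))
  instance_set(objects, dim = canvas)
}

render_toy_image <- function(s, fg, bg, noise_sd, blur_sigma) {
  img <- matrix(bg, s$dim[1], s$dim[2])
  for (px in s$objects) img[px] <- fg
  if (blur_sigma > 0) img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma))
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}
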