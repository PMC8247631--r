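#' Empirical style statistics of a set of annotated images
#'
#' Collects the distributions that characterise a style for synthesis:
#' objects per image, equivalent diameters, nearest-neighbour centroid
#' spacing, and foreground/background intensities (for the baseline
#' renderer). All are stored as empirical samples; synthesis draws from
#' them, so generated values always lie within the observed range.
#'
#' @param sets list of [instance_set()]s (rough pre-segmentation masks are
#'   acceptable).
#' @param images list of matching intensity images (same length/order).
#' @param max_samples cap on stored intensity samples per class.
#' @return a `style_stats` object.
#' @export
style_statistics <- function(sets, images, max_samples = 5000) {
  if (inherits(sets, "instance_set")) sets <- list(sets)
  if (is.matrix(images)) images <- list(images)
  if (!length(sets) || length(sets) != length(images))
    stop("need matched, non-empty lists of masks and images", call. = FALSE)
  counts <- purrr::map_int(sets, n_objects)
  diameters <- unlist(purrr::map(sets, ~ 2 * sqrt(lengths(.x$objects) / pi)))
  spacing <- unlist(purrr::map(sets, nn_spacing))
  fg <- c(); bg <- c()
  for (i in seq_along(sets)) {
    mask <- as_label_matrix(sets[[i]]) > 0
    fg <- c(fg, images[[i]][mask])
    bg <- c(bg, images[[i]][!mask])
  }
  if (length(fg) > max_samples) fg <- fg[seq(1, length(fg), length.out = max_samples)]
  if (length(bg) > max_samples) bg <- bg[seq(1, length(bg), length.out = max_samples)]
  structure(
    list(counts = counts, diameters = diameters, spacing = spacing,
         fg = fg, bg = bg, n_images = length(sets)),
    class = "style_stats"
  )
}

nn_spacing <- function(s) {
  if (n_objects(s) < 2) return(numeric())
  td <- tidy(s)
  d <- as.matrix(stats::dist(cbind(td$row, td$col)))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' @export
print.style_stats <- function(x, ...) {
  cat(sprintf(
    "<style_stats> from %d image(s): %.0f-%.0f objects/image, median diameter %.1f px\n",
    x$n_images, min(x$counts), max(x$counts),
    if (length(x$diameters)) stats::median(x$diameters) else NA
  ))
  invisible(x)
}

#' @export
glance.style_stats <- function(x, ...) {
  tibble::tibble(
    n_images = x$n_images,
    median_count = stats::median(x$counts),
    median_diameter = if (length(x$diameters)) stats::median(x$diameters) else NA_real_,
    median_spacing = if (length(x$spacing)) stats::median(x$spacing) else NA_real_,
    fg_mean = if (length(x$fg)) mean(x$fg) else NA_real_,
    bg_mean = if (length(x$bg)) mean(x$bg) else NA_real_
  )
}

#' Generate a style-matched synthetic nucleus mask
#'
#' Draws an object count and per-object diameters from the style's
#' empirical distributions, takes each shape either from the database
#' (rescaled to the drawn diameter) with probability `db_fraction` or from
#' the parametric simulator, and places objects by rejection sampling so
#' they never overlap.
#'
#' @param stats a `style_stats`.
#' @param db a `shape_db`, or `NULL` to simulate every shape.
#' @param canvas canvas `c(height, width)`, at least 64 x 64.
#' @param db_fraction per-object probability of drawing from the database
#'   (default 0.5, i.e. roughly half from each source).
#' @param seed integer seed.
#' @param margin minimum empty pixels between objects.
#' @param max_tries placement retries per object.
#' @return an [instance_set()]; labels are `1..n`.
#' @export
generate_mask <- function(stats, db = NULL, canvas = c(512, 512),
                          db_fraction = 0.5, seed = NULL, margin = 1,
                          max_tries = 1000) {
  stopifnot(inherits(stats, "style_stats"))
  if (any(canvas < 64)) stop("canvas must be at least 64 x 64", call. = FALSE)
  if (is.null(db)) db_fraction <- 0
  if (!is.null(seed)) withr::local_seed(seed)
  n_obj <- sample_empirical(stats$counts, 1)
  if (n_obj == 0) return(empty_instance_set(canvas))
  occupied <- matrix(FALSE, canvas[1], canvas[2])
  objects <- vector("list", n_obj)
  for (i in seq_len(n_obj)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      d <- max(3, sample_empirical(stats$diameters, 1))
      patch <- if (stats::runif(1) < db_fraction) {
        sample_db_shape(db, d)
      } else {
        simulate_shape(d, eccentricity = stats::runif(1, 0, 0.6),
                       irregularity = 0.2)
      }
      fr <- canvas[1] - nrow(patch) + 1L
      fc <- canvas[2] - ncol(patch) + 1L
      if (fr < 1 || fc < 1) next
      at <- c(sample.int(fr, 1), sample.int(fc, 1))
      px <- place_patch(patch, at, canvas)
      if (!any(occupied[px])) {
        occupied[place_patch_clipped(grow_patch(patch, margin),
                                     at - margin, canvas)] <- TRUE
        objects[[i]] <- px
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("mask generation failed: canvas too crowded after ",
           max_tries, " tries", call. = FALSE)
  }
  instance_set(objects, dim = canvas)
}

sample_empirical <- function(x, n) {
  if (!length(x)) stop("empty empirical distribution", call. = FALSE)
  x[sample.int(length(x), n, replace = TRUE)]
}

#' Baseline statistical style renderer
#'
#' A non-neural renderer satisfying the style-renderer contract: turns a
#' binary nucleus mask into a synthetic image by drawing foreground pixels
#' from the style's foreground intensity distribution and background
#' pixels from its background distribution, then smoothing and adding mild
#' noise. Deterministic given `seed`; output canvas equals the mask
#' canvas. A learned image-to-image renderer can be substituted anywhere
#' this function is accepted.
#'
#' @param mask an [instance_set()].
#' @param stats a `style_stats` carrying intensity distributions.
#' @param seed integer seed.
#' @param blur_sigma Gaussian smoothing sigma.
#' @param noise_sd additive noise after smoothing.
#' @return a numeric image matrix in `[0, 1]`.
#' @export
render_baseline <- function(mask, stats, seed = NULL, blur_sigma = 1,
                            noise_sd = 0.02) {
  stopifnot(inherits(mask, "instance_set"), inherits(stats, "style_stats"))
  if (!length(stats$fg) || !length(stats$bg))
    stop("style statistics lack intensity distributions", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  m <- as_label_matrix(mask) > 0
  img <- matrix(sample_empirical(stats$bg, length(m)), nrow(m), ncol(m))
  if (any(m)) img[m] <- sample_empirical(stats$fg, sum(m))
  if (blur_sigma > 0) img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma))
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a style-matched synthetic training set
#'
#' For every style cluster: estimates style statistics from the member
#' images and masks, builds a shape database from the member masks, and
#' generates `per_style` synthetic mask/image pairs with [generate_mask()]
#' and the given renderer. The output has exactly
#' `per_style * n_clusters` pairs.
#'
#' @param clusters a `style_clustering` (images with `NA` assignment are
#'   skipped).
#' @param data a tibble with columns `id`, `image`, `instances` matching
#'   `clusters$ids` (as produced by [make_toy_dataset()]).
#' @param per_style pairs to generate per style (default 20).
#' @param canvas synthetic canvas `c(height, width)`.
#' @param renderer a style renderer `function(mask, stats, seed)`
#'   (default [render_baseline()]).
#' @param db_fraction see [generate_mask()].
#' @param seed integer seed; each pair derives its own sub-seed.
#' @return a tibble with columns `style`, `pair`, `id` and list-columns
#'   `image`, `instances`.
#' @export
generate_training_set <- function(clusters, data, per_style = 20,
                                  canvas = c(512, 512),
                                  renderer = render_baseline,
                                  db_fraction = 0.5, seed) {
  stopifnot(inherits(clusters, "style_clustering"))
  stopifnot(all(c("id", "image", "instances") %in% names(data)))
  idx <- match(clusters$ids, data$id)
  if (anyNA(idx)) stop("clustering ids missing from data", call. = FALSE)
  styles <- sort(unique(clusters$assignment[!is.na(clusters$assignment)]))
  out <- purrr::map_dfr(styles, function(st) {
    members <- idx[which(clusters$assignment == st)]
    res <- tryCatch({
      stats <- style_statistics(data$instances[members], data$image[members])
      db <- tryCatch(build_shape_db(data$instances[members]),
                     error = function(e) NULL)
      purrr::map_dfr(seq_len(per_style), function(j) {
        sub_seed <- (as.integer(seed) + 7919L * as.integer(st) + j) %% 2147483647L
        mask <- generate_mask(stats, db, canvas = canvas,
                              db_fraction = if (is.null(db)) 0 else db_fraction,
                              seed = sub_seed)
        img <- renderer(mask, stats, seed = sub_seed)
        tibble::tibble(
          style = st, pair = j,
          id = sprintf("synthetic_s%03d_p%03d", st, j),
          image = list(img), instances = list(mask)
        )
      })
    }, error = function(e) {
      stop("synthesis failed for style ", st, ": ", conditionMessage(e),
           call. = FALSE)
    })
    res
  })
  if (!nrow(out)) {
    out <- tibble::tibble(style = integer(), pair = integer(),
                          id = character(), image = list(), instances = list())
  }
  out
}
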