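#' Estimate the typical nucleus diameter of an instance set
#'
#' The median equivalent-circle diameter, `2 * sqrt(area / pi)`, over the
#' objects. The median (rather than the mean) is robust to debris and
#' outlier objects; pass `stat = mean` to change it.
#'
#' @param s an [instance_set()] with at least one object.
#' @param stat summary function over per-object diameters.
#' @return diameter in pixels.
#' @export
estimate_typical_diameter <- function(s, stat = stats::median) {
  stopifnot(inherits(s, "instance_set"))
  if (!n_objects(s))
    stop("cannot estimate a diameter from an empty instance set; ",
         "supply a prior diameter instead", call. = FALSE)
  stat(2 * sqrt(lengths(s$objects) / pi))
}

#' Plan a size-normalizing rescale
#'
#' Computes the scale factor that maps an estimated typical nucleus
#' diameter onto the pipeline's operating point (40 px by default, where
#' the downstream segmenter performs best).
#'
#' @param d estimated typical diameter in pixels (`> 0`).
#' @param target target diameter in pixels (default 40).
#' @param canvas working canvas side in pixels (default 512).
#' @return a `scale_plan`: a one-row tibble with `estimated_diameter`,
#'   `target_diameter`, `factor`, `canvas`.
#' @examples
#' plan_scale(20)$factor  # 2: a 20-px image is doubled
#' @export
plan_scale <- function(d, target = 40, canvas = 512) {
  if (!is.finite(d) || d <= 0) stop("diameter must be positive", call. = FALSE)
  if (target <= 0) stop("target must be positive", call. = FALSE)
  out <- tibble::tibble(
    estimated_diameter = d, target_diameter = target,
    factor = target / d, canvas = as.integer(canvas)
  )
  class(out) <- c("scale_plan", class(out))
  out
}

#' Rescale an image/instance pair
#'
#' The intensity image is resampled with bilinear interpolation; each
#' object mask is resampled independently with nearest-neighbour
#' interpolation (labels are preserved and never mixed, and overlapping
#' objects survive). Objects that shrink to zero pixels are dropped.
#'
#' @param image numeric matrix.
#' @param s an [instance_set()] on the same canvas.
#' @param plan a `scale_plan` from [plan_scale()], or a bare numeric factor.
#' @return a list with elements `image` and `instances` on the rescaled
#'   canvas.
#' @export
rescale_pair <- function(image, s, plan) {
  factor <- if (is.numeric(plan) && !inherits(plan, "scale_plan")) plan else plan$factor
  stopifnot(is.finite(factor), factor > 0)
  stopifnot(inherits(s, "instance_set"))
  validate_same_canvas(image, s)
  new_dim <- as.integer(round(s$dim * factor))
  if (any(new_dim < 8))
    stop("rescaled canvas would be smaller than 8 px", call. = FALSE)
  if (identical(new_dim, s$dim) && isTRUE(all.equal(factor, 1))) {
    return(list(image = image, instances = s))
  }
  img2 <- as.matrix(EBImage::resize(image, w = new_dim[1], h = new_dim[2],
                                    filter = "bilinear"))
  objects <- list()
  labels <- integer()
  h <- s$dim[1]
  for (i in seq_along(s$objects)) {
    px <- s$objects[[i]]
    r <- (px - 1L) %% h + 1L
    cc <- (px - 1L) %/% h + 1L
    r0 <- min(r); c0 <- min(cc)
    patch <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
    patch[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
    pw <- max(1L, as.integer(round(nrow(patch) * factor)))
    ph <- max(1L, as.integer(round(ncol(patch) * factor)))
    sp <- as.matrix(EBImage::resize(patch * 1, w = pw, h = ph,
                                    filter = "none")) > 0
    at <- c(as.integer(round((r0 - 1) * factor)) + 1L,
            as.integer(round((c0 - 1) * factor)) + 1L)
    npx <- place_patch_clipped(sp, at, new_dim)
    if (length(npx)) {
      objects <- c(objects, list(npx))
      labels <- c(labels, s$labels[i])
    }
  }
  inst <- if (length(objects)) {
    instance_set(objects, dim = new_dim, labels = labels)
  } else {
    empty_instance_set(new_dim)
  }
  list(image = img2, instances = inst)
}

tile_starts <- function(n, size) {
  if (n <= size) return(1L)
  step <- max(1L, size %/% 2L)  # 50% overlap
  sort(unique(c(seq.int(1L, n - size + 1L, by = step), n - size + 1L)))
}

#' Crop or pad an image/mask pair to fixed-size tiles
#'
#' Small inputs are zero-padded at the bottom/right to `size x size`
#' (content anchored top-left); large inputs are cut into `size x size`
#' tiles with 50% overlap so every pixel is covered at least once. Objects
#' are clipped at tile borders but keep their labels within a tile.
#'
#' @param image numeric matrix.
#' @param s an [instance_set()] on the same canvas (optional: `NULL` tiles
#'   the image alone).
#' @param size tile side in pixels (default 512).
#' @return a tibble with one row per tile: `tile`, `row0`, `col0` (1-based
#'   offsets of the tile origin in the padded canvas) and list-columns
#'   `image` and `instances`.
#' @export
crop_or_pad <- function(image, s = NULL, size = 512) {
  stopifnot(size > 0)
  size <- as.integer(size)
  dim0 <- dim(image)
  pad_dim <- pmax(dim0, size)
  if (any(pad_dim > dim0)) {
    padded <- matrix(0, pad_dim[1], pad_dim[2])
    padded[seq_len(dim0[1]), seq_len(dim0[2])] <- image
    image <- padded
  }
  rs <- tile_starts(pad_dim[1], size)
  cs <- tile_starts(pad_dim[2], size)
  grid <- expand.grid(row0 = rs, col0 = cs)
  tiles <- purrr::pmap(grid, function(row0, col0) {
    img_t <- image[row0:(row0 + size - 1L), col0:(col0 + size - 1L)]
    inst_t <- if (is.null(s)) NULL else {
      crop_instances(s, row0, col0, size)
    }
    list(image = img_t, instances = inst_t)
  })
  tibble::tibble(
    tile = seq_len(nrow(grid)),
    row0 = as.integer(grid$row0), col0 = as.integer(grid$col0),
    image = purrr::map(tiles, "image"),
    instances = purrr::map(tiles, "instances")
  )
}

# clip an instance set to a size x size window at (row0, col0)
crop_instances <- function(s, row0, col0, size) {
  h <- s$dim[1]
  objects <- list()
  labels <- integer()
  for (i in seq_along(s$objects)) {
    px <- s$objects[[i]]
    r <- (px - 1L) %% h + 1L - row0 + 1L
    cc <- (px - 1L) %/% h + 1L - col0 + 1L
    keep <- r >= 1L & r <= size & cc >= 1L & cc <= size
    if (any(keep)) {
      objects <- c(objects, list(r[keep] + (cc[keep] - 1L) * size))
      labels <- c(labels, s$labels[i])
    }
  }
  if (!length(objects)) return(empty_instance_set(c(size, size)))
  instance_set(objects, dim = c(size, size), labels = labels)
}

#' Stitch tile instance sets back onto a full canvas
#'
#' Re-places each tile's objects at the tile origin and flattens
#' last-tile-wins, then re-extracts connected labels. Intended for
#' reassembling overlap-tiled inference output.
#'
#' @param tiles a tibble from [crop_or_pad()] (with non-`NULL` instances).
#' @param dim the original canvas `c(height, width)`.
#' @return an [instance_set()] on the original canvas.
#' @export
stitch_tiles <- function(tiles, dim) {
  canvas <- matrix(0L, dim[1], dim[2])
  next_label <- 1L
  for (i in seq_len(nrow(tiles))) {
    s <- tiles$instances[[i]]
    if (is.null(s) || !n_objects(s)) next
    size <- s$dim[1]
    for (j in seq_along(s$objects)) {
      px <- s$objects[[j]]
      r <- (px - 1L) %% size + tiles$row0[i]
      cc <- (px - 1L) %/% size + tiles$col0[i]
      keep <- r >= 1L & r <= dim[1] & cc >= 1L & cc <= dim[2]
      canvas[r[keep] + (cc[keep] - 1L) * dim[1]] <- next_label
      next_label <- next_label + 1L
    }
  }
  as_instance_set(canvas)
}
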