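#' Build a nucleus shape database from instance sets
#'
#' Crops every object to its bounding box and attaches shape descriptors
#' (area, equivalent diameter, eccentricity, solidity), all recomputable
#' from the stored patch. Objects that are not connected keep only their
#' largest connected component.
#'
#' @param sets a list of [instance_set()]s (a single set is accepted).
#' @return a `shape_db`: list with `patches` (logical matrices) and
#'   `descriptors` (a tibble, one row per entry).
#' @export
build_shape_db <- function(sets) {
  if (inherits(sets, "instance_set")) sets <- list(sets)
  patches <- list()
  for (s in sets) {
    for (i in seq_len(n_objects(s))) {
      p <- crop_to_bbox(object_mask(s, i))
      lab <- EBImage::bwlabel(p * 1)
      if (max(lab) > 1) {  # keep the largest component only
        sizes <- tabulate(lab[lab > 0])
        p <- crop_to_bbox(lab == which.max(sizes))
      }
      patches[[length(patches) + 1L]] <- p
    }
  }
  if (!length(patches))
    stop("no objects to build a shape database from", call. = FALSE)
  desc <- purrr::imap_dfr(patches, function(p, i) {
    dplyr::bind_cols(tibble::tibble(entry = i), shape_descriptors(p))
  })
  structure(list(patches = patches, descriptors = desc), class = "shape_db")
}

#' @export
print.shape_db <- function(x, ...) {
  cat(sprintf("<shape_db> %d nucleus shape(s), median diameter %.1f px\n",
              length(x$patches), stats::median(x$descriptors$eq_diameter)))
  invisible(x)
}

#' @export
tidy.shape_db <- function(x, ...) x$descriptors

#' Shape descriptors of a binary patch
#'
#' @param patch logical/binary matrix.
#' @return a one-row tibble: `area` (px), `eq_diameter`
#'   (`2*sqrt(area/pi)`), `eccentricity` (from central second moments) and
#'   `solidity` (area over convex-hull area, capped at 1).
#' @export
shape_descriptors <- function(patch) {
  idx <- which(patch != 0)
  area <- length(idx)
  stopifnot(area > 0)
  r <- (idx - 1L) %% nrow(patch) + 1L
  cc <- (idx - 1L) %/% nrow(patch) + 1L
  mu20 <- stats::var(r) * (area - 1) / area
  mu02 <- stats::var(cc) * (area - 1) / area
  mu11 <- if (area > 1) stats::cov(r, cc) * (area - 1) / area else 0
  if (area == 1) mu20 <- mu02 <- mu11 <- 0
  tr <- mu20 + mu02
  det_part <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + det_part) / 2
  l2 <- (tr - det_part) / 2
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  tibble::tibble(
    area = area,
    eq_diameter = 2 * sqrt(area / pi),
    eccentricity = ecc,
    solidity = min(1, area / convex_hull_pixels(r, cc))
  )
}

# pixels whose centres fall inside (or on) the convex hull of (r, c)
convex_hull_pixels <- function(r, cc) {
  pts <- unique(cbind(r, cc))
  if (nrow(pts) < 3) return(max(nrow(pts), 1))
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hv <- pts[hull, , drop = FALSE]
  grid <- expand.grid(r = min(r):max(r), c = min(cc):max(cc))
  # a point is inside a convex polygon iff the edge cross-products all
  # share one sign (orientation of chull's output does not matter then)
  all_pos <- rep(TRUE, nrow(grid))
  all_neg <- rep(TRUE, nrow(grid))
  nh <- nrow(hv)
  for (k in seq_len(nh)) {
    p1 <- hv[k, ]
    p2 <- hv[if (k == nh) 1 else k + 1, ]
    cross <- (p2[1] - p1[1]) * (grid$c - p1[2]) - (p2[2] - p1[2]) * (grid$r - p1[1])
    all_pos <- all_pos & cross >= -1e-9
    all_neg <- all_neg & cross <= 1e-9
  }
  sum(all_pos | all_neg)
}

#' Draw a shape from the database near a target diameter
#'
#' Descriptor-space nearest sampling: picks uniformly among the `pool`
#' entries closest to the requested equivalent diameter and rescales the
#' patch (nearest-neighbour) to hit the target.
#'
#' @param db a `shape_db`.
#' @param diameter target equivalent diameter in pixels.
#' @param pool number of nearest candidates to sample among.
#' @return a logical patch.
#' @export
sample_db_shape <- function(db, diameter, pool = 5) {
  d <- db$descriptors$eq_diameter
  cand <- order(abs(d - diameter))[seq_len(min(pool, length(d)))]
  pick <- cand[sample.int(length(cand), 1)]
  patch <- db$patches[[pick]]
  f <- diameter / d[pick]
  if (abs(f - 1) < 0.05) return(patch)
  pw <- max(2L, as.integer(round(nrow(patch) * f)))
  ph <- max(2L, as.integer(round(ncol(patch) * f)))
  out <- as.matrix(EBImage::resize(patch * 1, w = pw, h = ph, filter = "none")) > 0
  if (!any(out)) patch else crop_to_bbox(out)
}
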