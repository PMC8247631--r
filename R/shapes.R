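#' Simulate a nucleus-shaped binary patch
#'
#' Generates a perturbed-ellipse nucleus shape in the spirit of parametric
#' fluorescence-cell simulators: an ellipse of the requested equivalent
#' diameter and eccentricity, with its radial profile modulated by a smooth
#' low-order random perturbation of amplitude proportional to `irregularity`.
#' The shape is star-convex about its centre, hence connected and simply
#' connected.
#'
#' @param diameter target equivalent-circle diameter in pixels (`>= 3`).
#' @param eccentricity ellipse eccentricity in `[0, 1)`.
#' @param irregularity perturbation amplitude `>= 0` (0 = exact ellipse;
#'   values above ~0.8 are clamped to keep the radius positive).
#' @param seed optional integer seed; when given, the patch is a pure
#'   function of the arguments.
#' @param rotation ellipse orientation in radians; `NULL` (default) draws it
#'   uniformly at random.
#' @return a logical matrix cropped to the shape's bounding box.
#' @examples
#' p <- simulate_shape(20, eccentricity = 0.3, irregularity = 0.1, seed = 1)
#' sum(p) / (pi * 10^2)  # close to 1
#' @export
simulate_shape <- function(diameter, eccentricity = 0, irregularity = 0,
                           seed = NULL, rotation = NULL) {
  if (diameter < 3) stop("diameter must be at least 3 pixels", call. = FALSE)
  stopifnot(eccentricity >= 0, eccentricity < 1, irregularity >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  irregularity <- min(irregularity, 0.8)

  r0 <- diameter / 2
  # semi-axes with product r0^2 so the unperturbed area is pi * r0^2
  q <- (1 - eccentricity^2)^(1 / 4)
  a <- r0 / q
  b <- r0 * q
  phi <- if (is.null(rotation)) stats::runif(1, 0, pi) else rotation

  # smooth radial perturbation: low-order Fourier series, peak-normalised
  kk <- 2:5
  cc <- stats::rnorm(length(kk), 0, 1 / kk)
  ss <- stats::rnorm(length(kk), 0, 1 / kk)
  perturb <- function(theta) {
    g <- rowSums(vapply(seq_along(kk), function(i) {
      cc[i] * cos(kk[i] * theta) + ss[i] * sin(kk[i] * theta)
    }, numeric(length(theta))))
    peak <- max(abs(g), 1e-9)
    1 + irregularity * g / peak
  }

  half <- ceiling(max(a, b) * (1 + irregularity)) + 1
  side <- 2L * half + 1L
  ctr <- half + 1
  rows <- matrix(seq_len(side), side, side) - ctr
  cols <- matrix(seq_len(side), side, side, byrow = TRUE) - ctr
  theta <- atan2(rows, cols)
  rad <- sqrt(rows^2 + cols^2)
  t_ell <- theta - phi
  r_ell <- a * b / sqrt((b * cos(t_ell))^2 + (a * sin(t_ell))^2)
  inside <- rad <= r_ell * perturb(theta)
  crop_to_bbox(inside)
}

crop_to_bbox <- function(mask) {
  rs <- which(rowSums(mask) > 0)
  cs <- which(colSums(mask) > 0)
  if (!length(rs)) return(matrix(FALSE, 0, 0))
  mask[rs[1]:rs[length(rs)], cs[1]:cs[length(cs)], drop = FALSE]
}

# place a binary patch's pixels at (top-left row, col) on a h x w canvas;
# returns linear pixel indices, or NULL if the patch sticks out
place_patch <- function(patch, at, dim) {
  pr <- nrow(patch); pc <- ncol(patch)
  r0 <- at[1]; c0 <- at[2]
  if (r0 < 1 || c0 < 1 || r0 + pr - 1 > dim[1] || c0 + pc - 1 > dim[2]) return(NULL)
  idx <- which(patch)
  prow <- (idx - 1L) %% pr          # 0-based offset within the patch
  pcol <- (idx - 1L) %/% pr
  as.integer((r0 + prow) + (c0 + pcol - 1L) * dim[1])
}

# grow a patch by `margin` pixels (Chebyshev), enlarging the canvas so the
# halo is not clipped at the patch bounding box
grow_patch <- function(patch, margin) {
  if (margin <= 0) return(patch)
  padded <- matrix(FALSE, nrow(patch) + 2L * margin, ncol(patch) + 2L * margin)
  padded[margin + seq_len(nrow(patch)), margin + seq_len(ncol(patch))] <- patch
  brush <- matrix(TRUE, 2L * margin + 1L, 2L * margin + 1L)
  as.matrix(EBImage::dilate(padded * 1, brush)) > 0
}

# like place_patch but silently clips the out-of-canvas part
place_patch_clipped <- function(patch, at, dim) {
  idx <- which(patch)
  if (!length(idx)) return(integer())
  pr <- nrow(patch)
  row <- at[1] + (idx - 1L) %% pr
  col <- at[2] + (idx - 1L) %/% pr
  keep <- row >= 1L & row <= dim[1] & col >= 1L & col <= dim[2]
  as.integer(row[keep] + (col[keep] - 1L) * dim[1])
}
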