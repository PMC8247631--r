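#' Extract appearance features from a microscopy image
#'
#' A fixed, ordered feature set describing image "style": intensity
#' statistics (mean, sd, 1st/50th/99th percentiles), gray-level
#' co-occurrence texture statistics (contrast, correlation, homogeneity,
#' entropy; averaged over the horizontal and vertical unit offsets, which
#' makes them invariant under 90-degree rotation), mean gradient magnitude
#' (edge density) and Otsu foreground fraction.
#'
#' Maximal constant borders are trimmed before measuring, so the features
#' are invariant to padding an image with a constant background frame.
#'
#' @param image numeric matrix in `[0, 1]`, at least 16 x 16 (RGB arrays
#'   are averaged to gray first).
#' @param n_levels gray-level quantization for the co-occurrence matrix.
#' @return a one-row tibble with 11 feature columns.
#' @export
extract_features <- function(image, n_levels = 32) {
  if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  stopifnot(is.matrix(image))
  if (nrow(image) < 16 || ncol(image) < 16)
    stop("image must be at least 16 x 16", call. = FALSE)
  if (anyNA(image) || any(!is.finite(image)))
    stop("image must be finite", call. = FALSE)
  m <- trim_constant_border(image)

  qs <- stats::quantile(m, c(0.01, 0.5, 0.99), names = FALSE, type = 7)
  g <- glcm_stats(m, n_levels)

  gr <- 0
  if (nrow(m) > 2 && ncol(m) > 2) {
    gx <- (m[3:nrow(m), 2:(ncol(m) - 1)] - m[1:(nrow(m) - 2), 2:(ncol(m) - 1)]) / 2
    gy <- (m[2:(nrow(m) - 1), 3:ncol(m)] - m[2:(nrow(m) - 1), 1:(ncol(m) - 2)]) / 2
    gr <- mean(sqrt(gx^2 + gy^2))
  }

  fg <- 0
  if (stats::sd(m) > 0) {
    th <- EBImage::otsu(m, range = range(0, 1, m))
    fg <- mean(m > th)
  }

  tibble::tibble(
    int_mean = mean(m), int_sd = stats::sd(m),
    int_p01 = qs[1], int_p50 = qs[2], int_p99 = qs[3],
    glcm_contrast = g["contrast"], glcm_correlation = g["correlation"],
    glcm_homogeneity = g["homogeneity"], glcm_entropy = g["entropy"],
    edge_density = gr, fg_fraction = fg
  )
}

#' Feature table for a list of images
#' @param images list of numeric matrices.
#' @param ids optional image identifiers.
#' @return a tibble with an `id` column plus the [extract_features()]
#'   columns, one row per image.
#' @export
feature_table <- function(images, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(images))
  dplyr::bind_cols(
    tibble::tibble(id = ids),
    purrr::map_dfr(images, extract_features)
  )
}

# drop maximal leading/trailing rows and columns that are entirely equal
# to the corner value (an added constant frame)
trim_constant_border <- function(m) {
  v <- m[1, 1]
  row_bg <- rowSums(m != v) == 0
  col_bg <- colSums(m != v) == 0
  if (all(row_bg)) return(m)  # fully constant image: nothing to trim
  r1 <- which(!row_bg)[1]
  r2 <- utils::tail(which(!row_bg), 1)
  c1 <- which(!col_bg)[1]
  c2 <- utils::tail(which(!col_bg), 1)
  m[r1:r2, c1:c2, drop = FALSE]
}

# symmetric gray-level co-occurrence statistics, averaged over the
# right (0,1) and down (1,0) unit offsets
glcm_stats <- function(m, n_levels) {
  q <- pmin(floor(m * n_levels) + 1L, n_levels)
  one <- function(dr, dc) {
    a <- q[1:(nrow(q) - dr), 1:(ncol(q) - dc)]
    b <- q[(1 + dr):nrow(q), (1 + dc):ncol(q)]
    tab <- table(factor(a, levels = 1:n_levels), factor(b, levels = 1:n_levels))
    p <- (tab + t(tab)) / (2 * sum(tab))
    i <- matrix(1:n_levels, n_levels, n_levels)
    j <- t(i)
    mu <- sum(i * p)
    s2 <- sum((i - mu)^2 * p)
    corr <- if (s2 > 0) sum((i - mu) * (j - mu) * p) / s2 else 0
    nz <- p[p > 0]
    c(
      contrast = sum((i - j)^2 * p),
      correlation = corr,
      homogeneity = sum(p / (1 + (i - j)^2)),
      entropy = -sum(nz * log(nz))
    )
  }
  (one(0L, 1L) + one(1L, 0L)) / 2
}
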