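#' Run-length encode a binary mask (Kaggle DSB dialect)
#'
#' Encodes the pixel set of one object as `(start, length)` runs over the
#' 1-based, column-major (down-then-right) linearisation of the canvas — the
#' dialect used for Data Science Bowl 2018 submissions. Since R matrices are
#' column-major, the run index coincides with R's linear matrix index.
#'
#' @param pixels integer vector of pixel indices (1-based column-major), or a
#'   logical matrix mask.
#' @param dim canvas `c(height, width)`; required when `pixels` is a vector.
#' @return a tibble with columns `start`, `length` (0 rows for an empty mask).
#' @examples
#' rle_encode(c(1L), dim = c(4, 4))      # single pixel -> 1 1
#' rle_encode(1:4, dim = c(2, 2))        # full canvas  -> 1 4
#' @export
rle_encode <- function(pixels, dim = NULL) {
  if (is.matrix(pixels)) {
    dim <- dim(pixels)
    pixels <- which(pixels != 0)
  }
  stopifnot(!is.null(dim))
  pixels <- sort(unique(as.integer(pixels)))
  if (!length(pixels)) {
    return(tibble::tibble(start = integer(), length = integer()))
  }
  if (pixels[1] < 1L || pixels[length(pixels)] > prod(dim))
    stop("pixel indices outside the canvas", call. = FALSE)
  brk <- c(TRUE, diff(pixels) != 1L)
  starts <- pixels[brk]
  grp <- cumsum(brk)
  tibble::tibble(
    start = starts,
    length = as.integer(tabulate(grp, nbins = max(grp)))
  )
}

#' Decode a Kaggle run-length encoding to pixel indices
#'
#' @param runs a tibble/data.frame with columns `start`, `length`, or a
#'   whitespace-separated string "start length start length ...".
#' @param dim canvas `c(height, width)`.
#' @return sorted integer vector of pixel indices.
#' @export
rle_decode <- function(runs, dim) {
  if (is.character(runs)) {
    nums <- as.integer(strsplit(trimws(runs), "\\s+")[[1]])
    nums <- nums[!is.na(nums)]
    if (!length(nums)) return(integer())
    if (length(nums) %% 2L != 0L) stop("malformed RLE string", call. = FALSE)
    runs <- tibble::tibble(
      start = nums[seq(1, length(nums), by = 2)],
      length = nums[seq(2, length(nums), by = 2)]
    )
  }
  if (!nrow(runs)) return(integer())
  px <- unlist(purrr::map2(runs$start, runs$length, function(s, l) seq.int(s, s + l - 1L)))
  px <- sort(as.integer(px))
  if (anyDuplicated(px)) stop("overlapping RLE runs", call. = FALSE)
  if (px[1] < 1L || px[length(px)] > prod(dim))
    stop("RLE runs outside the canvas", call. = FALSE)
  px
}

rle_to_string <- function(runs) {
  if (!nrow(runs)) return("")
  paste(rbind(runs$start, runs$length), collapse = " ")
}

#' Read an instance set from disk
#'
#' Two formats are supported:
#' * `"label"`: a single-channel integer label image (16-bit TIFF is the
#'   canonical format; 8/16-bit PNG is also read). Each distinct non-zero
#'   label becomes one object.
#' * `"rle"`: a CSV in the Kaggle DSB submission dialect with columns
#'   `ImageId` and `EncodedPixels` (1-based, column-major runs). `shape`
#'   must be supplied; overlapping objects are preserved per record.
#'
#' @param path file path.
#' @param format `"label"` or `"rle"`.
#' @param shape canvas `c(height, width)`; required for `format = "rle"`.
#' @param image_id for RLE files holding several images: which `ImageId` to
#'   read (default: the first in file order).
#' @return an `instance_set`.
#' @export
read_instances <- function(path, format = c("label", "rle"), shape = NULL,
                           image_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "label") {
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      m <- png::readPNG(path, info = TRUE)
      depth <- attr(m, "info")$bit.depth
    } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      m <- tiff::readTIFF(path, info = TRUE)
      depth <- attr(m, "bits.per.sample")
      if (is.null(depth)) depth <- 16L
    } else {
      stop("unsupported label image format: ", path, call. = FALSE)
    }
    if (length(dim(m)) == 3L) m <- m[, , 1]
    lab <- m * (2^depth - 1)
    if (max(abs(lab - round(lab))) > 1e-3)
      stop("not an integer label image: ", path, call. = FALSE)
    as_instance_set(matrix(as.integer(round(lab)), nrow(m), ncol(m)))
  } else {
    if (is.null(shape)) stop("shape required for RLE format", call. = FALSE)
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("ImageId", "EncodedPixels") %in% names(df)))
      stop("RLE CSV must have columns ImageId, EncodedPixels", call. = FALSE)
    if (is.null(image_id)) image_id <- df$ImageId[1]
    df <- df[df$ImageId == image_id, , drop = FALSE]
    if (!nrow(df) || all(is.na(df$EncodedPixels)) ||
        all(trimws(as.character(df$EncodedPixels)) == "")) {
      return(empty_instance_set(shape))
    }
    objects <- purrr::map(as.character(df$EncodedPixels), rle_decode, dim = shape)
    keep <- lengths(objects) > 0
    instance_set(objects[keep], dim = shape)
  }
}

#' Write an instance set to disk
#'
#' For `format = "label"` the set is flattened last-object-wins and written
#' as a 16-bit single-channel TIFF (`.tif`/`.tiff`) or, for label values
#' up to 255 only, an 8-bit PNG. For `format = "rle"` every object is
#' preserved as its own CSV record (Kaggle dialect), so overlap survives a
#' round trip.
#'
#' @param s an `instance_set`.
#' @param path output path; extension selects the image writer for labels.
#' @param format `"label"` or `"rle"`.
#' @param image_id `ImageId` to write into RLE records (default `"image"`).
#' @return `path`, invisibly.
#' @export
write_instances <- function(s, path, format = c("label", "rle"),
                            image_id = "image") {
  format <- match.arg(format)
  stopifnot(inherits(s, "instance_set"))
  if (format == "label") {
    m <- as_label_matrix(s)
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      if (max(m, 0L) > 255L)
        stop("labels above 255 need 16-bit depth; write a .tif instead",
             call. = FALSE)
      png::writePNG(m / 255, path)
    } else {
      tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
    }
  } else {
    enc <- purrr::map_chr(s$objects, function(px) rle_to_string(rle_encode(px, dim = s$dim)))
    df <- tibble::tibble(ImageId = image_id, EncodedPixels = enc)
    if (!nrow(df)) df <- tibble::tibble(ImageId = image_id, EncodedPixels = "")
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a grayscale image as a numeric matrix in [0, 1]
#'
#' PNG and TIFF are supported; multi-channel images are averaged to gray.
#'
#' @param path file path.
#' @return numeric matrix (rows = image height).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  a
}

#' Write a grayscale image
#' @param m numeric matrix in `[0, 1]`.
#' @param path output path (`.png` or `.tif`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(m, path) {
  m[m < 0] <- 0; m[m > 1] <- 1
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  }
  invisible(path)
}
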