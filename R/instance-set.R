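#' Instance sets: per-object binary masks on one canvas
#'
#' An `instance_set` is the package's universal currency for segmentation
#' results: an ordered list of objects, each a set of pixels on a common
#' `height x width` canvas, with a unique positive integer label per object.
#' Objects may overlap (raw detector output can overlap); flattening to a
#' label matrix is last-object-wins.
#'
#' Pixels are stored as 1-based column-major linear indices into the canvas
#' (R's native matrix index), so index `i` addresses row
#' `(i - 1) %% height + 1`, column `(i - 1) %/% height + 1`.
#'
#' @param objects list of integer vectors, each the pixel indices of one
#'   object. All must be non-empty and within `1:(height*width)`.
#' @param dim canvas dimensions `c(height, width)` in pixels.
#' @param labels positive integer labels, one per object, unique. Defaults to
#'   `seq_along(objects)`.
#' @return An object of class `instance_set`.
#' @examples
#' m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L; m[3:4, 3:4] <- 2L
#' s <- as_instance_set(m)
#' n_objects(s)
#' @export
instance_set <- function(objects, dim, labels = seq_along(objects)) {
  stopifnot(is.list(objects), length(dim) == 2)
  dim <- as.integer(dim)
  if (any(dim < 1)) stop("canvas dimensions must be positive", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != length(objects))
    stop("one label per object required", call. = FALSE)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (length(labels) && any(labels < 1L))
    stop("labels must be positive integers", call. = FALSE)
  n <- prod(dim)
  objects <- lapply(objects, function(px) {
    px <- sort(unique(as.integer(px)))
    if (!length(px)) stop("objects must be non-empty", call. = FALSE)
    if (px[1] < 1L || px[length(px)] > n)
      stop("object pixels outside the canvas", call. = FALSE)
    px
  })
  structure(
    list(dim = dim, objects = objects, labels = labels),
    class = "instance_set"
  )
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf(
    "<instance_set> %d x %d canvas, %d object(s)\n",
    x$dim[1], x$dim[2], length(x$objects)
  ))
  if (length(x$objects)) {
    a <- object_areas(x)
    cat(sprintf(
      "  areas: min %d, median %.0f, max %d px\n",
      min(a), stats::median(a), max(a)
    ))
  }
  invisible(x)
}

#' Number of objects in an instance set
#' @param s an `instance_set`.
#' @return integer count.
#' @export
n_objects <- function(s) length(s$objects)

#' Per-object pixel areas
#' @param s an `instance_set`.
#' @return integer vector of areas, named by label.
#' @export
object_areas <- function(s) {
  stats::setNames(lengths(s$objects), s$labels)
}

#' Flatten an instance set to a label matrix
#'
#' Overlapping objects are resolved last-object-wins: objects are painted in
#' list order, later objects overwrite earlier ones. Background is 0.
#'
#' @param s an `instance_set`.
#' @return an integer matrix of dimensions `s$dim`.
#' @export
as_label_matrix <- function(s) {
  stopifnot(inherits(s, "instance_set"))
  m <- matrix(0L, s$dim[1], s$dim[2])
  for (i in seq_along(s$objects)) m[s$objects[[i]]] <- s$labels[i]
  m
}

#' Build an instance set from a label matrix
#'
#' One object per distinct non-zero label; label order is ascending.
#'
#' @param m an integer (or whole-number numeric) matrix; 0 = background.
#' @return an `instance_set`.
#' @export
as_instance_set <- function(m) {
  stopifnot(is.matrix(m))
  if (any(m != round(m))) stop("label matrix must be integer-valued", call. = FALSE)
  m <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  labs <- sort(unique(m[m > 0L]))
  objects <- split(which(m > 0L), factor(m[m > 0L], levels = labs))
  instance_set(unname(objects), dim = dim(m), labels = labs)
}

#' An empty instance set on a given canvas
#' @param dim canvas `c(height, width)`.
#' @return an `instance_set` with zero objects.
#' @export
empty_instance_set <- function(dim) {
  instance_set(list(), dim = dim, labels = integer())
}

#' Per-object binary mask as a logical matrix
#' @param s an `instance_set`.
#' @param which object position (not label).
#' @return logical matrix of the canvas dimensions.
#' @export
object_mask <- function(s, which) {
  m <- matrix(FALSE, s$dim[1], s$dim[2])
  m[s$objects[[which]]] <- TRUE
  m
}

#' Tidy view of an instance set
#'
#' @param x an `instance_set`.
#' @param ... unused.
#' @return a tibble with one row per object: `label`, `area`,
#'   `eq_diameter` (equivalent-circle diameter, `2*sqrt(area/pi)`),
#'   `row`, `col` (centroid, 1-based).
#' @export
tidy.instance_set <- function(x, ...) {
  if (!n_objects(x)) {
    return(tibble::tibble(
      label = integer(), area = integer(),
      eq_diameter = double(), row = double(), col = double()
    ))
  }
  h <- x$dim[1]
  purrr::map2_dfr(x$objects, x$labels, function(px, lb) {
    r <- (px - 1L) %% h + 1L
    cc <- (px - 1L) %/% h + 1L
    tibble::tibble(
      label = lb, area = length(px),
      eq_diameter = 2 * sqrt(length(px) / pi),
      row = mean(r), col = mean(cc)
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

validate_same_canvas <- function(a, b) {
  da <- if (inherits(a, "instance_set")) a$dim else dim(a)
  db <- if (inherits(b, "instance_set")) b$dim else dim(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop("canvas dimensions do not match", call. = FALSE)
  invisible(TRUE)
}

#' Clamp a matrix into a per-pixel probability map
#'
#' Values are clamped into `[0, 1]`; NA is not allowed.
#'
#' @param m numeric matrix.
#' @return a numeric matrix with values in `[0, 1]`, class `probability_map`.
#' @export
probability_map <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("probability map must not contain NA", call. = FALSE)
  m[m < 0] <- 0
  m[m > 1] <- 1
  class(m) <- c("probability_map", class(m))
  m
}
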