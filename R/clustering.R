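#' Automatic cluster count for style grouping
#'
#' Deliberately over-segments: one cluster per `oversegmentation` images,
#' `k = max(1, round(n / oversegmentation))`, capped at `n`. Over-splitting
#' a true style is harmless (each part still gets a matched renderer);
#' mixing two styles in one cluster is not.
#'
#' @param n_images number of images to cluster.
#' @param oversegmentation target images per cluster (default 15, which
#'   gives k = 134 on a ~2000-image set).
#' @return integer k.
#' @examples
#' choose_k(2010)  # 134
#' @export
choose_k <- function(n_images, oversegmentation = 15) {
  stopifnot(n_images >= 1, oversegmentation > 0)
  max(1L, min(as.integer(n_images), as.integer(round(n_images / oversegmentation))))
}

#' Cluster images into appearance styles
#'
#' Each image's row of the pairwise similarity matrix serves as its
#' embedding; the rows are clustered with k-means (multiple restarts,
#' seeded). Every image is assigned to exactly one cluster.
#'
#' @param features a [feature_table()] or feature matrix.
#' @param model a `similarity_model` (from [train_similarity()] or
#'   [metric_similarity()]); `NULL` fits a metric model on `features`.
#' @param k number of clusters (`<= n`); default [choose_k()] of n.
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return a `style_clustering`: list with `k`, `assignment` (integer per
#'   image), `similarity` (the n x n matrix), `inertia` (total
#'   within-cluster sum of squares) and `ids`.
#' @export
cluster_styles <- function(features, model = NULL, k = NULL, seed, nstart = 10) {
  x <- feature_matrix(features)
  n <- nrow(x)
  ids <- if (is.data.frame(features) && "id" %in% names(features)) {
    features$id
  } else {
    sprintf("image_%03d", seq_len(n))
  }
  if (is.null(model)) model <- metric_similarity(features)
  if (is.null(k)) k <- choose_k(n)
  if (k > n) stop("k must not exceed the number of images", call. = FALSE)
  s <- similarity_matrix(model, features)
  withr::local_seed(seed)
  emb <- s
  n_distinct <- nrow(unique(emb))
  k_eff <- min(k, n_distinct)
  if (k_eff == 1L) {
    assignment <- rep(1L, n)
    ctr <- matrix(colMeans(emb), 1)
    inertia <- sum(sweep(emb, 2, ctr[1, ])^2)
  } else if (k_eff == n_distinct) {
    # one cluster per distinct embedding row (k-means cannot be asked for
    # as many centres as points)
    key <- apply(emb, 1, paste, collapse = "\r")
    assignment <- as.integer(factor(key, levels = unique(key)))
    inertia <- 0
  } else {
    km <- stats::kmeans(emb, centers = k_eff, nstart = nstart, iter.max = 100)
    assignment <- as.integer(km$cluster)
    inertia <- km$tot.withinss
  }
  structure(
    list(k = k_eff, assignment = assignment, similarity = s,
         inertia = inertia, ids = ids),
    class = "style_clustering"
  )
}

#' @export
print.style_clustering <- function(x, ...) {
  cat(sprintf("<style_clustering> %d image(s) in %d cluster(s)\n",
              length(x$assignment), x$k))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Per-image cluster assignments
#' @param x a `style_clustering`.
#' @param ... unused.
#' @return a tibble with columns `id`, `cluster`.
#' @export
tidy.style_clustering <- function(x, ...) {
  tibble::tibble(id = x$ids, cluster = x$assignment)
}

#' @export
glance.style_clustering <- function(x, ...) {
  sizes <- tabulate(x$assignment, nbins = x$k)
  tibble::tibble(
    k = x$k, n_images = length(x$assignment), inertia = x$inertia,
    min_cluster_size = min(sizes), max_cluster_size = max(sizes)
  )
}

#' Drop images in under-populated style clusters
#'
#' Styles need enough member images to estimate usable statistics; images
#' whose cluster has fewer than `min_size` members are marked excluded
#' (`NA` cluster). The threshold is a package convention, configurable.
#'
#' @param clustering a `style_clustering`.
#' @param min_size minimum member count for a cluster to be kept.
#' @return the clustering with excluded assignments set to `NA`.
#' @export
filter_small_clusters <- function(clustering, min_size = 2) {
  sizes <- tabulate(clustering$assignment, nbins = clustering$k)
  small <- which(sizes < min_size)
  clustering$assignment[clustering$assignment %in% small] <- NA_integer_
  clustering
}
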