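#' Train a pairwise image-similarity model
#'
#' Learns the probability that two images come from the same imaging
#' condition, from labelled feature-vector pairs (1 = same condition,
#' 0 = different). The learner is a shallow fully connected network
#' (single hidden layer) on the absolute difference of z-scored feature
#' vectors; the absolute difference makes the model symmetric in its two
#' arguments by construction.
#'
#' @param pairs a tibble/data frame with list-columns `a` and `b` (numeric
#'   feature vectors of equal length, as rows of [feature_table()] without
#'   the id) and a column `label` in `{0, 1}`. At least 10 pairs and both
#'   labels must be present.
#' @param seed integer seed (network weights are randomly initialised).
#' @param hidden hidden-layer size.
#' @param decay weight decay.
#' @return a `similarity_model`.
#' @export
train_similarity <- function(pairs, seed, hidden = 4, decay = 0.01) {
  stopifnot(is.data.frame(pairs), all(c("a", "b", "label") %in% names(pairs)))
  if (nrow(pairs) < 10) stop("at least 10 training pairs required", call. = FALSE)
  y <- as.numeric(pairs$label)
  if (length(unique(y)) < 2)
    stop("both labels (0 and 1) must be present", call. = FALSE)
  xa <- do.call(rbind, lapply(pairs$a, as.numeric))
  xb <- do.call(rbind, lapply(pairs$b, as.numeric))
  stopifnot(ncol(xa) == ncol(xb))
  all_x <- rbind(xa, xb)
  center <- colMeans(all_x)
  scale <- apply(all_x, 2, stats::sd)
  scale[scale == 0] <- 1
  d <- abs(scale_rows(xa, center, scale) - scale_rows(xb, center, scale))
  withr::local_seed(seed)
  fit <- nnet::nnet(d, y, size = hidden, decay = decay, maxit = 500,
                    entropy = TRUE, trace = FALSE)
  acc <- mean((stats::predict(fit, d) > 0.5) == (y > 0.5))
  structure(
    list(kind = "learned", fit = fit, center = center, scale = scale,
         n_pairs = nrow(pairs), train_accuracy = acc),
    class = "similarity_model"
  )
}

#' Metric fallback similarity model
#'
#' When no labelled pairs exist, similarity falls back to a Gaussian
#' kernel on standardized Euclidean feature distance,
#' `exp(-d^2 / median(d^2))`, with the bandwidth set to the median squared
#' pairwise distance of a reference feature set.
#'
#' @param features a feature matrix or [feature_table()] (the `id` column
#'   is dropped automatically).
#' @return a `similarity_model` of kind `"metric"`.
#' @export
metric_similarity <- function(features) {
  x <- feature_matrix(features)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  z <- scale_rows(x, center, scale)
  d2 <- as.numeric(stats::dist(z))^2
  bw <- stats::median(d2[d2 > 0])
  if (!length(d2) || !is.finite(bw) || bw <= 0) bw <- 1
  structure(
    list(kind = "metric", center = center, scale = scale, bandwidth = bw,
         n_pairs = 0L, train_accuracy = NA_real_),
    class = "similarity_model"
  )
}

#' @export
print.similarity_model <- function(x, ...) {
  cat(sprintf("<similarity_model> kind: %s", x$kind))
  if (x$kind == "learned")
    cat(sprintf(", %d training pairs, train accuracy %.3f",
                x$n_pairs, x$train_accuracy))
  cat("\n")
  invisible(x)
}

#' Predict pairwise similarity
#'
#' @param model a `similarity_model`.
#' @param a,b numeric feature vectors or matrices (rows = observations).
#' @return same-condition probabilities in `[0, 1]`; symmetric in `a`, `b`.
#' @export
predict_similarity <- function(model, a, b) {
  a <- if (is.null(dim(a))) matrix(as.numeric(a), 1) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(as.numeric(b), 1) else as.matrix(b)
  za <- scale_rows(a, model$center, model$scale)
  zb <- scale_rows(b, model$center, model$scale)
  if (model$kind == "learned") {
    p <- as.numeric(stats::predict(model$fit, abs(za - zb)))
    pmin(pmax(p, 0), 1)
  } else {
    exp(-rowSums((za - zb)^2) / model$bandwidth)
  }
}

#' Similarity matrix of a feature set
#'
#' @param model a `similarity_model`.
#' @param features feature matrix or [feature_table()].
#' @return an `n x n` symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
similarity_matrix <- function(model, features) {
  x <- feature_matrix(features)
  n <- nrow(x)
  s <- diag(1, n)
  if (n > 1) {
    idx <- utils::combn(n, 2)
    v <- predict_similarity(model, x[idx[1, ], , drop = FALSE],
                            x[idx[2, ], , drop = FALSE])
    s[cbind(idx[1, ], idx[2, ])] <- v
    s[cbind(idx[2, ], idx[1, ])] <- v
  }
  s
}

#' @export
glance.similarity_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_pairs = x$n_pairs,
                 train_accuracy = x$train_accuracy)
}

#' Build labelled feature pairs from known conditions
#'
#' Convenience generator of training input for [train_similarity()]: draws
#' random same-condition (label 1) and different-condition (label 0) pairs
#' from a feature table with known group membership.
#'
#' @param features a [feature_table()] or feature matrix.
#' @param groups condition identifier per image.
#' @param n_pairs number of pairs to draw (split evenly between labels).
#' @param seed integer seed.
#' @return a tibble with list-columns `a`, `b` and a `label` column.
#' @export
make_training_pairs <- function(features, groups, n_pairs = 100, seed) {
  x <- feature_matrix(features)
  stopifnot(nrow(x) == length(groups))
  withr::local_seed(seed)
  same <- which(outer(groups, groups, "==") & upper.tri(diag(length(groups))))
  diff <- which(outer(groups, groups, "!=") & upper.tri(diag(length(groups))))
  if (!length(same) || !length(diff))
    stop("need at least two groups with two members each", call. = FALSE)
  n1 <- ceiling(n_pairs / 2)
  n0 <- n_pairs - n1
  pick <- c(sample(same, n1, replace = length(same) < n1),
            sample(diff, n0, replace = length(diff) < n0))
  lab <- c(rep(1, n1), rep(0, n0))
  n <- length(groups)
  i <- (pick - 1L) %% n + 1L
  j <- (pick - 1L) %/% n + 1L
  tibble::tibble(
    a = lapply(i, function(r) x[r, ]),
    b = lapply(j, function(r) x[r, ]),
    label = lab
  )
}

scale_rows <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  df <- as.data.frame(features)
  df <- df[vapply(df, is.numeric, logical(1))]
  as.matrix(df)
}
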