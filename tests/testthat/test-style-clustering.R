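toy_styles <- function(n_per_style, seed) {
  bright <- make_toy_dataset(n_per_style, seed = seed, fg = 0.8, bg = 0.15)
  dark <- make_toy_dataset(n_per_style, seed = seed + 1, fg = 0.2, bg = 0.85)
  list(images = c(bright$image, dark$image),
       style = rep(1:2, each = n_per_style))
}

test_that("features: degenerate and symmetric inputs", {
  flat <- extract_features(matrix(0.3, 32, 32))
  expect_equal(flat$int_sd, 0)
  expect_equal(flat$glcm_entropy, 0, ignore_attr = TRUE)
  expect_equal(flat$glcm_contrast, 0, ignore_attr = TRUE)
  expect_true(all(is.finite(as.numeric(flat))))

  # 90-degree rotation leaves the offset-averaged texture terms unchanged
  d <- make_toy_dataset(1, seed = 21)
  img <- d$image[[1]]
  rot <- t(img)[, rev(seq_len(nrow(img)))]
  f1 <- extract_features(img)
  f2 <- extract_features(rot)
  for (col in c("glcm_contrast", "glcm_correlation", "glcm_homogeneity",
                "glcm_entropy", "int_mean", "int_sd", "edge_density")) {
    expect_equal(f1[[col]], f2[[col]], tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("features are invariant to a constant background border", {
  d <- make_toy_dataset(1, seed = 22, noise_sd = 0.03)
  img <- d$image[[1]]
  border_val <- img[1, 1] * 0 + 0.5  # any constant
  padded <- matrix(0.5, nrow(img) + 20, ncol(img) + 20)
  padded[11:(10 + nrow(img)), 11:(10 + ncol(img))] <- img
  expect_equal(extract_features(img), extract_features(padded),
               tolerance = 1e-12)
})

test_that("feature distance separates planted styles", {
  st <- toy_styles(5, seed = 23)
  ft <- feature_matrix <- as.matrix(feature_table(st$images)[-1])
  z <- scale(ft)
  z[, apply(ft, 2, sd) == 0] <- 0
  dmat <- as.matrix(dist(z))
  within <- dmat[st$style[row(dmat)] == st$style[col(dmat)] & row(dmat) < col(dmat)]
  between <- dmat[st$style[row(dmat)] != st$style[col(dmat)]]
  expect_gt(mean(between), mean(within))
})

test_that("similarity learning separates styles and respects symmetry", {
  st <- toy_styles(10, seed = 24)
  ft <- feature_table(st$images)
  # train on half the images, evaluate pairs drawn from the other half
  train_idx <- c(1:5, 11:15)
  test_idx <- setdiff(seq_along(st$images), train_idx)
  pairs <- make_training_pairs(ft[train_idx, ], st$style[train_idx],
                               n_pairs = 80, seed = 3)
  model <- train_similarity(pairs, seed = 4)

  held <- make_training_pairs(ft[test_idx, ], st$style[test_idx],
                              n_pairs = 60, seed = 5)
  p <- purrr::map2_dbl(held$a, held$b, ~ predict_similarity(model, .x, .y))
  acc <- mean((p > 0.5) == (held$label > 0.5))
  expect_gte(acc, 0.9)

  # symmetry by construction
  fa <- as.numeric(ft[2, -1]); fb <- as.numeric(ft[12, -1])
  expect_equal(predict_similarity(model, fa, fb),
               predict_similarity(model, fb, fa), tolerance = 1e-9)

  # determinism given the seed
  model2 <- train_similarity(pairs, seed = 4)
  expect_equal(predict_similarity(model2, fa, fb),
               predict_similarity(model, fa, fb), tolerance = 1e-12)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  st <- toy_styles(10, seed = 25)
  ft <- feature_table(st$images)
  pairs <- make_training_pairs(ft, st$style, n_pairs = 100, seed = 6)
  set.seed(7)
  train <- sample(nrow(pairs), 60)
  shuffled <- pairs[train, ]
  shuffled$label <- sample(shuffled$label)
  model <- train_similarity(shuffled, seed = 8)
  held <- pairs[-train, ]
  p <- purrr::map2_dbl(held$a, held$b, ~ predict_similarity(model, .x, .y))
  acc <- mean((p > 0.5) == (held$label > 0.5))
  expect_true(abs(acc - 0.5) <= 0.2)
})

test_that("training input is validated", {
  st <- toy_styles(4, seed = 26)
  ft <- feature_table(st$images)
  pairs <- make_training_pairs(ft, st$style, n_pairs = 20, seed = 9)
  expect_error(train_similarity(pairs[1:5, ], seed = 1), "10")
  one_class <- pairs[pairs$label == 1, ]
  expect_error(train_similarity(one_class, seed = 1), "both labels")
})

test_that("automatic k over-segments at one cluster per 15 images", {
  expect_equal(choose_k(2010), 134L)
  expect_equal(choose_k(1), 1L)
  expect_equal(choose_k(10), 1L)
  expect_equal(choose_k(45), 3L)
})

test_that("similarity matrix is symmetric with unit diagonal", {
  st <- toy_styles(5, seed = 27)
  ft <- feature_table(st$images)
  s <- similarity_matrix(metric_similarity(ft), ft)
  expect_equal(s, t(s), tolerance = 1e-9)
  expect_equal(diag(s), rep(1, nrow(s)), tolerance = 1e-9)
  expect_true(all(s >= 0 & s <= 1 + 1e-12))
})

test_that("clustering edge cases: k = n and identical features", {
  st <- toy_styles(3, seed = 28)
  ft <- feature_table(st$images)
  sc <- cluster_styles(ft, k = 6, seed = 10)
  expect_equal(sort(unique(sc$assignment)), 1:6)  # every image its own cluster

  same <- matrix(1, 5, 4)
  sc1 <- cluster_styles(same, model = metric_similarity(same), k = 1, seed = 11)
  expect_equal(sc1$k, 1)
  expect_equal(sc1$inertia, 0)
  expect_error(cluster_styles(ft, k = 99, seed = 1), "exceed")
})

test_that("clustering recovers planted style structure", {
  st <- toy_styles(10, seed = 29)
  ft <- feature_table(st$images)
  sc <- cluster_styles(ft, k = 2, seed = 12)
  ari <- mclust::adjustedRandIndex(sc$assignment, st$style)
  expect_gte(ari, 0.9)
  # deterministic given the seed
  sc2 <- cluster_styles(ft, k = 2, seed = 12)
  expect_identical(sc$assignment, sc2$assignment)
})

test_that("small clusters can be filtered out", {
  st <- toy_styles(5, seed = 30)
  ft <- feature_table(st$images)
  sc <- cluster_styles(ft, k = 5, seed = 13)
  f <- filter_small_clusters(sc, min_size = 3)
  sizes <- table(f$assignment)
  expect_true(all(sizes >= 3))
})
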