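test_that("iou matches hand-counted pixel arithmetic", {
  dim <- c(20, 20)
  a <- square_mask(dim, 5, 5, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, square_mask(dim, 5, 16, 4)), 0)
  # 10x10 square against the same square shifted 2 columns:
  # intersection 10x8 = 80, union 200 - 80 = 120
  b <- square_mask(dim, 5, 7, 10)
  expect_equal(iou(a, b), 80 / 120)
  expect_equal(iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 0)
  expect_error(iou(a, matrix(FALSE, 4, 4)), "dimensions")
})

test_that("matching: perfect prediction and empty prediction", {
  d <- make_toy_dataset(1, objects_per_image = c(6, 6), seed = 2)
  s <- d$instances[[1]]
  mt <- match_objects(s, s)
  expect_true(all(mt$tp == 6))
  expect_true(all(mt$fp == 0) && all(mt$fn == 0))

  mt0 <- match_objects(empty_instance_set(s$dim), s)
  expect_true(all(mt0$tp == 0) && all(mt0$fp == 0) && all(mt0$fn == 6))
})

test_that("greedy matching equals exhaustive max-TP search on small cases", {
  for (seed in 1:40) {
    case <- random_match_case(seed)
    mt <- match_objects(case$pred, case$gt)
    im <- oracle_iou_matrix(case$pred, case$gt)
    for (k in seq_along(mt$threshold)) {
      expect_equal(mt$tp[k], oracle_max_tp(im, mt$threshold[k]),
                   info = sprintf("seed %d, t = %.2f", seed, mt$threshold[k]))
    }
  }
})

test_that("the hit rule is strictly greater-than", {
  dim <- c(10, 10)
  a <- square_mask(dim, 1, 1, 5)        # 25 px
  b <- a; b[1, 1] <- FALSE              # wait: build IoU exactly 0.5
  # 2x5 strip vs 2x5 strip shifted: make IoU exactly 0.5 via half overlap
  g <- square_mask(dim, 1, 1, 4)        # 16 px
  p <- matrix(FALSE, 10, 10); p[1:4, 3:6] <- TRUE  # overlap 4x2 = 8; union 24
  expect_equal(iou(g, p), 8 / 24)
  # exact threshold case: identical masks have IoU 1 > every t;
  # an IoU exactly at a threshold must not count
  half <- square_mask(dim, 1, 1, 2)     # 4 px inside an 8 px strip
  strip <- matrix(FALSE, 10, 10); strip[1:2, 1:4] <- TRUE
  expect_equal(iou(half, strip), 0.5)
  mt <- match_objects(mask_to_set(half), mask_to_set(strip), thresholds = 0.5)
  expect_equal(mt$tp, 0L)  # 0.5 is not > 0.5
})

test_that("DSB score reproduces the worked examples", {
  d <- make_toy_dataset(1, objects_per_image = c(4, 4), seed = 3)
  s <- d$instances[[1]]
  expect_true(abs(dsb_score(s, s) - 1) < 1e-39)

  # single gt/pred pair at IoU 2/3: hits at t in {0.50, 0.55, 0.60, 0.65}
  dim <- c(20, 20)
  gt <- mask_to_set(square_mask(dim, 5, 5, 10))
  pred <- mask_to_set(square_mask(dim, 5, 7, 10))
  expect_equal(dsb_score(pred, gt), 4 / 10, tolerance = 1e-12)

  expect_equal(dsb_score(empty_instance_set(dim), gt), 0)
  # both empty: perfect prediction scores 1 by convention
  expect_equal(dsb_score(empty_instance_set(dim), empty_instance_set(dim)), 1)
})

test_that("precision/recall/F1 match hand enumeration", {
  d <- make_toy_dataset(1, objects_per_image = c(5, 5), seed = 4)
  s <- d$instances[[1]]
  sc <- score_instances(s, s)
  expect_equal(c(sc$map, sc$mar, sc$mf1), c(1, 1, 1))

  # 1 gt (10x10), 2 preds: one a 90-px subset (IoU 0.9), one disjoint.
  # hits at the 8 thresholds below 0.9: precision 1/2, recall 1, F1 2/3
  dim <- c(30, 30)
  gt_m <- square_mask(dim, 3, 3, 10)
  p1 <- gt_m; p1[12, 3:12] <- FALSE     # drop the last row: 90 px
  expect_equal(sum(p1), 90)
  p2 <- square_mask(dim, 20, 20, 5)
  sc2 <- score_instances(mask_to_set(p1, p2), mask_to_set(gt_m))
  expect_equal(sc2$map, 8 / 10 * (1 / 2), tolerance = 1e-9)
  expect_equal(sc2$mar, 8 / 10, tolerance = 1e-9)
  expect_equal(sc2$mf1, 8 / 10 * (2 / 3), tolerance = 1e-9)

  # empty vs empty keeps the raw epsilon formula: all zero
  e <- empty_instance_set(dim)
  sc3 <- score_instances(e, e)
  expect_equal(c(sc3$map, sc3$mar, sc3$mf1), c(0, 0, 0))
  expect_equal(sc3$dsb, 1)  # the DSB convention
})

test_that("scores are invariant to relabeling and object order", {
  case <- random_match_case(99)
  pred <- case$pred
  perm <- sample(seq_len(n_objects(pred)))
  shuffled <- instance_set(pred$objects[perm], dim = pred$dim,
                           labels = 100L + seq_along(perm))
  expect_equal(dsb_score(shuffled, case$gt), dsb_score(pred, case$gt))
  expect_equal(score_instances(shuffled, case$gt)[c("map", "mar", "mf1")],
               score_instances(pred, case$gt)[c("map", "mar", "mf1")])
})

test_that("per-threshold TP is non-increasing in the threshold", {
  for (seed in c(7, 17, 27)) {
    case <- random_match_case(seed)
    mt <- match_objects(case$pred, case$gt)
    expect_true(all(diff(mt$tp) <= 0))
  }
})

test_that("set-level report averages per-image scores", {
  d <- make_toy_dataset(2, objects_per_image = c(4, 4), seed = 6)
  rep <- score_set(d$instances, d$instances, ids = d$id)
  g <- glance(rep)
  expect_equal(g$dsb, 1, tolerance = 1e-30)
  expect_equal(g$n_images, 2)
  # one perfect, one empty prediction: set mean is the mean of 1 and 0
  rep2 <- score_set(list(d$instances[[1]], empty_instance_set(c(128, 128))),
                    d$instances)
  expect_equal(glance(rep2)$dsb, 0.5, tolerance = 1e-12)
})

test_that("error taxonomy: clean, split, merge and missed cases", {
  d <- make_toy_dataset(1, objects_per_image = c(5, 5), seed = 8)
  s <- d$instances[[1]]
  expect_equal(unlist(error_taxonomy(s, s)), c(missed = 0, false_detected = 0,
                                               split = 0, merged = 0))

  # 100-px gt covered 50 px each by two predictions -> one split
  dim <- c(30, 30)
  gt_m <- square_mask(dim, 3, 3, 10)
  top <- gt_m; top[8:12, ] <- FALSE      # rows 3-7: 50 px
  bottom <- gt_m; bottom[3:7, ] <- FALSE # rows 8-12: 50 px
  et <- error_taxonomy(mask_to_set(top, bottom), mask_to_set(gt_m))
  expect_equal(et$split, 1L)
  expect_equal(et$missed, 0L)

  # one prediction exactly covering two gt objects -> one merge
  g1 <- square_mask(dim, 3, 3, 8)
  g2 <- square_mask(dim, 3, 12, 8)
  u <- g1 | g2
  et2 <- error_taxonomy(mask_to_set(u), mask_to_set(g1, g2))
  expect_equal(et2$merged, 1L)
  expect_equal(et2$false_detected, 0L)
  # the merged gt objects have a corresponding (merging) prediction,
  # so they are not additionally counted as missed
  expect_equal(et2$missed, 0L)

  # a gt with no overlapping prediction at all is missed; a prediction with
  # no gt is falsely detected
  et3 <- error_taxonomy(mask_to_set(square_mask(dim, 20, 20, 5)),
                        mask_to_set(square_mask(dim, 3, 3, 5)))
  expect_equal(et3$missed, 1L)
  expect_equal(et3$false_detected, 1L)
})

test_that("mask BCE loss: closed forms and the double-loop oracle", {
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_lt(mask_bce_loss(y, y), 1e-6)
  expect_equal(mask_bce_loss(matrix(0.5, 8, 8), y), log(2), tolerance = 1e-9)
  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(runif(64), 8, 8)
    yy <- matrix(rbinom(64, 1, 0.5), 8, 8)
    expect_equal(mask_bce_loss(p, yy), oracle_bce(p, yy), tolerance = 1e-12)
    expect_gte(mask_bce_loss(p, yy), 0)
  }
  expect_error(mask_bce_loss(matrix(0.5, 4, 4), matrix(0, 5, 5)), "dimensions")
  expect_error(mask_bce_loss(matrix(2, 4, 4), matrix(0, 4, 4)), "0, 1")
})

test_that("classification accuracy is correct / total", {
  expect_equal(classification_accuracy(rep(1, 10), rep(1, 10)), 1)
  expect_equal(classification_accuracy(rep(0, 10), rep(1, 10)), 0)
  set.seed(1)
  truth <- rbinom(64, 1, 0.5)
  calls <- truth
  flip <- sample(64, 28)  # 36 of 64 correct
  calls[flip] <- 1 - calls[flip]
  expect_equal(classification_accuracy(calls, truth), 36 / 64)
  expect_error(classification_accuracy(integer(), integer()), "non-empty")
})
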