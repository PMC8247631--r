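test_that("contained objects are removed, disjoint ones kept, idempotently", {
  d <- make_toy_dataset(1, objects_per_image = c(5, 5), seed = 61)
  s <- d$instances[[1]]
  expect_identical(remove_contained(s), s)

  dim <- c(20, 20)
  big <- square_mask(dim, 3, 3, 10)
  small <- square_mask(dim, 5, 5, 3)   # strictly inside big
  s2 <- mask_to_set(big, small)
  out <- remove_contained(s2)
  expect_equal(n_objects(out), 1)
  expect_equal(out$labels, 1L)
  expect_identical(remove_contained(out), out)  # idempotent

  # equal-size identical twins both survive (neither is larger)
  s3 <- mask_to_set(big, big)
  expect_equal(n_objects(remove_contained(s3)), 2)
})

test_that("surrounded objects merge into their surrounder", {
  d <- make_toy_dataset(1, objects_per_image = c(5, 5), seed = 62)
  s <- d$instances[[1]]
  expect_identical(merge_surrounded(s, 0.17), s)  # isolated objects

  # a 4x4 block with a ring-like neighbour covering most of its boundary
  dim <- c(20, 20)
  inner <- square_mask(dim, 8, 8, 4)
  ring <- square_mask(dim, 6, 6, 8) & !square_mask(dim, 8, 8, 4)
  s2 <- mask_to_set(ring, inner)
  out <- merge_surrounded(s2, 0.17)
  expect_equal(n_objects(out), 1)
  expect_equal(out$labels, 1L)  # keeps the absorbing object's label
  expect_setequal(out$objects[[1]], sort(c(which(ring), which(inner))))

  # p1 = 1 merges nothing (a boundary fraction cannot exceed 1)
  expect_equal(n_objects(merge_surrounded(s2, 1)), 2)

  # two adjacent squares: the small square has 3 of its 9 boundary pixels
  # against the big one (1/3) -> merges at p1 = 0.17, not at p1 = 0.5;
  # the most-surrounded object is absorbed, so the big square's label stays
  a <- square_mask(dim, 5, 5, 6)
  b <- square_mask(dim, 5, 11, 3)
  sab <- mask_to_set(a, b)
  m17 <- merge_surrounded(sab, 0.17)
  expect_equal(n_objects(m17), 1)
  expect_equal(m17$labels, 1L)
  expect_equal(n_objects(merge_surrounded(sab, 0.5)), 2)
})

test_that("small-object removal is strict", {
  dim <- c(40, 40)
  objs <- mask_to_set(
    square_mask(dim, 1, 1, 3),     # 9 px -> rounded to 10-ish? no: 9
    square_mask(dim, 10, 10, 7),   # 49 px
    square_mask(dim, 20, 20, 10)   # 100 px
  )
  expect_identical(remove_small(objs, 0), objs)
  out <- remove_small(objs, 49)    # strictly smaller than 49 removed
  expect_equal(sort(lengths(out$objects)), c(49L, 100L))
  expect_equal(n_objects(remove_small(objs, 1e9)), 0)
  expect_identical(remove_small(out, 49), out)  # idempotent
})

test_that("probability-guided correction follows the morphology oracles", {
  d <- make_toy_dataset(1, objects_per_image = c(6, 6), seed = 63)
  s <- d$instances[[1]]

  # empty band is the identity
  expect_identical(unet_correct(s, matrix(0.5, 128, 128), 0.9, 0, 0), s)

  # probability 1 everywhere: every object dilated by one (box element);
  # fixtures are >2 px apart so there are no conflicts
  allone <- matrix(1, 128, 128)
  dil <- unet_correct(s, allone, 0.5, 1, 1)
  for (i in seq_len(n_objects(s))) {
    expect_identical(object_mask(dil, i), oracle_dilate1(object_mask(s, i)))
  }

  # probability 0 everywhere: every object eroded by one
  allzero <- matrix(0, 128, 128)
  ero <- unet_correct(s, allzero, 0.5, 1, 1)
  kept <- match(ero$labels, s$labels)
  for (j in seq_len(n_objects(ero))) {
    expect_identical(object_mask(ero, j),
                     oracle_erode1(object_mask(s, kept[j])))
  }

  # disputed band pixels go to the nearest original object
  dim <- c(20, 20)
  a <- square_mask(dim, 5, 3, 4)    # cols 3-6
  b <- square_mask(dim, 5, 9, 4)    # cols 9-12, gap at cols 7-8
  s2 <- mask_to_set(a, b)
  out <- unet_correct(s2, matrix(1, 20, 20), 0.5, 0, 1)
  pa <- out$objects[[1]]; pb <- out$objects[[2]]
  expect_equal(length(intersect(pa, pb)), 0)
  cols_a <- (pa - 1) %/% 20 + 1
  cols_b <- (pb - 1) %/% 20 + 1
  expect_true(max(cols_a) <= 7)  # a expands into col 7 (nearer a)
  expect_true(min(cols_b) >= 8)  # b expands into col 8 (nearer b)

  expect_error(unet_correct(s, matrix(1, 4, 4), 0.5, 1, 1), "dimensions")
})

test_that("low-confidence objects are removed by the mean-probability floor", {
  dim <- c(30, 30)
  a <- square_mask(dim, 2, 2, 5)
  b <- square_mask(dim, 20, 20, 5)
  s <- mask_to_set(a, b)
  prob <- matrix(0.5, 30, 30)
  prob[b] <- 0.95
  expect_identical(remove_low_confidence(s, prob, 0), s)
  out <- remove_low_confidence(s, prob, 0.8)
  expect_equal(out$labels, 2L)  # the 0.5-confidence object is gone

  # strictness of "<": mean exactly at the floor survives
  prob2 <- matrix(0, 30, 30)
  prob2[a] <- 0.8
  expect_equal(n_objects(remove_low_confidence(mask_to_set(a), prob2, 0.8)), 1)
})

test_that("the full chain cleans planted debris and respects stage switches", {
  triples <- debris_tuning_fixture(1, seed = 64)
  tr <- triples[[1]]
  expect_gt(n_objects(tr$pred), n_objects(tr$gt))

  out <- postprocess_chain(tr$pred, tr$prob,
                           postprocess_params(p2 = 50, p3 = 0.5, p6 = 0.2))
  expect_equal(n_objects(out), n_objects(tr$gt))  # debris (< 50 px) removed
  expect_gt(dsb_score(out, tr$gt), dsb_score(tr$pred, tr$gt))

  # stage bypass: with every stage off the chain is the identity
  expect_identical(postprocess_chain(tr$pred, tr$prob, stages = character()),
                   tr$pred)

  # all-background probability with a confidence floor empties the set
  zero <- matrix(0, 128, 128)
  expect_equal(n_objects(postprocess_chain(tr$pred, zero,
                                           postprocess_params(p6 = 0.8))), 0)
})

test_that("correction against the rasterized truth never hurts the score", {
  d <- make_toy_dataset(2, objects_per_image = c(6, 6), seed = 65)
  for (i in 1:2) {
    gt <- d$instances[[i]]
    prob <- (as_label_matrix(gt) > 0) * 1
    # nudge the prediction: erode every object by one, then let the
    # correction pull the contour back out
    pred <- unet_correct(gt, matrix(0, 128, 128), 0.5, 1, 1)
    before <- dsb_score(pred, gt)
    after <- dsb_score(unet_correct(pred, prob, 0.5, 1, 1), gt)
    expect_gte(after, before - 0.01)
  }
})

test_that("chain stages always output valid instance sets", {
  triples <- debris_tuning_fixture(1, seed = 66)
  tr <- triples[[1]]
  stages <- list(
    remove_contained(tr$pred),
    merge_surrounded(tr$pred, 0.17),
    remove_small(tr$pred, 44),
    unet_correct(tr$pred, tr$prob, 0.9375, 1, 1),
    remove_low_confidence(tr$pred, tr$prob, 0.8)
  )
  for (s in stages) {
    expect_s3_class(s, "instance_set")
    expect_lte(n_objects(s), n_objects(tr$pred))  # never adds objects
    if (n_objects(s)) {
      expect_true(all(lengths(s$objects) > 0))
      expect_false(anyDuplicated(s$labels) > 0)
    }
  }
})

test_that("GA smoke: degenerate settings are deterministic and sane", {
  triples <- debris_tuning_fixture(1, seed = 67)
  f1 <- optimize_params(triples, population = 1, generations = 0, seed = 5)
  f2 <- optimize_params(triples, population = 1, generations = 0, seed = 5)
  expect_identical(f1$params, f2$params)
  # population of one, zero generations: the single (default) member wins
  expect_equal(f1$fitness, f1$default_fitness)

  f3 <- optimize_params(triples, population = 6, generations = 2, seed = 6)
  expect_gte(f3$fitness, f3$default_fitness - 1e-9)   # elitism over defaults
  expect_true(all(diff(f3$history$best) >= -1e-12))   # monotone best fitness
})
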