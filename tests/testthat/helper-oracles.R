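# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: set arithmetic on logical matrices, explicit
# double loops, and exhaustive search.

# mask helpers ---------------------------------------------------------------

square_mask <- function(dim, r0, c0, side) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- TRUE
  m
}

mask_to_set <- function(...) {
  masks <- list(...)
  dm <- dim(masks[[1]])
  instance_set(lapply(masks, which), dim = dm)
}

# Jaccard on logical matrices, straight from the definition
oracle_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# exhaustive maximum-TP one-to-one matching at threshold t (strict >)
oracle_max_tp <- function(iou_mat, t) {
  n_gt <- nrow(iou_mat)
  n_pr <- ncol(iou_mat)
  if (n_gt == 0 || n_pr == 0) return(0L)
  rec <- function(g, used) {
    if (g > n_gt) return(0L)
    best <- rec(g + 1L, used)
    for (p in seq_len(n_pr)) {
      if (!used[p] && iou_mat[g, p] > t) {
        used[p] <- TRUE
        best <- max(best, 1L + rec(g + 1L, used))
        used[p] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(n_pr))
}

oracle_iou_matrix <- function(pred, gt) {
  n_g <- n_objects(gt)
  n_p <- n_objects(pred)
  out <- matrix(0, n_g, n_p)
  for (g in seq_len(n_g)) {
    for (p in seq_len(n_p)) {
      out[g, p] <- oracle_iou(object_mask(gt, g), object_mask(pred, p))
    }
  }
  out
}

# double-loop binary cross-entropy, the naive transcription
oracle_bce <- function(p, y, clip = 1e-12) {
  tot <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      pij <- min(max(p[i, j], clip), 1 - clip)
      tot <- tot + y[i, j] * log(pij) + (1 - y[i, j]) * log(1 - pij)
    }
  }
  -tot / (nrow(p) * ncol(p))
}

# Chebyshev (8-connectivity, box element) dilation/erosion by shifting
shift_or_na <- function(m, dr, dc, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
  out
}

oracle_dilate1 <- function(m) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out | shift_or_na(m, dr, dc, FALSE)
  out
}

oracle_erode1 <- function(m) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out & shift_or_na(m, dr, dc, FALSE)
  out
}

# random small instance sets for matcher stress tests: jittered copies of
# ground-truth rectangles plus occasional spurious boxes, giving IoU values
# that straddle the threshold grid
random_match_case <- function(seed, dim = c(32, 32), max_obj = 5) {
  set.seed(seed)
  n_gt <- sample.int(max_obj, 1)
  gt_masks <- list()
  for (i in seq_len(n_gt)) {
    side <- sample(3:8, 1)
    r0 <- sample.int(dim[1] - side, 1)
    c0 <- sample.int(dim[2] - side, 1)
    gt_masks[[i]] <- square_mask(dim, r0, c0, side)
  }
  pr_masks <- list()
  for (i in seq_len(n_gt)) {
    if (runif(1) < 0.85) {  # jittered copy
      sh <- sample(-3:3, 2, replace = TRUE)
      pr_masks[[length(pr_masks) + 1]] <- shift_or_na(gt_masks[[i]], sh[1], sh[2], FALSE)
    }
  }
  while (length(pr_masks) < max_obj && runif(1) < 0.3) {
    side <- sample(3:8, 1)
    r0 <- sample.int(dim[1] - side, 1)
    c0 <- sample.int(dim[2] - side, 1)
    pr_masks[[length(pr_masks) + 1]] <- square_mask(dim, r0, c0, side)
  }
  pr_masks <- Filter(function(m) any(m), pr_masks)
  gt <- instance_set(lapply(gt_masks, which), dim = dim)
  pred <- if (length(pr_masks)) {
    instance_set(lapply(pr_masks, which), dim = dim)
  } else {
    empty_instance_set(dim)
  }
  list(pred = pred, gt = gt)
}

# GA tuning fixture: near-perfect predictions polluted with sub-50 px
# debris; the probability map covers the debris too, so only the area rule
# can remove it
debris_tuning_fixture <- function(n_images, seed) {
  data <- make_toy_dataset(n_images, objects_per_image = c(8, 10),
                           diameter = c(10, 12), canvas = c(128, 128),
                           seed = seed)
  lapply(seq_len(n_images), function(i) {
    gt <- data$instances[[i]]
    set.seed(seed + 100 + i)
    lab <- as_label_matrix(gt)
    debris <- list()
    tries <- 0
    while (length(debris) < 4 && tries < 500) {
      tries <- tries + 1
      d <- runif(1, 5.2, 7.6)  # areas roughly 20-48 px
      patch <- simulate_shape(d, irregularity = 0.1)
      r0 <- sample.int(128 - nrow(patch), 1)
      c0 <- sample.int(128 - ncol(patch), 1)
      px <- which(patch)
      rows <- r0 + (px - 1L) %% nrow(patch)
      cols <- c0 + (px - 1L) %/% nrow(patch)
      lin <- rows + (cols - 1L) * 128L
      if (all(lab[lin] == 0)) {
        debris[[length(debris) + 1]] <- lin
        lab[lin] <- 99L
      }
    }
    pred <- instance_set(c(gt$objects, debris), dim = gt$dim)
    prob_src <- (as_label_matrix(pred) > 0) * 1
    prob <- probability_map(as.matrix(EBImage::gblur(prob_src, sigma = 0.8)))
    list(pred = pred, prob = prob, gt = gt)
  })
}
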