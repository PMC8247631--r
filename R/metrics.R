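#' Intersection over union of two binary masks
#'
#' The Jaccard index `|a and b| / (|a| + |b| - |a and b|)`, the matching
#' criterion for object hits. When both masks are empty the IoU is defined
#' as 0.
#'
#' @param a,b logical/binary matrices on the same canvas, or integer pixel
#'   index vectors (then `dim` is ignored for bounds and only equality of
#'   interpretation is assumed).
#' @return a real in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 10, 10); a[3:6, 3:6] <- TRUE
#' iou(a, a)
#' @export
iou <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    stopifnot(is.matrix(a), is.matrix(b))
    validate_same_canvas(a, b)
    a <- which(a != 0)
    b <- which(b != 0)
  }
  inter <- length(intersect(a, b))
  uni <- length(a) + length(b) - inter
  if (uni == 0) return(0)
  inter / uni
}

# IoU for every overlapping (gt, pred) object pair; positions, not labels
pairwise_iou <- function(pred, gt) {
  if (!n_objects(pred) || !n_objects(gt)) {
    return(tibble::tibble(gt = integer(), pred = integer(),
                          intersection = integer(), iou = double()))
  }
  gt_df <- tibble::tibble(
    px = unlist(gt$objects),
    gt = rep.int(seq_along(gt$objects), lengths(gt$objects))
  )
  pr_df <- tibble::tibble(
    px = unlist(pred$objects),
    pred = rep.int(seq_along(pred$objects), lengths(pred$objects))
  )
  ov <- dplyr::inner_join(gt_df, pr_df, by = "px",
                          relationship = "many-to-many")
  if (!nrow(ov)) {
    return(tibble::tibble(gt = integer(), pred = integer(),
                          intersection = integer(), iou = double()))
  }
  ga <- lengths(gt$objects)
  pa <- lengths(pred$objects)
  ov |>
    dplyr::count(.data$gt, .data$pred, name = "intersection") |>
    dplyr::mutate(iou = .data$intersection /
                    (ga[.data$gt] + pa[.data$pred] - .data$intersection))
}

#' Match predicted to ground-truth objects over IoU thresholds
#'
#' Builds a one-to-one pairing by greedy selection in order of descending
#' IoU (ties broken by ground-truth label, then predicted label). For
#' thresholds at or above 0.5 a pair with IoU above the threshold is unique
#' per object, so the greedy pairing attains the maximum possible number of
#' true positives. A pair counts as a hit at threshold `t` iff its IoU is
#' strictly greater than `t`; unmatched ground-truth objects are false
#' negatives and unmatched predictions false positives.
#'
#' @param pred,gt [instance_set()]s on the same canvas.
#' @param thresholds IoU thresholds (default 0.5 to 0.95 in steps of 0.05).
#' @return a `match_table`: a tibble with columns `threshold`, `tp`, `fp`,
#'   `fn`, carrying the matched pairs (columns `gt`, `pred` as labels, `iou`)
#'   in attribute `"pairs"`.
#' @export
match_objects <- function(pred, gt, thresholds = dsb_thresholds()) {
  stopifnot(inherits(pred, "instance_set"), inherits(gt, "instance_set"))
  validate_same_canvas(pred, gt)
  pairs <- greedy_match(pred, gt)
  n_gt <- n_objects(gt)
  n_pred <- n_objects(pred)
  tab <- tibble::tibble(
    threshold = thresholds,
    tp = purrr::map_int(thresholds, ~ sum(pairs$iou > .x)),
  ) |>
    dplyr::mutate(fp = n_pred - .data$tp, fn = n_gt - .data$tp)
  attr(tab, "pairs") <- pairs
  class(tab) <- c("match_table", class(tab))
  tab
}

# greedy one-to-one pairing by descending IoU; returns labels
greedy_match <- function(pred, gt) {
  cand <- pairwise_iou(pred, gt)
  out <- tibble::tibble(gt = integer(), pred = integer(), iou = double())
  if (nrow(cand)) {
    cand <- cand[order(-cand$iou, gt$labels[cand$gt], pred$labels[cand$pred]), ]
    g_used <- logical(n_objects(gt))
    p_used <- logical(n_objects(pred))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      g <- cand$gt[i]; p <- cand$pred[i]
      if (!g_used[g] && !p_used[p]) {
        g_used[g] <- TRUE
        p_used[p] <- TRUE
        keep[i] <- TRUE
      }
    }
    cand <- cand[keep, ]
    out <- tibble::tibble(
      gt = gt$labels[cand$gt], pred = pred$labels[cand$pred], iou = cand$iou
    )
  }
  out
}

#' The standard DSB threshold grid
#' @return `seq(0.5, 0.95, by = 0.05)`.
#' @export
dsb_thresholds <- function() seq(0.5, 0.95, by = 0.05)

#' DSB 2018 score for one image
#'
#' The Kaggle Data Science Bowl 2018 metric: the mean over IoU thresholds
#' 0.5 to 0.95 (step 0.05) of `TP(t) / (TP(t) + FP(t) + FN(t) + eps)`.
#' An image where both prediction and ground truth are empty scores 1 (a
#' perfect prediction must score 1; the raw formula would give 0).
#'
#' @param pred,gt [instance_set()]s on the same canvas.
#' @param thresholds IoU thresholds.
#' @param eps small constant added to denominators (default `1e-40`).
#' @return a real in `[0, 1]`.
#' @export
dsb_score <- function(pred, gt, thresholds = dsb_thresholds(), eps = 1e-40) {
  if (!n_objects(pred) && !n_objects(gt)) return(1)
  mt <- match_objects(pred, gt, thresholds)
  mean(mt$tp / (mt$tp + mt$fp + mt$fn + eps))
}

#' Threshold-averaged precision, recall and F1 plus the DSB score
#'
#' Per threshold `t`:
#' `precision(t) = TP/(TP+FP+eps)`, `recall(t) = TP/(TP+FN+eps)`,
#' `F1(t) = 2 P R/(P+R+eps)`; each is averaged over the threshold grid to
#' give mAP, mAR and mF1 for the image. Note mF1 is the threshold-averaged
#' harmonic mean, not the harmonic mean of mAP and mAR.
#'
#' @inheritParams dsb_score
#' @return a one-row tibble: `dsb`, `map`, `mar`, `mf1`, `n_pred`, `n_gt`.
#' @export
score_instances <- function(pred, gt, thresholds = dsb_thresholds(),
                            eps = 1e-40) {
  mt <- match_objects(pred, gt, thresholds)
  per_t <- dplyr::mutate(
    tibble::as_tibble(mt),
    precision = .data$tp / (.data$tp + .data$fp + eps),
    recall = .data$tp / (.data$tp + .data$fn + eps),
    f1 = 2 * .data$precision * .data$recall /
      (.data$precision + .data$recall + eps),
    dsb = .data$tp / (.data$tp + .data$fp + .data$fn + eps)
  )
  dsb <- if (!n_objects(pred) && !n_objects(gt)) 1 else mean(per_t$dsb)
  tibble::tibble(
    dsb = dsb,
    map = mean(per_t$precision),
    mar = mean(per_t$recall),
    mf1 = mean(per_t$f1),
    n_pred = n_objects(pred),
    n_gt = n_objects(gt)
  )
}

#' Score a set of images
#'
#' Per-image scores plus the set-level report: the mean of the per-image
#' threshold-averaged scores over the images (the DSB convention).
#'
#' @param pred,gt lists of [instance_set()]s of equal length.
#' @param ids optional image identifiers.
#' @param thresholds,eps see [dsb_score()].
#' @return an object of class `score_report`: a tibble of per-image scores
#'   (`id`, `dsb`, `map`, `mar`, `mf1`, `n_pred`, `n_gt`) with the set-level
#'   means available through [glance.score_report()].
#' @export
score_set <- function(pred, gt, ids = NULL, thresholds = dsb_thresholds(),
                      eps = 1e-40) {
  stopifnot(length(pred) == length(gt))
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(pred))
  per <- purrr::map2_dfr(pred, gt, score_instances,
                         thresholds = thresholds, eps = eps)
  out <- dplyr::bind_cols(tibble::tibble(id = ids), per)
  class(out) <- c("score_report", class(out))
  out
}

#' Set-level summary of a score report
#' @param x a `score_report` from [score_set()].
#' @param ... unused.
#' @return a one-row tibble with mean `dsb`, `map`, `mar`, `mf1` and the
#'   number of images.
#' @export
glance.score_report <- function(x, ...) {
  tibble::tibble(
    dsb = mean(x$dsb), map = mean(x$map), mar = mean(x$mar),
    mf1 = mean(x$mf1), n_images = nrow(x)
  )
}

#' Four-way segmentation error taxonomy
#'
#' Classifies disagreements between a prediction and the ground truth into
#' the four error modes of nucleus segmentation: missed nuclei, falsely
#' detected objects, splits (one ground-truth object fragmented across
#' several predictions) and merges (one prediction covering several
#' ground-truth objects).
#'
#' An object is *matched* when it participates in a one-to-one pair with
#' IoU above 0.5. A ground-truth object lacking such a match is a *split*
#' when at least two predictions each cover at least 30% of its area (at
#' least 15% each when more than two contribute); it is *missed* when no
#' prediction covers a significant (30%) part of it at all. Merges apply
#' the same rule with the roles of prediction and ground truth swapped
#' (coverage fractions measured on the predicted object's area);
#' unmatched predictions with no significant ground-truth overlap are
#' *falsely detected*. Unmatched objects with exactly one significant
#' partial counterpart fall into no category (they are boundary errors,
#' not detection errors).
#'
#' @param pred,gt [instance_set()]s on the same canvas.
#' @param frac2 significant-overlap fraction when exactly two objects
#'   contribute (default 0.30).
#' @param frac_many fraction when more than two contribute (default 0.15).
#' @return a one-row tibble: `missed`, `false_detected`, `split`, `merged`.
#' @export
error_taxonomy <- function(pred, gt, frac2 = 0.30, frac_many = 0.15) {
  stopifnot(inherits(pred, "instance_set"), inherits(gt, "instance_set"))
  validate_same_canvas(pred, gt)
  pairs <- greedy_match(pred, gt)
  hit <- pairs[pairs$iou > 0.5, ]
  gt_matched <- gt$labels %in% hit$gt
  pred_matched <- pred$labels %in% hit$pred
  ov <- pairwise_iou(pred, gt)

  # coverage fractions of each gt object by predictions
  split_of <- function(fracs) {
    n30 <- sum(fracs >= frac2)
    n15 <- sum(fracs >= frac_many)
    n30 >= 2 || n15 >= 3
  }
  gt_areas <- lengths(gt$objects)
  pr_areas <- lengths(pred$objects)
  splits <- 0L; missed <- 0L
  for (g in seq_len(n_objects(gt))) {
    if (gt_matched[g]) next
    fr <- ov$intersection[ov$gt == g] / gt_areas[g]
    if (length(fr) >= 2 && split_of(fr)) {
      splits <- splits + 1L
    } else if (!length(fr) || max(fr) < frac2) {
      missed <- missed + 1L
    }
  }
  merges <- 0L; falsed <- 0L
  for (p in seq_len(n_objects(pred))) {
    if (pred_matched[p]) next
    fr <- ov$intersection[ov$pred == p] / pr_areas[p]
    if (length(fr) >= 2 && split_of(fr)) {
      merges <- merges + 1L
    } else if (!length(fr) || max(fr) < frac2) {
      falsed <- falsed + 1L
    }
  }
  tibble::tibble(missed = missed, false_detected = falsed,
                 split = splits, merged = merges)
}

#' Mean binary cross-entropy over a mask
#'
#' The per-pixel average binary cross-entropy between a predicted
#' probability grid and a binary target — the mask-branch loss of
#' detection-style segmentation networks:
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`.
#' Probabilities are clipped to `[clip, 1 - clip]` so the loss stays finite
#' on saturated predictions.
#'
#' @param pred_probs numeric matrix of probabilities in `[0, 1]`.
#' @param gt binary matrix of the same dimensions.
#' @param clip clipping epsilon (default `1e-12`).
#' @return a non-negative real; `log(2)` when `pred_probs` is uniformly 0.5.
#' @export
mask_bce_loss <- function(pred_probs, gt, clip = 1e-12) {
  stopifnot(is.matrix(pred_probs), is.matrix(gt))
  validate_same_canvas(pred_probs, gt)
  if (any(pred_probs < 0 | pred_probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!all(gt %in% c(0, 1)))
    stop("ground truth must be binary", call. = FALSE)
  p <- pmin(pmax(pred_probs, clip), 1 - clip)
  y <- as.numeric(gt)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Classification accuracy
#'
#' Fraction of correct binary calls — as used to summarise a
#' real-versus-synthetic discrimination study.
#'
#' @param calls,truth equal-length vectors of 0/1 calls and true classes.
#' @return correct / total.
#' @export
classification_accuracy <- function(calls, truth) {
  if (!length(calls) || length(calls) != length(truth))
    stop("calls and truth must be non-empty and of equal length", call. = FALSE)
  if (!all(calls %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("calls and truth must be 0/1", call. = FALSE)
  mean(calls == truth)
}
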