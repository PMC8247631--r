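#' Post-processing parameter six-tuple
#'
#' The six parameters governing the refinement chain, in chain order:
#' * `p1` — boundary-surround fraction above which an object is merged
#'   into its neighbour (fraction in `[0, 1]`; 0.17 means 17%).
#' * `p2` — minimum object area in pixels (strictly smaller objects are
#'   removed).
#' * `p3` — probability threshold deciding membership inside the contour
#'   band.
#' * `p4`, `p5` — band extent in pixels, inwards / outwards of the
#'   detected contour.
#' * `p6` — minimum mean object probability (strictly lower-confidence
#'   objects are removed).
#'
#' Defaults are the tuned operating point `(0.17, 44, 0.9375, 1, 1, 0.8)`.
#'
#' @param p1,p2,p3,p4,p5,p6 see above.
#' @return a one-row tibble of class `postprocess_params`.
#' @export
postprocess_params <- function(p1 = 0.17, p2 = 44, p3 = 0.9375,
                               p4 = 1, p5 = 1, p6 = 0.8) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p3 >= 0, p3 <= 1,
            p4 >= 0, p5 >= 0, p6 >= 0, p6 <= 1)
  out <- tibble::tibble(p1 = p1, p2 = p2, p3 = p3,
                        p4 = as.integer(round(p4)),
                        p5 = as.integer(round(p5)), p6 = p6)
  class(out) <- c("postprocess_params", class(out))
  out
}

#' Remove objects entirely contained in a larger object
#'
#' An object is dropped iff its pixel set is a subset of a strictly larger
#' object's pixel set (only meaningful when instances overlap). Idempotent.
#'
#' @param s an [instance_set()].
#' @return the filtered [instance_set()].
#' @export
remove_contained <- function(s) {
  n <- n_objects(s)
  if (n < 2) return(s)
  ov <- pairwise_iou(s, s)
  areas <- lengths(s$objects)
  drop <- rep(FALSE, n)
  for (r in seq_len(nrow(ov))) {
    a <- ov$gt[r]; b <- ov$pred[r]
    if (a != b && ov$intersection[r] == areas[a] && areas[b] > areas[a])
      drop[a] <- TRUE
  }
  keep_objects(s, !drop)
}

#' Merge objects surrounded by a neighbour
#'
#' An object is merged into a neighbour when more than `p1` of its
#' boundary pixels touch that neighbour (8-connectivity). When several
#' merges qualify, the most-surrounded object is absorbed first; the
#' merged object is the union of the two and keeps the absorbing object's
#' label. Applied repeatedly until a fixed point (at most `n` passes).
#'
#' @param s an [instance_set()].
#' @param p1 surround fraction in `[0, 1]`; the default is the tuned 0.17
#'   (17%).
#' @return an [instance_set()].
#' @export
merge_surrounded <- function(s, p1 = 0.17) {
  stopifnot(p1 >= 0, p1 <= 1)
  repeat {
    n <- n_objects(s)
    if (n < 2) return(s)
    best <- NULL
    for (a in seq_len(n)) {
      frac <- surround_fractions(s, a)
      if (length(frac) && max(frac) > p1 &&
          (is.null(best) || max(frac) > best$frac)) {
        best <- list(a = a, b = as.integer(names(frac)[which.max(frac)]),
                     frac = max(frac))
      }
    }
    if (is.null(best)) return(s)
    objects <- s$objects
    objects[[best$b]] <- sort(unique(c(objects[[best$b]], objects[[best$a]])))
    s <- instance_set(objects[-best$a], dim = s$dim,
                      labels = s$labels[-best$a])
  }
}

# fraction of object a's boundary pixels 8-adjacent to each other object;
# named by the other object's position index
surround_fractions <- function(s, a) {
  h <- s$dim[1]; w <- s$dim[2]
  px <- s$objects[[a]]
  nb <- neighbours8(px, h, w)
  in_a <- matrix(nb %in% px & !is.na(nb), nrow = length(px))
  on_canvas <- matrix(!is.na(nb), nrow = length(px))
  boundary <- rowSums(in_a) < rowSums(on_canvas)  # has a neighbour outside a
  if (!any(boundary)) return(numeric())
  nb <- nb[boundary, , drop = FALSE]
  out <- numeric(0)
  for (b in seq_along(s$objects)) {
    if (b == a) next
    adj <- matrix(nb %in% s$objects[[b]], nrow = nrow(nb))
    hits <- sum(rowSums(adj) > 0)
    if (hits > 0) out[as.character(b)] <- hits / sum(boundary)
  }
  out
}

# 8-neighbourhood linear indices; NA off canvas
neighbours8 <- function(px, h, w) {
  r <- (px - 1L) %% h + 1L
  cc <- (px - 1L) %/% h + 1L
  off <- cbind(
    c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  nb <- matrix(NA_integer_, length(px), 8)
  for (k in 1:8) {
    rr <- r + off[k, 1]; ck <- cc + off[k, 2]
    ok <- rr >= 1L & rr <= h & ck >= 1L & ck <= w
    nb[ok, k] <- rr[ok] + (ck[ok] - 1L) * h
  }
  nb
}

#' Remove small objects
#'
#' Objects with area strictly smaller than `p2` pixels are removed.
#' Idempotent.
#'
#' @param s an [instance_set()].
#' @param p2 area threshold in pixels.
#' @return an [instance_set()].
#' @export
remove_small <- function(s, p2 = 44) {
  stopifnot(p2 >= 0)
  keep_objects(s, lengths(s$objects) >= p2)
}

#' Probability-guided contour correction
#'
#' For each object a soft margin band is built: `p5` pixels outwards
#' (dilation) minus `p4` pixels inwards (erosion) of the contour, with a
#' square structuring element. Inside the band a pixel belongs to the
#' object iff its probability is at least `p3`; membership outside the
#' band is unchanged. Pixels claimed by several objects go to the object
#' whose original mask is nearest (ties to the lower label). Objects
#' corrected down to zero pixels are dropped. Never adds objects.
#'
#' @param s an [instance_set()].
#' @param prob a probability matrix on the same canvas.
#' @param p3 probability threshold in `[0, 1]`.
#' @param p4,p5 non-negative integer band extents (inwards / outwards).
#' @return an [instance_set()].
#' @export
unet_correct <- function(s, prob, p3 = 0.9375, p4 = 1, p5 = 1) {
  stopifnot(inherits(s, "instance_set"))
  validate_same_canvas(s, prob)
  p4 <- as.integer(round(p4)); p5 <- as.integer(round(p5))
  stopifnot(p4 >= 0, p5 >= 0)
  if ((p4 == 0 && p5 == 0) || !n_objects(s)) return(s)
  h <- s$dim[1]; w <- s$dim[2]
  new_objects <- vector("list", n_objects(s))
  for (i in seq_len(n_objects(s))) {
    px <- s$objects[[i]]
    r <- (px - 1L) %% h + 1L
    cc <- (px - 1L) %/% h + 1L
    # work in a window: bbox expanded by p5
    r1 <- max(1L, min(r) - p5); r2 <- min(h, max(r) + p5)
    c1 <- max(1L, min(cc) - p5); c2 <- min(w, max(cc) + p5)
    wh <- r2 - r1 + 1L
    patch <- matrix(FALSE, wh, c2 - c1 + 1L)
    patch[cbind(r - r1 + 1L, cc - c1 + 1L)] <- TRUE
    dil <- if (p5 > 0) {
      as.matrix(EBImage::dilate(patch * 1, makeBrush_box(p5))) > 0
    } else patch
    ero <- if (p4 > 0) {
      as.matrix(EBImage::erode(patch * 1, makeBrush_box(p4))) > 0
    } else patch
    band <- dil & !ero
    pw <- prob[r1:r2, c1:c2, drop = FALSE]
    new_patch <- ero | (band & pw >= p3)
    idx <- which(new_patch)
    nr <- (idx - 1L) %% wh + r1
    nc <- (idx - 1L) %/% wh + c1
    new_objects[[i]] <- as.integer(nr + (nc - 1L) * h)
  }
  new_objects <- resolve_claims(new_objects, s, h)
  keep <- lengths(new_objects) > 0
  if (!any(keep)) return(empty_instance_set(s$dim))
  instance_set(new_objects[keep], dim = s$dim, labels = s$labels[keep])
}

makeBrush_box <- function(p) EBImage::makeBrush(2L * p + 1L, shape = "box")

# give each multiply-claimed pixel to the object whose original mask is
# nearest; ties to the lower label
resolve_claims <- function(new_objects, s, h) {
  all_px <- unlist(new_objects)
  dup <- unique(all_px[duplicated(all_px)])
  if (!length(dup)) return(new_objects)
  owner <- rep.int(seq_along(new_objects), lengths(new_objects))
  for (px in dup) {
    claim <- owner[all_px == px]
    pr <- (px - 1L) %% h + 1L
    pc <- (px - 1L) %/% h + 1L
    d <- vapply(claim, function(o) {
      orig <- s$objects[[o]]
      if (px %in% orig) return(0)
      orr <- (orig - 1L) %% h + 1L
      occ <- (orig - 1L) %/% h + 1L
      min((orr - pr)^2 + (occ - pc)^2)
    }, numeric(1))
    best <- claim[order(d, s$labels[claim])][1]
    for (o in setdiff(claim, best)) {
      new_objects[[o]] <- setdiff(new_objects[[o]], px)
    }
  }
  new_objects
}

#' Remove low-confidence objects
#'
#' Objects whose mean probability over their pixels is strictly below
#' `p6` are removed.
#'
#' @param s an [instance_set()].
#' @param prob probability matrix on the same canvas.
#' @param p6 mean-probability floor in `[0, 1]`.
#' @return an [instance_set()].
#' @export
remove_low_confidence <- function(s, prob, p6 = 0.8) {
  stopifnot(p6 >= 0, p6 <= 1)
  validate_same_canvas(s, prob)
  keep <- purrr::map_lgl(s$objects, function(px) mean(prob[px]) >= p6)
  keep_objects(s, keep)
}

keep_objects <- function(s, keep) {
  if (all(keep)) return(s)
  if (!any(keep)) return(empty_instance_set(s$dim))
  instance_set(s$objects[keep], dim = s$dim, labels = s$labels[keep])
}

#' The full six-parameter refinement chain
#'
#' Applies, in order: [remove_contained()], [merge_surrounded()] (`p1`),
#' [remove_small()] (`p2`), [unet_correct()] (`p3`, `p4`, `p5`),
#' [remove_low_confidence()] (`p6`). Individual stages can be switched
#' off; the whole refinement may be skipped when boundary-level accuracy
#' is not needed.
#'
#' @param s an [instance_set()] (raw detector output).
#' @param prob probability matrix on the same canvas.
#' @param params a [postprocess_params()] row.
#' @param stages character subset of
#'   `c("contained", "surrounded", "small", "correct", "confidence")`.
#' @return the refined [instance_set()].
#' @export
postprocess_chain <- function(s, prob, params = postprocess_params(),
                              stages = c("contained", "surrounded", "small",
                                         "correct", "confidence")) {
  if ("contained" %in% stages) s <- remove_contained(s)
  if ("surrounded" %in% stages) s <- merge_surrounded(s, params$p1)
  if ("small" %in% stages) s <- remove_small(s, params$p2)
  if ("correct" %in% stages) s <- unet_correct(s, prob, params$p3, params$p4, params$p5)
  if ("confidence" %in% stages) s <- remove_low_confidence(s, prob, params$p6)
  s
}
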