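#' Classical threshold-plus-watershed segmentation backend
#'
#' A fully deterministic, CPU-only backend satisfying the segmentation
#' backend contract `(image) -> (instances, probability map)`: Otsu global
#' threshold, morphological opening, then a distance-transform watershed
#' to separate touching nuclei. The probability map is the smoothed
#' foreground score normalised to `[0, 1]`. Intended as the pluggable
#' fallback where a trained neural backend is not available, and as the
#' pre-segmenter for size estimation.
#'
#' Bright-on-dark images are assumed; if the foreground is darker than the
#' background the image is inverted first (decided by comparing the Otsu
#' class means).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param min_area objects smaller than this many pixels are discarded.
#' @param blur_sigma pre-threshold smoothing sigma.
#' @param tolerance watershed tolerance.
#' @return a list with `instances` (an [instance_set()]) and `prob` (a
#'   probability matrix).
#' @export
baseline_segment <- function(image, min_area = 20, blur_sigma = 1,
                             tolerance = 1) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (diff(rng) == 0) {
    return(list(instances = empty_instance_set(dim(image)),
                prob = probability_map(matrix(0, nrow(image), ncol(image)))))
  }
  norm <- (image - rng[1]) / diff(rng)
  sm <- as.matrix(EBImage::gblur(norm, sigma = blur_sigma))
  th <- EBImage::otsu(sm, range = c(0, 1))
  # nuclei are the minority phase; invert when the bright side dominates
  if (mean(sm > th) > 0.5) {
    sm <- 1 - sm
    th <- 1 - th
  }
  fg <- sm > th
  fg <- as.matrix(EBImage::opening(fg * 1, EBImage::makeBrush(3, "box"))) > 0
  if (!any(fg)) {
    return(list(instances = empty_instance_set(dim(image)),
                prob = probability_map(matrix(0, nrow(image), ncol(image)))))
  }
  dm <- EBImage::distmap(fg * 1)
  ws <- as.matrix(EBImage::watershed(dm, tolerance = tolerance))
  lab <- matrix(as.integer(ws), nrow(ws), ncol(ws))
  inst <- as_instance_set(lab)
  inst <- keep_objects(inst, lengths(inst$objects) >= min_area)
  # relabel 1..n after filtering
  if (n_objects(inst)) {
    inst <- instance_set(inst$objects, dim = inst$dim,
                         labels = seq_len(n_objects(inst)))
  }
  band <- as.matrix(EBImage::gblur(fg * 1, sigma = 1))
  band <- band / max(band)
  list(instances = inst, prob = probability_map(band))
}

#' Training-data preparation: cluster, synthesize, augment
#'
#' The training-side flow: extract features, cluster images into styles,
#' estimate per-style statistics, generate `per_style` synthetic
#' mask/image pairs per style, and (optionally) augment the real pairs.
#' When masks are absent, the baseline backend supplies rough
#' pre-segmentation masks for style learning.
#'
#' @param data a tibble with columns `id`, `image` and optionally
#'   `instances` (as from [make_toy_dataset()]).
#' @param per_style synthetic pairs per style cluster.
#' @param k number of style clusters; `NULL` uses [choose_k()].
#' @param canvas synthetic canvas.
#' @param renderer style renderer (default [render_baseline()]).
#' @param augment logical: also produce one augmented copy of each real
#'   pair.
#' @param cfg an [augment_config()].
#' @param seed integer seed.
#' @return a list with `clusters` (a `style_clustering`), `synthetic` (a
#'   tibble of generated pairs), `augmented` (tibble or `NULL`) and
#'   `manifest` (a tibble describing every produced sample).
#' @export
run_training_prep <- function(data, per_style = 20, k = NULL,
                              canvas = c(256, 256),
                              renderer = render_baseline,
                              augment = FALSE, cfg = augment_config(),
                              seed) {
  stopifnot(is.data.frame(data), nrow(data) >= 1,
            all(c("id", "image") %in% names(data)))
  if (!"instances" %in% names(data) || any(purrr::map_lgl(data$instances, is.null))) {
    data$instances <- purrr::map(data$image, ~ baseline_segment(.x)$instances)
  }
  feats <- feature_table(data$image, ids = data$id)
  if (is.null(k)) k <- choose_k(nrow(data))
  clusters <- cluster_styles(feats, model = NULL, k = k, seed = seed)
  synthetic <- generate_training_set(clusters, data, per_style = per_style,
                                     canvas = canvas, renderer = renderer,
                                     seed = seed)
  augmented <- NULL
  if (augment) {
    augmented <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
      aug <- augment_sample(data$image[[i]], data$instances[[i]], cfg,
                            seed = (as.integer(seed) + i) %% 2147483647L)
      tibble::tibble(id = paste0(data$id[i], "_aug"),
                     image = list(aug$image), instances = list(aug$instances))
    })
  }
  manifest <- dplyr::bind_rows(
    tibble::tibble(id = data$id, source = "real",
                   style = clusters$assignment,
                   n_objects = purrr::map_int(data$instances, n_objects)),
    tibble::tibble(id = synthetic$id, source = "synthetic",
                   style = synthetic$style,
                   n_objects = purrr::map_int(synthetic$instances, n_objects)),
    if (!is.null(augmented)) {
      tibble::tibble(id = augmented$id, source = "augmented",
                     style = clusters$assignment,
                     n_objects = purrr::map_int(augmented$instances, n_objects))
    }
  )
  list(clusters = clusters, synthetic = synthetic, augmented = augmented,
       manifest = manifest)
}

#' Size-normalized inference with post-processing
#'
#' Per image: pre-segment with the backend, estimate the typical nucleus
#' diameter, rescale the image so nuclei hit the target diameter, segment
#' the normalized image, map the instances back to native resolution,
#' refine with the post-processing chain, and (when ground truth is
#' given) score. Scoring happens at native resolution so the ground truth
#' is never resampled.
#'
#' @param data tibble with columns `id`, `image` and optionally
#'   `instances` (ground truth).
#' @param backend a segmentation backend
#'   `function(image) -> list(instances =, prob =)`
#'   (default [baseline_segment()]).
#' @param params a [postprocess_params()] row.
#' @param target target nucleus diameter in pixels.
#' @param prior_diameter fallback diameter when the pre-segmentation
#'   finds no objects.
#' @param refine logical; `FALSE` skips the post-processing chain.
#' @param verbose log per-stage lines.
#' @return a list with `predictions` (tibble: `id`, `instances`, `prob`,
#'   `factor`, `seconds`) and `scores` (a [score_set()] report, or `NULL`
#'   without ground truth).
#' @export
run_inference <- function(data, backend = baseline_segment,
                          params = postprocess_params(), target = 40,
                          prior_diameter = target, refine = TRUE,
                          verbose = FALSE) {
  stopifnot(is.data.frame(data), all(c("id", "image") %in% names(data)))
  if (!nrow(data)) {
    return(list(predictions = tibble::tibble(
      id = character(), instances = list(), prob = list(),
      factor = double(), seconds = double()
    ), scores = NULL))
  }
  preds <- purrr::map(seq_len(nrow(data)), function(i) {
    t0 <- proc.time()[["elapsed"]]
    img <- data$image[[i]]
    pre <- tryCatch(backend(img), error = function(e) {
      stop("backend failed on image '", data$id[i], "' (pre-segmentation): ",
           conditionMessage(e), call. = FALSE)
    })
    d <- if (n_objects(pre$instances)) {
      estimate_typical_diameter(pre$instances)
    } else {
      prior_diameter
    }
    plan <- plan_scale(d, target = target)
    factor <- plan$factor
    # clamp to the supported rescale window
    factor <- min(max(factor, 0.25), 4)
    sc <- rescale_pair(img, pre$instances, factor)
    seg <- tryCatch(backend(sc$image), error = function(e) {
      stop("backend failed on image '", data$id[i], "' (segmentation): ",
           conditionMessage(e), call. = FALSE)
    })
    back <- rescale_pair(unclass(seg$prob), seg$instances, 1 / factor)
    inst <- back$instances
    # the inverse rescale can land a pixel or two off the native canvas
    inst <- conform_canvas(inst, dim(img))
    prob <- probability_map(as.matrix(EBImage::resize(
      seg$prob, w = nrow(img), h = ncol(img), filter = "bilinear"
    )))
    if (refine) inst <- postprocess_chain(inst, prob, params)
    dt <- proc.time()[["elapsed"]] - t0
    if (verbose) {
      message(sprintf("[inference] %s: factor %.2f, %d object(s), %.2fs",
                      data$id[i], factor, n_objects(inst), dt))
    }
    list(instances = inst, prob = prob, factor = factor, seconds = dt)
  })
  out <- tibble::tibble(
    id = data$id,
    instances = purrr::map(preds, "instances"),
    prob = purrr::map(preds, "prob"),
    factor = purrr::map_dbl(preds, "factor"),
    seconds = purrr::map_dbl(preds, "seconds")
  )
  scores <- NULL
  if ("instances" %in% names(data) &&
      !any(purrr::map_lgl(data$instances, is.null))) {
    scores <- score_set(out$instances, data$instances, ids = data$id)
  }
  list(predictions = out, scores = scores)
}

# re-express an instance set on a (possibly slightly different) canvas
conform_canvas <- function(s, dim) {
  dim <- as.integer(dim)
  if (identical(s$dim, dim)) return(s)
  h0 <- s$dim[1]
  objects <- list(); labels <- integer()
  for (i in seq_along(s$objects)) {
    px <- s$objects[[i]]
    r <- (px - 1L) %% h0 + 1L
    cc <- (px - 1L) %/% h0 + 1L
    keep <- r <= dim[1] & cc <= dim[2]
    if (any(keep)) {
      objects <- c(objects, list(r[keep] + (cc[keep] - 1L) * dim[1]))
      labels <- c(labels, s$labels[i])
    }
  }
  if (!length(objects)) return(empty_instance_set(dim))
  instance_set(objects, dim = dim, labels = labels)
}

#' Read and validate a pipeline configuration
#'
#' A single YAML file holds every tunable of the pipeline; unknown keys are
#' rejected so typos fail loudly, and CLI flags override config keys.
#' Recognised keys (all optional, defaults in parentheses):
#' `schema` (1), `target_diameter` (40), `canvas` (512), `per_style` (20),
#' `k` ("auto"), `oversegmentation` (15), `db_fraction` (0.5), `seed` (1),
#' `min_area` (20), `refine` (TRUE), and a `postprocess` block with
#' `p1..p6`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file's values.
#' @return a validated named list of class `pipeline_config`, including a
#'   `params` element built by [postprocess_params()].
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    schema = 1L, target_diameter = 40, canvas = 512L, per_style = 20L,
    k = "auto", oversegmentation = 15, db_fraction = 0.5, seed = 1L,
    min_area = 20L, refine = TRUE,
    postprocess = list(p1 = 0.17, p2 = 44, p3 = 0.9375, p4 = 1, p5 = 1,
                       p6 = 0.8)
  )
  cfg <- defaults
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    bad <- setdiff(names(raw), names(defaults))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!is.null(raw$schema) && raw$schema != 1L)
      stop("unsupported config schema version: ", raw$schema, call. = FALSE)
    cfg <- utils::modifyList(cfg, raw)
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  stopifnot(cfg$target_diameter > 0, cfg$canvas >= 8, cfg$per_style >= 0,
            cfg$oversegmentation > 0, cfg$db_fraction >= 0,
            cfg$db_fraction <= 1, cfg$min_area >= 0)
  if (!identical(cfg$k, "auto")) stopifnot(cfg$k >= 1)
  cfg$params <- do.call(postprocess_params, cfg$postprocess)
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

#' End-to-end demonstration on generated fixtures
#'
#' Generates a toy dataset, runs training preparation (clustering +
#' synthesis) and size-normalized inference with the baseline backend,
#' and returns everything. Deterministic given `seed`.
#'
#' @param n_images number of toy images.
#' @param seed integer seed.
#' @param per_style synthetic pairs per style.
#' @param canvas toy canvas.
#' @return a list with `data`, `prep`, `inference`, and `summary` (a
#'   one-row tibble of headline numbers).
#' @export
run_demo <- function(n_images = 6, seed = 1, per_style = 2,
                     canvas = c(128, 128)) {
  data <- make_toy_dataset(n_images, objects_per_image = c(6, 10),
                           diameter = c(18, 22), canvas = canvas, seed = seed)
  prep <- run_training_prep(data, per_style = per_style, k = 1,
                            canvas = canvas, seed = seed)
  inf <- run_inference(data, params = postprocess_params(p2 = 20, p6 = 0.2))
  summary <- dplyr::bind_cols(
    glance(inf$scores),
    tibble::tibble(n_synthetic = nrow(prep$synthetic))
  )
  list(data = data, prep = prep, inference = inf, summary = summary)
}
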