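#' Synthetic multi-center study configuration
#'
#' [center_profile()] describes one validation center: number of
#' single-frame images, polyp prevalence (probability that a frame contains
#' at least one polyp), image resolution, the mixture over polyp size
#' classes, per-class truncated log-normal area parameters, the mixture over
#' reference shapes (convex ellipses standing in for protruded polyps,
#' non-convex crescents for flat ones), and the number of patients (images
#' are assigned round-robin).
#'
#' @param center_id center label.
#' @param n_images number of frames.
#' @param prevalence probability in `[0, 1]` that a frame has a polyp.
#' @param resolution `c(width, height)` in pixels.
#' @param size_mixture weights over `c(small, medium, large)`; normalised.
#' @param area_meanlog per-class log-normal `meanlog` of the polyp area at
#'   1920x1080 (scaled to `resolution`); areas are truncated to the class
#'   interval.
#' @param area_sdlog log-normal `sdlog` common to the classes.
#' @param shape_mixture weights over `c(ellipse, crescent)`.
#' @param patients number of patients at the center.
#' @return a `pv_center_profile`.
#' @export
center_profile <- function(center_id, n_images, prevalence,
                           resolution = c(1920, 1080),
                           size_mixture = c(small = 0.25, medium = 0.45, large = 0.30),
                           area_meanlog = log(c(small = 4500, medium = 20000, large = 80000)),
                           area_sdlog = 0.5,
                           shape_mixture = c(ellipse = 0.7, crescent = 0.3),
                           patients = max(1L, round(n_images / 4))) {
  stopifnot(prevalence >= 0, prevalence <= 1, n_images >= 1,
            all(size_mixture >= 0), sum(size_mixture) > 0,
            all(shape_mixture >= 0), sum(shape_mixture) > 0)
  structure(list(
    center_id = as.character(center_id), n_images = as.integer(n_images),
    prevalence = prevalence, resolution = as.integer(resolution),
    size_mixture = size_mixture / sum(size_mixture),
    area_meanlog = area_meanlog, area_sdlog = area_sdlog,
    shape_mixture = shape_mixture / sum(shape_mixture),
    patients = as.integer(patients)
  ), class = "pv_center_profile")
}

#' Detector perturbation model
#'
#' Turns reference objects into detector-like box predictions:
#'
#' * size-dependent misses — `miss_rate(area) = plogis(miss_slope *
#'   (log(m) - log(area)))` with midpoint area `m` (at 1920x1080, scaled to
#'   the image resolution), so smaller polyps are missed more often;
#'   `miss_slope = 0` gives a flat 50% miss rate for negative controls;
#' * localization jitter — the true bounding box center is shifted by
#'   Gaussian noise, absolute in pixels (`jitter = "absolute"`, sd
#'   `center_jitter_sd`) or relative to the box extent
#'   (`jitter = "relative"`, sd `center_jitter_frac` times box
#'   width/height);
#' * multiplicative scale noise — box width and height are rescaled by a
#'   common log-normal factor `exp(N(0, scale_noise_sd))`;
#' * confidence — `clip(realized mask IoU + N(0, confidence_sd), 0, 1)`, so
#'   confidence ranking correlates with prediction quality;
#' * false positives — per image a Poisson(`fp_per_image`) number of random
#'   boxes with `Beta(fp_conf_shape)` confidences.
#'
#' Absolute-pixel jitter is the mechanism that produces a strong polyp-size
#' effect on AP; [relative_jitter_control()] returns the negative-control
#' variant (relative jitter, size-independent miss rate) under which the
#' effect vanishes.
#'
#' @param jitter `"absolute"` or `"relative"`.
#' @param center_jitter_sd absolute jitter sd in pixels.
#' @param center_jitter_frac relative jitter sd as a fraction of the box
#'   extent.
#' @param scale_noise_sd log-scale sd of the multiplicative size noise.
#' @param miss_midpoint_area area (px at 1920x1080) with 50% miss rate.
#' @param miss_slope logistic slope in log-area; `>= 0`.
#' @param fp_per_image Poisson rate of false positives per image.
#' @param confidence_sd sd of the Gaussian confidence noise.
#' @param fp_conf_shape `c(alpha, beta)` of the false-positive confidence
#'   distribution.
#' @return a `pv_perturbation_model`.
#' @export
perturbation_model <- function(jitter = c("absolute", "relative"),
                               center_jitter_sd = 15,
                               center_jitter_frac = 0.15,
                               scale_noise_sd = 0.1,
                               miss_midpoint_area = 6000,
                               miss_slope = 1.28,
                               fp_per_image = 0.2,
                               confidence_sd = 0.1,
                               fp_conf_shape = c(2, 5)) {
  jitter <- match.arg(jitter)
  stopifnot(center_jitter_sd >= 0, center_jitter_frac >= 0, scale_noise_sd >= 0,
            miss_midpoint_area > 0, miss_slope >= 0, fp_per_image >= 0,
            confidence_sd >= 0)
  structure(list(
    jitter = jitter, center_jitter_sd = center_jitter_sd,
    center_jitter_frac = center_jitter_frac, scale_noise_sd = scale_noise_sd,
    miss_midpoint_area = miss_midpoint_area, miss_slope = miss_slope,
    fp_per_image = fp_per_image, confidence_sd = confidence_sd,
    fp_conf_shape = fp_conf_shape
  ), class = "pv_perturbation_model")
}

#' @rdname perturbation_model
#' @param model a `pv_perturbation_model`.
#' @export
relative_jitter_control <- function(model = perturbation_model()) {
  model$jitter <- "relative"
  model$miss_slope <- 0
  model
}

#' Negative-control study specification
#'
#' Rebuilds a study spec so that no size-dependent mechanism remains:
#' localization jitter becomes relative to the object extent, the miss rate
#' becomes size-independent ([relative_jitter_control()]), and every
#' center's size mixture is made uniform. The last step matters because
#' class-stratified AP shares false positives across classes: with unequal
#' class prevalences the smaller class suffers proportionally more
#' contamination, an artifact of the metric's composition that has nothing
#' to do with detection quality. Under this control the size-class AP gaps
#' collapse; under the default absolute-jitter study they do not.
#'
#' @param spec a [study_spec()].
#' @return a `pv_study_spec`.
#' @export
negative_control_spec <- function(spec) {
  spec$perturbation <- relative_jitter_control(spec$perturbation)
  spec$centers <- purrr::map(spec$centers, function(prof) {
    prof$size_mixture <- c(small = 1, medium = 1, large = 1) / 3
    prof
  })
  spec
}

#' Clinician-rating simulation model
#'
#' @param generating_criterion [criterion()] whose hit/miss decision plays
#'   the clinician's judgment.
#' @param label_noise probability in `[0, 1]` of flipping a rating.
#' @return a `pv_rating_model`.
#' @export
rating_model <- function(generating_criterion = criterion("mask_iou", 0),
                         label_noise = 0) {
  stopifnot(label_noise >= 0, label_noise <= 1)
  structure(list(generating_criterion = generating_criterion,
                 label_noise = label_noise),
            class = "pv_rating_model")
}

#' Study specification
#'
#' @param centers list of [center_profile()]s.
#' @param perturbation a [perturbation_model()].
#' @param rating optional [rating_model()].
#' @param seed integer seed; a fixed seed makes generation byte-identical.
#' @return a `pv_study_spec`.
#' @export
study_spec <- function(centers, perturbation = perturbation_model(),
                       rating = rating_model(), seed = 1L) {
  if (inherits(centers, "pv_center_profile")) centers <- list(centers)
  structure(list(centers = centers, perturbation = perturbation,
                 rating = rating, seed = as.integer(seed)),
            class = "pv_study_spec")
}

#' Default six-center study
#'
#' Six centers with frame counts 256, 276, 457, 227, 208 and 88 and polyp
#' prevalences 98%, 89%, 99%, 64%, 99% and 94% at 1920x1080 — the scale of
#' a typical multi-center single-frame polyp test set. The same
#' configuration ships as `inst/extdata/six_center.yaml`.
#'
#' @param seed integer seed.
#' @param scale multiplier on the per-center frame counts (use `< 1` for
#'   quick desk runs).
#' @param ... passed on to [center_profile()] (e.g. `resolution`).
#' @return a `pv_study_spec`.
#' @export
default_six_center_spec <- function(seed = 1L, scale = 1, ...) {
  n <- c(256, 276, 457, 227, 208, 88)
  phi <- c(0.98, 0.89, 0.99, 0.64, 0.99, 0.94)
  centers <- purrr::map(seq_along(n), function(i) {
    center_profile(paste0("center", i), max(1L, round(n[i] * scale)), phi[i], ...)
  })
  study_spec(centers, seed = seed)
}

#' Read a study specification from YAML or JSON
#'
#' The file mirrors the constructor arguments: a `centers` list (fields of
#' [center_profile()]), optional `perturbation`, `rating` and `seed`
#' entries.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return a `pv_study_spec`.
#' @export
read_study_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  centers <- purrr::map(cfg$centers, function(cc) {
    args <- cc
    if (!is.null(args$resolution)) args$resolution <- as.integer(unlist(args$resolution))
    if (!is.null(args$size_mixture)) args$size_mixture <- unlist(args$size_mixture)
    if (!is.null(args$shape_mixture)) args$shape_mixture <- unlist(args$shape_mixture)
    if (!is.null(args$area_meanlog)) args$area_meanlog <- unlist(args$area_meanlog)
    do.call(center_profile, args)
  })
  pert <- if (is.null(cfg$perturbation)) perturbation_model()
          else do.call(perturbation_model, cfg$perturbation)
  rat <- if (is.null(cfg$rating)) rating_model()
         else rating_model(criterion(cfg$rating$kind %||% "mask_iou",
                                     cfg$rating$threshold %||% 0),
                           cfg$rating$label_noise %||% 0)
  study_spec(centers, pert, rat, seed = cfg$seed %||% 1L)
}

# ---- shape generation --------------------------------------------------

make_ellipse_runs <- function(cx, cy, a, b, width, height) {
  r0 <- max(0L, floor(cy - b)); r1 <- min(height - 1L, ceiling(cy + b))
  rws <- r0:r1
  t <- (rws + 0.5 - cy) / b
  ok <- abs(t) < 1
  rws <- rws[ok]
  half <- a * sqrt(1 - t[ok]^2)
  xs <- pmax(0L, ceiling(cx - half - 0.5))
  xe <- pmin(width, floor(cx + half - 0.5) + 1L)
  new_region(rws, xs, xe, width, height)
}

make_crescent_region <- function(cx, cy, a, b, width, height) {
  base <- make_ellipse_runs(cx, cy, a, b, width, height)
  bite <- make_ellipse_runs(cx, cy - 0.55 * b, 0.8 * a, 0.75 * b, width, height)
  region_difference(base, bite)
}

# Sample a log-normal area truncated to [lo, hi] by rejection with a
# uniform fallback, then rasterize the shape, rescaling until the realized
# pixel count lands in the class interval.
sample_polyp_region <- function(class, shape, prof) {
  w <- prof$resolution[1]; h <- prof$resolution[2]
  scale <- (w * h) / (1920 * 1080)
  bounds <- switch(class,
    small = c(225, 100^2 - 1), medium = c(100^2, 200^2),
    large = c(200^2 + 1, min(250000, 0.2 * 1920 * 1080))
  ) * scale
  meanlog <- prof$area_meanlog[[class]] + log(scale)
  area <- NA_real_
  for (k in 1:50) {
    cand <- stats::rlnorm(1, meanlog, prof$area_sdlog)
    if (cand >= bounds[1] && cand <= bounds[2]) { area <- cand; break }
  }
  if (is.na(area)) area <- stats::runif(1, bounds[1], bounds[2])
  target <- if (shape == "crescent") area / 0.68 else area
  q <- exp(stats::rnorm(1, 0, 0.2))
  a <- sqrt(target * q / pi); b <- sqrt(target / (pi * q))
  if (2 * a + 4 > w || 2 * b + 4 > h) {
    rlang::abort(paste0("cannot fit a ", class, " polyp into a ", w, "x", h, " canvas"),
                 class = "polypval_generation_error")
  }
  cx <- stats::runif(1, a + 1, w - a - 1)
  cy <- stats::runif(1, b + 1, h - b - 1)
  for (k in 1:20) {
    reg <- if (shape == "crescent") make_crescent_region(cx, cy, a, b, w, h)
           else make_ellipse_runs(cx, cy, a, b, w, h)
    got <- region_area(reg)
    if (got >= bounds[1] && got <= bounds[2] && got > 0) return(reg)
    adj <- sqrt(mean(bounds) / max(got, 1))
    a <- min(a * adj, (w - 4) / 2); b <- min(b * adj, (h - 4) / 2)
    cx <- min(max(cx, a + 1), w - a - 1)
    cy <- min(max(cy, b + 1), h - b - 1)
  }
  rlang::abort(paste0("failed to generate a ", class, " ", shape, " within its area interval"),
               class = "polypval_generation_error")
}

#' Generate the reference side of a synthetic study
#'
#' Per center, `n_images` frames; each frame carries a polyp with the
#' center's prevalence (and a second one with probability 0.05). Ellipse
#' masks are convex and labelled `"protruded"`; crescents are non-convex
#' (their centroid can fall outside the mask) and labelled `"flat"`.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [study_spec()].
#' @return a [pv_dataset()] without predictions.
#' @export
generate_references <- function(spec) {
  stopifnot(inherits(spec, "pv_study_spec"))
  set.seed(spec$seed)
  images <- list(); refs <- list()
  for (prof in spec$centers) {
    cid <- prof$center_id
    for (i in seq_len(prof$n_images)) {
      iid <- sprintf("%s_img%04d", cid, i)
      images[[length(images) + 1L]] <- tibble::tibble(
        image_id = iid, width = prof$resolution[1], height = prof$resolution[2],
        center_id = cid,
        patient_id = sprintf("%s_pat%03d", cid, ((i - 1L) %% prof$patients) + 1L)
      )
      if (stats::runif(1) >= prof$prevalence) next
      n_polyps <- 1L + stats::rbinom(1, 1, 0.05)
      for (k in seq_len(n_polyps)) {
        class <- sample(names(prof$size_mixture), 1, prob = prof$size_mixture)
        shape <- sample(names(prof$shape_mixture), 1, prob = prof$shape_mixture)
        reg <- sample_polyp_region(class, shape, prof)
        refs[[length(refs) + 1L]] <- tibble::tibble(
          ref_id = sprintf("%s_ref%d", iid, k), image_id = iid, mask = list(reg),
          polyp_type = if (shape == "crescent") "flat" else "protruded",
          area_px = region_area(reg)
        )
      }
    }
  }
  pv_dataset(dplyr::bind_rows(images),
             if (length(refs)) dplyr::bind_rows(refs) else NULL)
}

miss_probability <- function(model, area, width, height) {
  if (model$miss_slope == 0) return(rep(0.5, length(area)))
  scale <- (width * height) / (1920 * 1080)
  stats::plogis(model$miss_slope * (log(model$miss_midpoint_area * scale) - log(area)))
}

#' Generate detector-like predictions for a reference dataset
#'
#' Applies the [perturbation_model()]: per reference a size-dependent miss
#' draw, then center jitter, scale noise and clipping to the canvas, with
#' confidence tied to the realized mask IoU; plus Poisson false positives.
#' Deterministic given `seed`.
#'
#' @param ds a [pv_dataset()] with references.
#' @param model a [perturbation_model()].
#' @param seed integer seed.
#' @return `ds` with predictions attached.
#' @export
generate_predictions <- function(ds, model = perturbation_model(), seed = 1L) {
  stopifnot(inherits(model, "pv_perturbation_model"))
  set.seed(seed)
  refs_by_img <- split(seq_len(nrow(ds$references)), ds$references$image_id)
  preds <- list()
  for (i in seq_len(nrow(ds$images))) {
    iid <- ds$images$image_id[i]
    w <- ds$images$width[i]; h <- ds$images$height[i]
    k <- 0L
    for (j in refs_by_img[[iid]]) {
      ref <- ds$references[j, ]
      if (stats::runif(1) < miss_probability(model, ref$area_px, w, h)) next
      bb <- bounding_box(ref$mask[[1]])
      bw <- unname(bb["x1"] - bb["x0"]); bh <- unname(bb["y1"] - bb["y0"])
      sdx <- if (model$jitter == "absolute") model$center_jitter_sd
             else model$center_jitter_frac * bw
      sdy <- if (model$jitter == "absolute") model$center_jitter_sd
             else model$center_jitter_frac * bh
      ctr <- box_center(bb) + stats::rnorm(2, 0, c(sdx, sdy))
      s <- exp(stats::rnorm(1, 0, model$scale_noise_sd))
      x0 <- round(ctr[1] - s * bw / 2); x1 <- round(ctr[1] + s * bw / 2)
      y0 <- round(ctr[2] - s * bh / 2); y1 <- round(ctr[2] + s * bh / 2)
      x0 <- max(0, min(x0, w - 1)); y0 <- max(0, min(y0, h - 1))
      x1 <- min(w, max(x1, x0 + 1)); y1 <- min(h, max(y1, y0 + 1))
      pb <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
      inter <- region_box_intersection_area(ref$mask[[1]], pb)
      iou <- inter / (ref$area_px + box_area(pb) - inter)
      conf <- min(1, max(0, iou + stats::rnorm(1, 0, model$confidence_sd)))
      k <- k + 1L
      preds[[length(preds) + 1L]] <- tibble::tibble(
        pred_id = sprintf("%s_p%02d", iid, k), image_id = iid,
        x0 = x0, y0 = y0, x1 = x1, y1 = y1, confidence = conf
      )
    }
    n_fp <- stats::rpois(1, model$fp_per_image)
    for (f in seq_len(n_fp)) {
      area <- stats::rlnorm(1, log(8000 * (w * h) / (1920 * 1080)), 0.7)
      q <- exp(stats::rnorm(1, 0, 0.2))
      fw <- max(4, min(round(sqrt(area * q)), w - 2))
      fh <- max(4, min(round(sqrt(area / q)), h - 2))
      x0 <- floor(stats::runif(1, 0, w - fw)); y0 <- floor(stats::runif(1, 0, h - fh))
      k <- k + 1L
      preds[[length(preds) + 1L]] <- tibble::tibble(
        pred_id = sprintf("%s_p%02d", iid, k), image_id = iid,
        x0 = x0, y0 = y0, x1 = x0 + fw, y1 = y0 + fh,
        confidence = stats::rbeta(1, model$fp_conf_shape[1], model$fp_conf_shape[2])
      )
    }
  }
  pv_dataset(ds$images, if (nrow(ds$references)) ds$references else NULL,
             if (length(preds)) dplyr::bind_rows(preds) else NULL, ds$ratings)
}

#' Simulate clinician usefulness ratings
#'
#' Each prediction is rated `"useful"` iff it hits any reference on its
#' image under the model's generating criterion, then flipped with
#' probability `label_noise`. Raters `r1`-`r3` are assigned round-robin.
#' Deterministic given `seed`.
#'
#' @param ds a [pv_dataset()] with predictions.
#' @param model a [rating_model()].
#' @param seed integer seed.
#' @return `ds` with ratings attached.
#' @export
simulate_ratings <- function(ds, model = rating_model(), seed = 1L) {
  stopifnot(inherits(model, "pv_rating_model"))
  if (!nrow(ds$predictions)) {
    rlang::abort("simulate_ratings requires predictions", class = "polypval_usage_error")
  }
  set.seed(seed)
  ps <- pair_scores(ds, model$generating_criterion)
  hit_preds <- unique(ps$pred_id[ps$hit])
  pr <- ds$predictions
  useful <- pr$pred_id %in% hit_preds
  flip <- stats::runif(nrow(pr)) < model$label_noise
  useful <- xor(useful, flip)
  ratings <- tibble::tibble(
    pred_id = pr$pred_id,
    rating = ifelse(useful, "useful", "not_useful"),
    rater_id = paste0("r", (seq_len(nrow(pr)) - 1L) %% 3L + 1L)
  )
  pv_dataset(ds$images, if (nrow(ds$references)) ds$references else NULL,
             pr, ratings)
}

#' Generate a complete synthetic study
#'
#' References, predictions and (when the spec carries a rating model)
#' ratings, from one seed: references use `spec$seed`, predictions
#' `spec$seed + 1`, ratings `spec$seed + 2`.
#'
#' @param spec a [study_spec()].
#' @return a [pv_dataset()].
#' @export
generate_study <- function(spec) {
  ds <- generate_references(spec)
  ds <- generate_predictions(ds, spec$perturbation, seed = spec$seed + 1L)
  if (!is.null(spec$rating) && nrow(ds$predictions)) {
    ds <- simulate_ratings(ds, spec$rating, seed = spec$seed + 2L)
  }
  ds
}
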