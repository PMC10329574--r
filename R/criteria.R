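#' Localization criteria
#'
#' A localization criterion decides whether a predicted box spatially
#' corresponds to a reference polyp. Supported kinds:
#'
#' * overlap-based — `"box_iou"` (predicted box vs the reference's bounding
#'   box, closed form), `"mask_iou"` (rasterized predicted box vs the
#'   segmentation mask) and `"hull_iou"` (vs the mask's convex hull), each
#'   with an IoU cutoff `threshold` in `[0, 1]`. A pair is a hit when
#'   `score >= threshold` for `threshold > 0`, and `score > 0` when
#'   `threshold == 0` (so "Mask IoU > 0" is expressed as threshold 0).
#' * point-based — `"point_in_box"`, `"point_in_mask"`, `"point_in_hull"`:
#'   hit iff the center point of the predicted box falls on a foreground
#'   pixel of the respective reference region; `threshold` is ignored.
#' * `"center_distance"` — hit iff the Euclidean distance between the
#'   predicted box center and the reference center is at most `threshold`
#'   (pixels). `threshold = "equiv_radius"` uses the per-reference
#'   equivalent radius `sqrt(area_px / pi)`. The reference center is the
#'   mask centroid by default (`ref_center = "centroid"`); the bounding-box
#'   center is available via `ref_center = "box_center"`.
#'
#' @param kind criterion kind, see above.
#' @param threshold IoU cutoff, distance bound in pixels, or
#'   `"equiv_radius"`; ignored for point kinds.
#' @param ref_center reference center definition for `center_distance`.
#' @return a `pv_criterion`.
#' @examples
#' criterion("box_iou", 0.5)
#' criterion("mask_iou", 0)          # "Mask IoU > 0"
#' criterion("point_in_mask")
#' criterion("center_distance", "equiv_radius")
#' @export
criterion <- function(kind = c("box_iou", "mask_iou", "hull_iou", "point_in_box",
                               "point_in_mask", "point_in_hull", "center_distance"),
                      threshold = NULL,
                      ref_center = c("centroid", "box_center")) {
  kind <- match.arg(kind)
  ref_center <- match.arg(ref_center)
  if (kind %in% c("box_iou", "mask_iou", "hull_iou")) {
    if (is.null(threshold)) threshold <- 0.5
    if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
      rlang::abort("overlap threshold must be in [0, 1]", class = "polypval_usage_error")
    }
  } else if (kind == "center_distance") {
    if (is.null(threshold)) threshold <- "equiv_radius"
    if (is.numeric(threshold) && threshold < 0) {
      rlang::abort("distance bound tau must be >= 0", class = "polypval_usage_error")
    }
    if (is.character(threshold) && threshold != "equiv_radius") {
      rlang::abort("character threshold must be 'equiv_radius'", class = "polypval_usage_error")
    }
  } else {
    threshold <- NULL
  }
  structure(list(kind = kind, threshold = threshold, ref_center = ref_center),
            class = "pv_criterion")
}

is_overlap_kind <- function(kind) kind %in% c("box_iou", "mask_iou", "hull_iou")

criterion_label <- function(crit) {
  if (is_overlap_kind(crit$kind)) {
    op <- if (identical(crit$threshold, 0)) " > 0" else paste0(" >= ", format(crit$threshold))
    paste0(crit$kind, op)
  } else if (crit$kind == "center_distance") {
    paste0("center_distance <= ", if (is.character(crit$threshold)) "equiv_radius"
           else format(crit$threshold))
  } else {
    crit$kind
  }
}

#' @export
print.pv_criterion <- function(x, ...) {
  cat("<pv_criterion ", criterion_label(x), ">\n", sep = "")
  invisible(x)
}

#' @export
tidy.pv_criterion <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 threshold = if (is.numeric(x$threshold)) x$threshold else NA_real_,
                 label = criterion_label(x))
}

# Rasterize a (possibly non-integer) box by pixel-center inclusion: pixel c
# is covered iff c + 0.5 lies in [x0, x1). Identity for integer boxes.
raster_box <- function(b) {
  rb <- c(x0 = ceiling(b[["x0"]] - 0.5), y0 = ceiling(b[["y0"]] - 0.5),
          x1 = ceiling(b[["x1"]] - 0.5), y1 = ceiling(b[["y1"]] - 0.5))
  if (rb["x1"] <= rb["x0"]) rb["x1"] <- rb["x0"] + 1
  if (rb["y1"] <= rb["y0"]) rb["y1"] <- rb["y0"] + 1
  rb
}

# Hit rule for a vector of scores/distances under a criterion.
score_is_hit <- function(crit, score, dist = NULL, tau = NULL) {
  if (is_overlap_kind(crit$kind)) {
    if (crit$threshold > 0) score >= crit$threshold else score > 0
  } else if (crit$kind == "center_distance") {
    dist <= tau
  } else {
    score == 1
  }
}

# Per-reference derived geometry used in scoring; hull rasters are computed
# only when the criterion needs them.
ref_geometry <- function(ds, need_hull_raster = FALSE, need_hull_poly = FALSE) {
  rf <- ds$references
  geo <- purrr::map(seq_len(nrow(rf)), function(i) {
    m <- rf$mask[[i]]
    bb <- bounding_box(m)
    out <- list(bbox = bb, centroid = mask_centroid(m), area = rf$area_px[i],
                mask = m)
    if (need_hull_poly || need_hull_raster) out$hull_poly <- convex_hull_polygon(m)
    if (need_hull_raster) out$hull <- convex_hull_region(m)
    out
  })
  stats::setNames(geo, rf$ref_id)
}

#' Score all same-image (prediction, reference) pairs
#'
#' Computes the criterion's localization score for every prediction paired
#' with every reference on the same image, together with the center distance
#' (used for deterministic tie-breaking) and the hit decision.
#'
#' @param ds a [pv_dataset()].
#' @param crit a [criterion()].
#' @return a tibble with columns `pred_id`, `ref_id`, `image_id`, `score`,
#'   `center_dist`, `hit`. For `center_distance` criteria the score is the
#'   negative distance, so that a larger score is always better.
#' @export
pair_scores <- function(ds, crit) {
  stopifnot(inherits(crit, "pv_criterion"))
  pr <- ds$predictions
  rf <- ds$references
  pairs <- dplyr::inner_join(
    pr[, c("pred_id", "image_id", "x0", "y0", "x1", "y1")],
    rf[, c("ref_id", "image_id")],
    by = "image_id", relationship = "many-to-many"
  )
  geo <- ref_geometry(ds,
                      need_hull_raster = crit$kind == "hull_iou",
                      need_hull_poly = crit$kind == "point_in_hull")
  n <- nrow(pairs)
  score <- numeric(n); dist <- numeric(n); tau <- numeric(n)
  for (i in seq_len(n)) {
    g <- geo[[pairs$ref_id[i]]]
    pb <- c(x0 = pairs$x0[i], y0 = pairs$y0[i], x1 = pairs$x1[i], y1 = pairs$y1[i])
    pc <- box_center(pb)
    rc <- if (crit$ref_center == "centroid") g$centroid else box_center(g$bbox)
    dist[i] <- sqrt(sum((pc - rc)^2))
    tau[i] <- if (is.character(crit$threshold %||% "")) sqrt(g$area / pi)
              else crit$threshold %||% NA_real_
    score[i] <- switch(crit$kind,
      box_iou = box_iou(pb, g$bbox),
      mask_iou = {
        rb <- raster_box(pb)
        inter <- region_box_intersection_area(g$mask, rb)
        inter / (g$area + box_area(rb) - inter)
      },
      hull_iou = {
        rb <- raster_box(pb)
        inter <- region_box_intersection_area(g$hull, rb)
        inter / (region_area(g$hull) + box_area(rb) - inter)
      },
      point_in_box = as.numeric(floor(pc[1]) >= g$bbox["x0"] && floor(pc[1]) < g$bbox["x1"] &&
                                floor(pc[2]) >= g$bbox["y0"] && floor(pc[2]) < g$bbox["y1"]),
      point_in_mask = as.numeric(point_in_region(pc, g$mask)),
      point_in_hull = as.numeric(point_in_hull(pc, g$mask)),
      center_distance = -dist[i]
    )
  }
  pairs$score <- score
  pairs$center_dist <- dist
  pairs$tau <- tau
  pairs$hit <- score_is_hit(crit, score, dist, tau)
  out <- pairs[, c("pred_id", "ref_id", "image_id", "score", "center_dist", "tau", "hit")]
  attr(out, "criterion") <- crit
  out
}
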