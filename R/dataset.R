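#' Multi-center polyp detection dataset
#'
#' A `pv_dataset` bundles four tibbles sharing identifier columns:
#'
#' * `images`: one row per endoscopy frame — `image_id`, `width`, `height`,
#'   `center_id`, `patient_id`.
#' * `references`: one row per annotated polyp — `ref_id`, `image_id`,
#'   `mask` (list-column of [pv_region][region_from_matrix] binary masks),
#'   `polyp_type` (`"flat"` or `"protruded"`), `area_px`.
#' * `predictions`: one row per detector output — `pred_id`, `image_id`,
#'   half-open box corners `x0`, `y0`, `x1`, `y1`, and `confidence` in
#'   `[0, 1]`.
#' * `ratings` (optional): one row per clinician-rated prediction —
#'   `pred_id`, `rating` (`"useful"` / `"not_useful"`), `rater_id`.
#'
#' @param images,references,predictions,ratings tibbles as described above.
#' @param validate run [validate_dataset()] (default `TRUE`).
#' @return a `pv_dataset`.
#' @export
pv_dataset <- function(images, references = NULL, predictions = NULL,
                       ratings = NULL, validate = TRUE) {
  images <- tibble::as_tibble(images)
  references <- if (is.null(references)) empty_references() else tibble::as_tibble(references)
  predictions <- if (is.null(predictions)) empty_predictions() else tibble::as_tibble(predictions)
  if (!is.null(ratings)) ratings <- tibble::as_tibble(ratings)
  ds <- structure(
    list(images = images, references = references,
         predictions = predictions, ratings = ratings),
    class = "pv_dataset"
  )
  if (validate) validate_dataset(ds)
  ds
}

empty_references <- function() {
  tibble::tibble(ref_id = character(0), image_id = character(0),
                 mask = list(), polyp_type = character(0), area_px = integer(0))
}

empty_predictions <- function() {
  tibble::tibble(pred_id = character(0), image_id = character(0),
                 x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                 y1 = numeric(0), confidence = numeric(0))
}

abort_integrity <- function(msg) {
  rlang::abort(msg, class = "polypval_integrity_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "polypval_validation_error")
}

#' Validate a dataset's invariants
#'
#' Checks identifier uniqueness, referential integrity (every reference,
#' prediction and rating resolves to an existing image / prediction),
#' positive image and box extents, confidences in `[0, 1]`, non-empty masks
#' inside the canvas, consistent `area_px`, and at most one rating per
#' prediction.
#'
#' @param ds a `pv_dataset`.
#' @return `ds`, invisibly; aborts with a classed error otherwise.
#' @export
validate_dataset <- function(ds) {
  im <- ds$images
  if (anyDuplicated(im$image_id)) abort_validation("duplicate image_id in images")
  if (any(im$width < 1 | im$height < 1)) abort_validation("image width/height must be >= 1")
  rf <- ds$references
  if (nrow(rf)) {
    if (anyDuplicated(rf$ref_id)) abort_validation("duplicate ref_id in references")
    bad <- setdiff(rf$image_id, im$image_id)
    if (length(bad)) abort_integrity(paste0("reference cites unknown image_id: ", bad[1]))
    if (!all(rf$polyp_type %in% c("flat", "protruded"))) {
      abort_validation("polyp_type must be 'flat' or 'protruded'")
    }
    dims <- stats::setNames(split(cbind(im$width, im$height), seq_len(nrow(im))), im$image_id)
    for (i in seq_len(nrow(rf))) {
      m <- rf$mask[[i]]
      if (!is_region(m) || !length(m$rows)) {
        abort_validation(paste0("empty mask for ref_id ", rf$ref_id[i]))
      }
      wh <- dims[[rf$image_id[i]]]
      if (min(m$xs) < 0 || min(m$rows) < 0 || max(m$xe) > wh[1] || max(m$rows) >= wh[2]) {
        abort_validation(paste0("mask outside canvas for ref_id ", rf$ref_id[i]))
      }
      if (rf$area_px[i] != region_area(m)) {
        abort_validation(paste0("area_px inconsistent with mask for ref_id ", rf$ref_id[i]))
      }
    }
  }
  pr <- ds$predictions
  if (nrow(pr)) {
    if (anyDuplicated(pr$pred_id)) abort_validation("duplicate pred_id in predictions")
    bad <- setdiff(pr$image_id, im$image_id)
    if (length(bad)) abort_integrity(paste0("prediction cites unknown image_id: ", bad[1]))
    if (any(pr$x1 <= pr$x0 | pr$y1 <= pr$y0)) {
      abort_validation("prediction boxes must have positive width and height")
    }
    if (any(pr$confidence < 0 | pr$confidence > 1)) {
      abort_validation("confidence must be in [0, 1]")
    }
    wh <- im[match(pr$image_id, im$image_id), c("width", "height")]
    if (any(pr$x0 >= wh$width | pr$y0 >= wh$height | pr$x1 <= 0 | pr$y1 <= 0)) {
      abort_validation("prediction box does not intersect the image canvas")
    }
  }
  rt <- ds$ratings
  if (!is.null(rt) && nrow(rt)) {
    if (anyDuplicated(rt$pred_id)) abort_validation("at most one rating per pred_id")
    bad <- setdiff(rt$pred_id, pr$pred_id)
    if (length(bad)) abort_integrity(paste0("rating cites unknown pred_id: ", bad[1]))
    if (!all(rt$rating %in% c("useful", "not_useful"))) {
      abort_validation("rating must be 'useful' or 'not_useful'")
    }
  }
  invisible(ds)
}

#' @export
print.pv_dataset <- function(x, ...) {
  cat(sprintf("<pv_dataset: %d images, %d references, %d predictions%s, %d centers>\n",
              nrow(x$images), nrow(x$references), nrow(x$predictions),
              if (is.null(x$ratings)) "" else sprintf(", %d ratings", nrow(x$ratings)),
              dplyr::n_distinct(x$images$center_id)))
  invisible(x)
}

#' Restrict a dataset to one center
#' @param ds a `pv_dataset`.
#' @param center_id center to keep.
#' @return a `pv_dataset` with images, references, predictions and ratings
#'   of that center only.
#' @export
filter_center <- function(ds, center_id) {
  if (!center_id %in% ds$images$center_id) {
    rlang::abort(paste0("unknown center_id: ", center_id), class = "polypval_usage_error")
  }
  keep <- ds$images$image_id[ds$images$center_id == center_id]
  rt <- ds$ratings
  pr <- dplyr::filter(ds$predictions, .data$image_id %in% keep)
  if (!is.null(rt)) rt <- dplyr::filter(rt, .data$pred_id %in% pr$pred_id)
  pv_dataset(
    images = dplyr::filter(ds$images, .data$image_id %in% keep),
    references = dplyr::filter(ds$references, .data$image_id %in% keep),
    predictions = pr, ratings = rt, validate = FALSE
  )
}

#' Polyp prevalence
#'
#' Fraction of images (optionally restricted to one center) containing at
#' least one reference polyp.
#'
#' @param ds a `pv_dataset`.
#' @param center_id optional center to restrict to.
#' @return a single number in `[0, 1]`.
#' @export
prevalence <- function(ds, center_id = NULL) {
  im <- ds$images
  if (!is.null(center_id)) {
    if (!center_id %in% im$center_id) {
      rlang::abort(paste0("unknown center_id: ", center_id), class = "polypval_usage_error")
    }
    im <- dplyr::filter(im, .data$center_id == !!center_id)
  }
  if (!nrow(im)) {
    rlang::abort("prevalence undefined: no images in scope", class = "polypval_undefined_error")
  }
  mean(im$image_id %in% ds$references$image_id)
}

#' Per-center dataset summary
#'
#' One row per center with frame count, reference/prediction counts and
#' prevalence, plus a pooled `"all"` row.
#'
#' @param x a `pv_dataset`.
#' @param ... unused.
#' @return a tibble.
#' @export
glance.pv_dataset <- function(x, ...) {
  per <- x$images |>
    dplyr::left_join(
      dplyr::count(x$references, .data$image_id, name = "n_ref"),
      by = "image_id"
    ) |>
    dplyr::mutate(n_ref = dplyr::coalesce(.data$n_ref, 0L)) |>
    dplyr::group_by(.data$center_id) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      n_references = sum(.data$n_ref),
      prevalence = mean(.data$n_ref > 0),
      .groups = "drop"
    )
  preds <- x$predictions |>
    dplyr::left_join(x$images[, c("image_id", "center_id")], by = "image_id") |>
    dplyr::count(.data$center_id, name = "n_predictions")
  per <- dplyr::left_join(per, preds, by = "center_id") |>
    dplyr::mutate(n_predictions = dplyr::coalesce(.data$n_predictions, 0L))
  all_row <- tibble::tibble(
    center_id = "all",
    n_images = nrow(x$images),
    n_references = nrow(x$references),
    prevalence = if (nrow(x$images)) prevalence(x) else NA_real_,
    n_predictions = nrow(x$predictions)
  )
  dplyr::bind_rows(per, all_row)
}
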