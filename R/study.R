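#' Polyp size classes
#'
#' Size classes are defined in pixels at a 1920x1080 reference resolution:
#' polyps smaller than `100^2` pixels are small, polyps larger than `200^2`
#' pixels are large, and the rest are medium. For images at other
#' resolutions both area thresholds are scaled by
#' `(width * height) / (1920 * 1080)`.
#'
#' @param small_max_area small/medium boundary at reference resolution.
#' @param large_min_area medium/large boundary at reference resolution.
#' @param reference_resolution `c(width, height)` the thresholds refer to.
#' @return a `pv_size_rule`.
#' @export
size_rule <- function(small_max_area = 100^2, large_min_area = 200^2,
                      reference_resolution = c(1920, 1080)) {
  stopifnot(small_max_area < large_min_area)
  structure(list(small_max_area = small_max_area, large_min_area = large_min_area,
                 reference_resolution = reference_resolution),
            class = "pv_size_rule")
}

#' @describeIn size_rule classify areas; boundary areas (exactly `100^2` or
#'   `200^2` scaled) are medium. Vectorized over `area_px`.
#' @param area_px foreground pixel counts.
#' @param width,height resolution of the images the areas were measured on.
#' @param rule a [size_rule()].
#' @return factor with levels small, medium, large.
#' @export
size_class <- function(area_px, width, height, rule = size_rule()) {
  scale <- (width * height) / prod(rule$reference_resolution)
  cls <- ifelse(area_px < rule$small_max_area * scale, "small",
                ifelse(area_px > rule$large_min_area * scale, "large", "medium"))
  factor(cls, levels = c("small", "medium", "large"))
}

reference_sizes <- function(ds, rule = size_rule()) {
  rf <- dplyr::left_join(ds$references[, c("ref_id", "image_id", "area_px", "polyp_type")],
                         ds$images[, c("image_id", "width", "height", "center_id",
                                       "patient_id")],
                         by = "image_id")
  rf$size_class <- size_class(rf$area_px, rf$width, rf$height, rule)
  rf
}

scope_datasets <- function(ds) {
  centers <- sort(unique(ds$images$center_id))
  scopes <- c(stats::setNames(purrr::map(centers, ~ filter_center(ds, .x)), centers),
              list(all = ds))
  scopes
}

#' Per-center metric panel
#'
#' Computes the [metric_panel()] for each center and for the pooled dataset
#' (`center_id = "all"`). Centers with no references get `NA` metric values
#' rather than zeros.
#'
#' @inheritParams confusion_counts
#' @return a tibble `center_id`, `metric`, `value`, `criterion`,
#'   `confidence_cutoff` (class `pv_center_panel`).
#' @export
per_center_panel <- function(ds, crit = criterion("box_iou", 0.5),
                             confidence_cutoff = 0.5) {
  out <- purrr::imap_dfr(scope_datasets(ds), function(sub, cid) {
    panel <- if (nrow(sub$references)) {
      metric_panel(sub, crit, confidence_cutoff)
    } else {
      tibble::tibble(metric = c("sensitivity", "ppv", "f1", "f2"),
                     value = NA_real_, criterion = criterion_label(crit),
                     confidence_cutoff = confidence_cutoff)
    }
    dplyr::mutate(panel, center_id = cid, .before = 1)
  })
  class(out) <- c("pv_center_panel", class(out))
  out
}

#' Across-center spread of a per-center panel
#'
#' Mean, sample standard deviation (n - 1), minimum and maximum of each
#' metric across centers (the pooled `"all"` row is excluded).
#'
#' @param panel output of [per_center_panel()].
#' @return a tibble `metric`, `mean`, `sd`, `min`, `max`, `n_centers`.
#' @export
across_center_summary <- function(panel) {
  panel |>
    dplyr::filter(.data$center_id != "all", !is.na(.data$value)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value),
      min = min(.data$value), max = max(.data$value),
      n_centers = dplyr::n(), .groups = "drop"
    )
}

# AP restricted to one size class with COCO-style "ignore" semantics:
# predictions matched to out-of-class references are removed from the sweep
# (neither TP nor FP); unmatched predictions stay false positives.
ap_for_class <- function(ranked, class_ref_ids, n_class_refs) {
  if (n_class_refs == 0) return(NA_real_)
  keep <- is.na(ranked$ref_id) | ranked$ref_id %in% class_ref_ids
  r <- ranked[keep, , drop = FALSE]
  if (!nrow(r)) return(0)
  cv <- curve_from_ranked(r, n_class_refs)
  ap_101(cv$recall, cv$precision)
}

#' Size-stratified average precision
#'
#' AP at IoU threshold 0.5 and the range mean over 0.5:0.95, stratified by
#' center and polyp size class. References outside a size class are ignored
#' rather than counted against the detector: predictions matched to them are
#' dropped from that class's sweep. The `"all"` rows are pooled (micro)
#' computations over all centers, not means of the per-center values; use
#' [across_center_sd()] for the across-center spread.
#'
#' @param ds a [pv_dataset()].
#' @param kind overlap criterion kind (default `"box_iou"`).
#' @param rule a [size_rule()].
#' @return a tibble `center_id`, `size_class`, `n_ref`, `ap50`, `ap50_95`
#'   (class `pv_size_ap`); empty classes have `NA` AP cells.
#' @export
size_stratified_ap <- function(ds, kind = "box_iou", rule = size_rule()) {
  check_overlap_kind(kind)
  sizes_all <- reference_sizes(ds, rule)
  grid <- seq(0.5, 0.95, by = 0.05)
  out <- purrr::imap_dfr(scope_datasets(ds), function(sub, cid) {
    sizes <- sizes_all[sizes_all$ref_id %in% sub$references$ref_id, ]
    engine <- build_engine(sub, criterion(kind, 0.5))
    ranked <- purrr::map(grid, ~ run_greedy(engine, threshold = .x))
    names(ranked) <- format(grid)
    purrr::map_dfr(c("small", "medium", "large"), function(cl) {
      ids <- sizes$ref_id[sizes$size_class == cl]
      aps <- vapply(ranked, ap_for_class, numeric(1),
                    class_ref_ids = ids, n_class_refs = length(ids))
      tibble::tibble(center_id = cid, size_class = cl, n_ref = length(ids),
                     ap50 = aps[["0.50"]],
                     ap50_95 = if (length(ids)) mean(aps) else NA_real_)
    })
  })
  out$size_class <- factor(out$size_class, levels = c("small", "medium", "large"))
  class(out) <- c("pv_size_ap", class(out))
  out
}

#' Across-center sample standard deviation of stratified AP
#'
#' @param strat output of [size_stratified_ap()] (or any tibble with
#'   `center_id`, `size_class` and value columns).
#' @param value column to summarise (default `ap50`).
#' @return a tibble `size_class`, `mean`, `sd`, `n_centers`; `sd` uses the
#'   n - 1 denominator and is 0 iff all centers agree.
#' @export
across_center_sd <- function(strat, value = "ap50") {
  strat |>
    dplyr::filter(.data$center_id != "all", !is.na(.data[[value]])) |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarise(
      mean = mean(.data[[value]]), sd = stats::sd(.data[[value]]),
      n_centers = dplyr::n(), .groups = "drop"
    )
}

#' Default criterion families for comparison and agreement reports
#'
#' Position-focused: point in box / mask / hull and center distance with the
#' per-reference equivalent radius as bound. Outline-focused: box, mask and
#' hull IoU at 0.5 plus the permissive "mask IoU > 0".
#'
#' @return a named list of [criterion()] objects.
#' @export
default_position_criteria <- function() {
  list(
    point_in_box = criterion("point_in_box"),
    point_in_mask = criterion("point_in_mask"),
    point_in_hull = criterion("point_in_hull"),
    center_distance = criterion("center_distance", "equiv_radius")
  )
}

#' @rdname default_position_criteria
#' @export
default_outline_criteria <- function() {
  list(
    box_iou_0.5 = criterion("box_iou", 0.5),
    mask_iou_0.5 = criterion("mask_iou", 0.5),
    hull_iou_0.5 = criterion("hull_iou", 0.5),
    mask_iou_gt0 = criterion("mask_iou", 0)
  )
}

#' Compare counting metrics and AP across localization criteria
#'
#' One row per criterion with Sensitivity, PPV, F1, F2 (at the confidence
#' cutoff) and AP over the pooled dataset.
#'
#' @param ds a [pv_dataset()].
#' @param criteria list of [criterion()] objects (named or not).
#' @param confidence_cutoff confidence cutoff for the counting metrics.
#' @return a tibble `criterion`, `sensitivity`, `ppv`, `f1`, `f2`, `ap`.
#' @export
criterion_comparison <- function(ds, criteria = c(default_outline_criteria()["box_iou_0.5"],
                                                  default_position_criteria()[1:3]),
                                 confidence_cutoff = 0.5) {
  if (!length(criteria)) rlang::abort("need at least one criterion",
                                      class = "polypval_usage_error")
  purrr::map_dfr(criteria, function(crit) {
    cc <- confusion_counts(ds, crit, confidence_cutoff)
    sens <- if (cc$n_ref > 0) sensitivity(cc) else NA_real_
    prec <- if (cc$n_pred > 0) ppv(cc) else NA_real_
    tibble::tibble(
      criterion = criterion_label(crit),
      sensitivity = sens, ppv = prec,
      f1 = if (!is.na(sens) && !is.na(prec)) f_beta(prec, sens, 1) else NA_real_,
      f2 = if (!is.na(sens) && !is.na(prec)) f_beta(prec, sens, 2) else NA_real_,
      ap = average_precision(ds, crit)
    )
  })
}

#' Agreement of localization criteria with clinician usefulness ratings
#'
#' A rated prediction "meets" a criterion when its pair with any reference
#' on its image is a hit (no assignment is involved; a prediction on an
#' image without references can never be a hit). For each criterion the
#' report gives the fraction of "useful"-rated predictions meeting it and
#' the fraction of "not useful"-rated predictions not meeting it; a
#' fraction whose rating class is empty is `NA`.
#'
#' @param ds a [pv_dataset()] with ratings.
#' @param criteria list of [criterion()] objects.
#' @return a tibble `criterion`, `frac_useful_accepted`,
#'   `frac_not_useful_rejected`, `n_useful`, `n_not_useful`
#'   (class `pv_agreement`).
#' @export
agreement_fractions <- function(ds, criteria = c(default_position_criteria(),
                                                 default_outline_criteria())) {
  if (is.null(ds$ratings) || !nrow(ds$ratings)) {
    rlang::abort("agreement analysis requires ratings", class = "polypval_usage_error")
  }
  rt <- ds$ratings
  out <- purrr::map_dfr(criteria, function(crit) {
    ps <- pair_scores(ds, crit)
    hit_preds <- unique(ps$pred_id[ps$hit])
    hit <- rt$pred_id %in% hit_preds
    useful <- rt$rating == "useful"
    tibble::tibble(
      criterion = criterion_label(crit),
      frac_useful_accepted = if (any(useful)) mean(hit[useful]) else NA_real_,
      frac_not_useful_rejected = if (any(!useful)) mean(!hit[!useful]) else NA_real_,
      n_useful = sum(useful), n_not_useful = sum(!useful)
    )
  })
  class(out) <- c("pv_agreement", class(out))
  out
}

#' Per-object IoU table for external hierarchical modelling
#'
#' One row per reference object with its center, patient and image
#' identifiers, polyp type, size class, and the localization score of its
#' matched prediction at the given criterion and cutoff (`NA` when the
#' object was missed). The center/patient/image columns are the grouping
#' hierarchy a mixed-effects model of IoU on size and type would use; the
#' fit itself is out of scope here and can be run with any modelling
#' package.
#'
#' @inheritParams confusion_counts
#' @param rule a [size_rule()].
#' @return a tibble.
#' @export
object_iou_table <- function(ds, crit = criterion("box_iou", 0.5),
                             confidence_cutoff = 0.5, rule = size_rule()) {
  ranked <- run_greedy(build_engine(ds, crit), confidence_cutoff = confidence_cutoff)
  ps <- pair_scores(ds, crit)
  matched <- ranked[!is.na(ranked$ref_id), c("pred_id", "ref_id")]
  matched <- dplyr::left_join(matched, ps[, c("pred_id", "ref_id", "score")],
                              by = c("pred_id", "ref_id"))
  reference_sizes(ds, rule) |>
    dplyr::left_join(matched[, c("ref_id", "score")], by = "ref_id") |>
    dplyr::select("ref_id", "center_id", "patient_id", "image_id",
                  "polyp_type", "size_class", "area_px", iou = "score")
}
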