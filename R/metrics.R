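#' Object-level counting metrics
#'
#' @param counts a one-row tibble from [confusion_counts()] (or anything
#'   with `tp`, `fp`, `fn` columns).
#' @return a single number.
#' @name counting_metrics
NULL

#' @describeIn counting_metrics `tp / (tp + fn)`; errors when no reference
#'   objects are in scope.
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    rlang::abort("sensitivity undefined: no reference objects in scope",
                 class = "polypval_undefined_error")
  }
  counts$tp / (counts$tp + counts$fn)
}

#' @describeIn counting_metrics positive predictive value `tp / (tp + fp)`;
#'   errors when no predictions survive the cutoff (reported as absent by
#'   the report builders, never silently 0).
#' @export
ppv <- function(counts) {
  if (counts$tp + counts$fp == 0) {
    rlang::abort("PPV undefined: no predictions in scope",
                 class = "polypval_undefined_error")
  }
  counts$tp / (counts$tp + counts$fp)
}

#' F-beta score
#'
#' `(1 + beta^2) * p * r / (beta^2 * p + r)`, with the convention that the
#' score is 0 when `p + r = 0`. `beta = 2` weights sensitivity (recall)
#' higher than precision.
#'
#' @param p precision / PPV in `[0, 1]`.
#' @param r recall / sensitivity in `[0, 1]`.
#' @param beta positive weight.
#' @return F-beta in `[0, 1]`.
#' @export
f_beta <- function(p, r, beta = 1) {
  stopifnot(beta > 0, p >= 0, p <= 1, r >= 0, r <= 1)
  if (p + r == 0) return(0)
  (1 + beta^2) * p * r / (beta^2 * p + r)
}

# recall/precision sequence from a ranked match table
curve_from_ranked <- function(ranked, n_ref) {
  tp_cum <- cumsum(!is.na(ranked$ref_id))
  k <- seq_len(nrow(ranked))
  tibble::tibble(
    rank = k, pred_id = ranked$pred_id, confidence = ranked$confidence,
    outcome = ifelse(is.na(ranked$ref_id), "FP", "TP"),
    tp = tp_cum, fp = k - tp_cum,
    recall = tp_cum / n_ref, precision = tp_cum / k
  )
}

# 101-point interpolated AP from a (recall, precision) point set
ap_101 <- function(recall, precision) {
  if (!length(recall)) return(0)
  grid <- seq(0, 1, by = 0.01)
  mean(vapply(grid, function(r) {
    ok <- recall >= r - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1)))
}

#' Precision-recall curve over the confidence sweep
#'
#' Predictions are pooled over all images of the dataset, ranked by
#' descending confidence (ties by `pred_id`), and matched incrementally;
#' each rank emits cumulative tp/fp and the resulting (recall, precision)
#' point. The matching state at rank k equals [match_image()] applied to the
#' top-k predictions.
#'
#' @param ds a [pv_dataset()] with at least one reference.
#' @param crit a [criterion()].
#' @return a `pv_pr_curve` tibble (`rank`, `pred_id`, `confidence`,
#'   `outcome`, `tp`, `fp`, `recall`, `precision`) with the reference count
#'   in `attr(, "n_ref")`.
#' @export
pr_curve <- function(ds, crit) {
  if (!nrow(ds$references)) {
    rlang::abort("PR curve undefined: dataset has no reference objects",
                 class = "polypval_undefined_error")
  }
  ranked <- run_greedy(build_engine(ds, crit))
  out <- curve_from_ranked(ranked, nrow(ds$references))
  attr(out, "n_ref") <- nrow(ds$references)
  attr(out, "criterion") <- crit
  class(out) <- c("pv_pr_curve", class(out))
  out
}

#' @export
tidy.pv_pr_curve <- function(x, ...) {
  tibble::as_tibble(x)[, c("rank", "recall", "precision", "confidence", "outcome")]
}

#' @export
glance.pv_pr_curve <- function(x, ...) {
  tibble::tibble(
    n_ref = attr(x, "n_ref"), n_pred = nrow(x),
    final_recall = if (nrow(x)) x$recall[nrow(x)] else 0,
    ap = ap_101(x$recall, x$precision),
    criterion = criterion_label(attr(x, "criterion"))
  )
}

#' Average precision (101-point interpolation)
#'
#' `AP = mean over r in {0, 0.01, ..., 1} of max precision at recall >= r`
#' (0 when no curve point reaches the recall level), computed on the pooled
#' confidence sweep of [pr_curve()]. An all-point (area-under-PR) variant is
#' available via `interpolation = "all_points"` for sensitivity analysis;
#' the 101-point rule is always the default.
#'
#' @inheritParams pr_curve
#' @param interpolation `"101_point"` (default) or `"all_points"`.
#' @return AP in `[0, 1]`; 0 when there are no predictions.
#' @export
average_precision <- function(ds, crit, interpolation = c("101_point", "all_points")) {
  interpolation <- match.arg(interpolation)
  curve <- pr_curve(ds, crit)
  if (!nrow(curve)) return(0)
  if (interpolation == "101_point") {
    ap_101(curve$recall, curve$precision)
  } else {
    # area under the interpolated precision envelope in recall
    env <- rev(cummax(rev(curve$precision)))
    r <- c(0, curve$recall)
    sum(diff(r) * env)
  }
}

ap_from_engine <- function(engine, threshold) {
  if (engine$n_ref == 0) {
    rlang::abort("AP undefined: no reference objects", class = "polypval_undefined_error")
  }
  ranked <- run_greedy(engine, threshold = threshold)
  if (!nrow(ranked)) return(0)
  cv <- curve_from_ranked(ranked, engine$n_ref)
  ap_101(cv$recall, cv$precision)
}

check_overlap_kind <- function(kind) {
  if (!is_overlap_kind(kind)) {
    rlang::abort("threshold sweeps require an overlap kind (box_iou, mask_iou, hull_iou)",
                 class = "polypval_usage_error")
  }
  kind
}

#' AP as a function of the IoU threshold
#'
#' Computes the 101-point AP for one overlap-based criterion kind at every
#' threshold of the grid. Pair scores are computed once; only the hit rule
#' changes along the grid.
#'
#' @param ds a [pv_dataset()].
#' @param kind `"box_iou"`, `"mask_iou"` or `"hull_iou"`.
#' @param grid threshold grid (default `seq(0.05, 0.95, by = 0.05)`).
#' @return a tibble `threshold`, `ap` (class `pv_ap_sweep`).
#' @export
ap_threshold_sweep <- function(ds, kind = "box_iou", grid = seq(0.05, 0.95, by = 0.05)) {
  check_overlap_kind(kind)
  if (!length(grid)) rlang::abort("empty threshold grid", class = "polypval_usage_error")
  engine <- build_engine(ds, criterion(kind, 0.5))
  out <- tibble::tibble(
    threshold = grid,
    ap = vapply(grid, function(t) ap_from_engine(engine, t), numeric(1))
  )
  attr(out, "kind") <- kind
  class(out) <- c("pv_ap_sweep", class(out))
  out
}

#' Mean AP over a threshold range
#'
#' Arithmetic mean of the per-threshold APs on `lo, lo + step, ..., hi`
#' (inclusive), e.g. `ap_range_mean(ds, "box_iou", 0.5, 0.95)` for the
#' COCO-style AP at 0.5:0.95. A degenerate range `lo == hi` equals the
#' single-threshold AP.
#'
#' @inheritParams ap_threshold_sweep
#' @param lo,hi range ends in `[0, 1]`, `lo <= hi`.
#' @param step grid step (default 0.05).
#' @return mean AP.
#' @export
ap_range_mean <- function(ds, kind = "box_iou", lo = 0.5, hi = 0.95, step = 0.05) {
  check_overlap_kind(kind)
  if (lo > hi || lo < 0 || hi > 1) {
    rlang::abort("need 0 <= lo <= hi <= 1", class = "polypval_usage_error")
  }
  grid <- seq(lo, hi, by = step)
  mean(ap_threshold_sweep(ds, kind, grid)$ap)
}

#' Full metric panel for one evaluation scope
#'
#' Sensitivity, PPV, F1 and F2 at the given criterion and confidence
#' cutoff, plus AP at thresholds 0.5 and 0.75 and the range mean over
#' 0.5:0.95 for the criterion's kind (overlap kinds only; for point-based
#' and distance criteria a single AP under that criterion is reported).
#' Metrics that are undefined in scope (e.g. PPV with zero kept
#' predictions) are reported as `NA`, never as 0.
#'
#' @inheritParams confusion_counts
#' @return a tidy tibble `metric`, `value`, `criterion`,
#'   `confidence_cutoff`.
#' @export
metric_panel <- function(ds, crit, confidence_cutoff = 0.5) {
  cc <- confusion_counts(ds, crit, confidence_cutoff)
  sens <- if (cc$n_ref > 0) sensitivity(cc) else NA_real_
  prec <- if (cc$n_pred > 0) ppv(cc) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec)) f_beta(prec, sens, 1) else NA_real_
  f2 <- if (!is.na(sens) && !is.na(prec)) f_beta(prec, sens, 2) else NA_real_
  vals <- c(sensitivity = sens, ppv = prec, f1 = f1, f2 = f2)
  if (is_overlap_kind(crit$kind)) {
    engine <- build_engine(ds, crit)
    vals <- c(vals,
              "ap@0.5" = ap_from_engine(engine, 0.5),
              "ap@0.75" = ap_from_engine(engine, 0.75),
              "ap@0.5:0.95" = mean(vapply(seq(0.5, 0.95, by = 0.05),
                                          function(t) ap_from_engine(engine, t),
                                          numeric(1))))
  } else {
    vals <- c(vals, ap = average_precision(ds, crit))
  }
  tibble::tibble(
    metric = names(vals), value = unname(vals),
    criterion = criterion_label(crit), confidence_cutoff = confidence_cutoff
  )
}
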