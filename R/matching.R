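#' Greedy one-to-one assignment and confusion counts
#'
#' Predictions are processed in descending confidence (ties broken by
#' `pred_id`); each takes the still-unmatched reference with the best
#' localization score among its hits (score ties broken by smaller center
#' distance, then by `ref_id`). This is the COCO-style greedy convention;
#' because matching follows the global confidence ranking, matching the
#' top-k predictions of a confidence sweep equals matching them per image
#' in isolation.
#'
#' @name matching
NULL

# Precompute the threshold-independent matching engine: ranked predictions
# and, per prediction, its candidate references in priority order.
build_engine <- function(ds, crit) {
  ps <- pair_scores(ds, crit)
  pr <- ds$predictions
  ord <- order(-pr$confidence, pr$pred_id)
  preds <- pr[ord, c("pred_id", "image_id", "confidence")]
  cand <- split(ps[order(-ps$score, ps$center_dist, ps$ref_id),
                   c("pred_id", "ref_id", "score", "center_dist", "tau")],
                factor(ps$pred_id[order(-ps$score, ps$center_dist, ps$ref_id)],
                       levels = unique(preds$pred_id)))
  list(preds = preds, cand = cand, n_ref = nrow(ds$references),
       ref_ids = ds$references$ref_id, crit = crit)
}

# Run the greedy sweep at a given overlap threshold (NULL = the criterion's
# own) and confidence cutoff. Returns the ranked prediction table with the
# matched ref_id (NA for false positives).
run_greedy <- function(engine, threshold = NULL, confidence_cutoff = 0) {
  crit <- engine$crit
  if (!is.null(threshold)) crit$threshold <- threshold
  preds <- engine$preds[engine$preds$confidence >= confidence_cutoff, , drop = FALSE]
  matched <- new.env(parent = emptyenv())
  ref_id <- rep(NA_character_, nrow(preds))
  for (i in seq_len(nrow(preds))) {
    cd <- engine$cand[[preds$pred_id[i]]]
    if (is.null(cd) || !nrow(cd)) next
    hits <- score_is_hit(crit, cd$score, -cd$score, cd$tau)
    if (crit$kind == "center_distance") hits <- (-cd$score) <= cd$tau
    for (j in which(hits)) {
      rid <- cd$ref_id[j]
      if (is.null(matched[[rid]])) {
        matched[[rid]] <- TRUE
        ref_id[i] <- rid
        break
      }
    }
  }
  preds$ref_id <- ref_id
  preds
}

#' Match the predictions of one image to its references
#'
#' @param ds a [pv_dataset()].
#' @param crit a [criterion()].
#' @param image_id image to match; `NULL` (default) matches every image.
#' @return a list with `matches` (tibble `pred_id`, `ref_id`, `confidence`),
#'   `unmatched_preds` and `unmatched_refs` (character vectors).
#' @export
match_image <- function(ds, crit, image_id = NULL) {
  if (!is.null(image_id)) {
    if (!image_id %in% ds$images$image_id) {
      rlang::abort(paste0("unknown image_id: ", image_id), class = "polypval_usage_error")
    }
    keep_im <- image_id
  } else {
    keep_im <- ds$images$image_id
  }
  sub <- pv_dataset(
    ds$images[ds$images$image_id %in% keep_im, ],
    { r <- ds$references[ds$references$image_id %in% keep_im, ]; if (nrow(r)) r },
    { p <- ds$predictions[ds$predictions$image_id %in% keep_im, ]; if (nrow(p)) p },
    validate = FALSE
  )
  ranked <- run_greedy(build_engine(sub, crit))
  matches <- ranked[!is.na(ranked$ref_id), c("pred_id", "ref_id", "confidence")]
  list(
    matches = tibble::as_tibble(matches),
    unmatched_preds = ranked$pred_id[is.na(ranked$ref_id)],
    unmatched_refs = setdiff(sub$references$ref_id, matches$ref_id)
  )
}

#' Object-level confusion counts
#'
#' Predictions at or above the confidence cutoff are matched greedily per
#' image under the criterion; `tp` counts matched pairs, `fp` unmatched kept
#' predictions, and `fn` unmatched references. Always `tp + fn = `number of
#' references and `tp + fp = `number of kept predictions.
#'
#' @param ds a [pv_dataset()].
#' @param crit a [criterion()].
#' @param confidence_cutoff minimum confidence for a prediction to enter the
#'   counting; the default 0.5 is a reporting convention, not a recommendation,
#'   and is echoed in the output so it is always explicit.
#' @return a one-row tibble `tp`, `fp`, `fn`, `n_ref`, `n_pred`,
#'   `confidence_cutoff`, `criterion`.
#' @export
confusion_counts <- function(ds, crit, confidence_cutoff = 0.5) {
  if (confidence_cutoff < 0 || confidence_cutoff > 1) {
    rlang::abort("confidence_cutoff must be in [0, 1]", class = "polypval_usage_error")
  }
  ranked <- run_greedy(build_engine(ds, crit), confidence_cutoff = confidence_cutoff)
  tp <- sum(!is.na(ranked$ref_id))
  tibble::tibble(
    tp = tp, fp = nrow(ranked) - tp, fn = nrow(ds$references) - tp,
    n_ref = nrow(ds$references), n_pred = nrow(ranked),
    confidence_cutoff = confidence_cutoff, criterion = criterion_label(crit)
  )
}
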