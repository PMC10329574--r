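#' Reading and writing datasets
#'
#' Two on-disk dialects are supported:
#'
#' * `"coco_json"` — a single JSON file in the COCO annotation dialect:
#'   `images` (with custom `center_id`, `patient_id`), `annotations` with a
#'   `segmentation` that is either a polygon (list of flat coordinate
#'   arrays) or an uncompressed column-major run-length encoding
#'   (`{"counts": [...], "size": [height, width]}`) plus a custom
#'   `polyp_type`, and optional `predictions` (COCO-results boxes
#'   `[x, y, width, height]` with `confidence`) and `ratings`.
#' * `"mask_png_dir"` — a directory with an `index.csv`
#'   (`image_id, center_id, patient_id, mask_path` and optionally
#'   `polyp_type`) plus one binary mask PNG per annotated image; image
#'   dimensions are taken from the PNG.
#'
#' On-disk boxes are `[x, y, width, height]` and are converted to half-open
#' corners on load. [write_dataset()] emits a canonical key-sorted
#' serialization that [read_dataset()] inverts exactly, so writing the same
#' dataset twice gives identical bytes.
#'
#' @name dataset_io
NULL

#' @rdname dataset_io
#' @param path file (`coco_json`) or directory (`mask_png_dir`).
#' @param dialect `"coco_json"` or `"mask_png_dir"`.
#' @return [read_dataset()]: a validated [pv_dataset()].
#' @export
read_dataset <- function(path, dialect = c("coco_json", "mask_png_dir")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("no such path: ", path), class = "polypval_io_error")
  }
  switch(dialect,
    coco_json = read_dataset_coco(path),
    mask_png_dir = read_dataset_pngdir(path)
  )
}

read_dataset_coco <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$images)) {
    rlang::abort("coco_json: missing 'images' array", class = "polypval_format_error")
  }
  images <- purrr::map_dfr(doc$images, function(im) {
    if (is.null(im$width) || is.null(im$height)) {
      rlang::abort(paste0("coco_json: image ", im$id %||% "?", " lacks width/height"),
                   class = "polypval_format_error")
    }
    tibble::tibble(
      image_id = as.character(im$id), width = as.integer(im$width),
      height = as.integer(im$height),
      center_id = as.character(im$center_id %||% "c1"),
      patient_id = as.character(im$patient_id %||% "unknown")
    )
  })
  dims <- images[, c("image_id", "width", "height")]
  references <- purrr::map_dfr(doc$annotations %||% list(), function(an) {
    iid <- as.character(an$image_id)
    d <- dims[dims$image_id == iid, ]
    if (!nrow(d)) abort_integrity(paste0("reference cites unknown image_id: ", iid))
    seg <- an$segmentation
    m <- decode_segmentation(seg, d$width, d$height, ref_id = as.character(an$id))
    tibble::tibble(
      ref_id = as.character(an$id), image_id = iid, mask = list(m),
      polyp_type = as.character(an$polyp_type %||% "protruded"),
      area_px = region_area(m)
    )
  })
  predictions <- purrr::map_dfr(doc$predictions %||% list(), function(pd) {
    bb <- as.numeric(pd$bbox)
    tibble::tibble(
      pred_id = as.character(pd$id), image_id = as.character(pd$image_id),
      x0 = bb[1], y0 = bb[2], x1 = bb[1] + bb[3], y1 = bb[2] + bb[4],
      confidence = as.numeric(pd$confidence %||% pd$score)
    )
  })
  ratings <- if (!is.null(doc$ratings)) {
    purrr::map_dfr(doc$ratings, function(rt) {
      tibble::tibble(pred_id = as.character(rt$pred_id),
                     rating = as.character(rt$rating),
                     rater_id = as.character(rt$rater_id %||% "unknown"))
    })
  }
  pv_dataset(images,
             if (nrow(references)) references else NULL,
             if (nrow(predictions)) predictions else NULL,
             ratings)
}

decode_segmentation <- function(seg, width, height, ref_id = "?") {
  m <- if (is.list(seg) && !is.null(seg$counts)) {
    size <- as.integer(unlist(seg$size))
    if (!identical(size, c(height, width))) {
      rlang::abort(paste0("RLE size mismatch for ref_id ", ref_id),
                   class = "polypval_format_error")
    }
    region_from_rle(unlist(seg$counts), width, height)
  } else if (is.list(seg)) {
    polys <- purrr::map(seg, ~ region_from_polygon(as.numeric(unlist(.x)), width, height))
    purrr::reduce(polys, region_union)
  } else {
    rlang::abort(paste0("undecodable segmentation for ref_id ", ref_id),
                 class = "polypval_format_error")
  }
  if (!length(m$rows)) {
    abort_validation(paste0("empty mask for ref_id ", ref_id))
  }
  m
}

read_dataset_pngdir <- function(path) {
  idx_path <- file.path(path, "index.csv")
  if (!file.exists(idx_path)) {
    rlang::abort(paste0("mask_png_dir: missing ", idx_path), class = "polypval_format_error")
  }
  idx <- readr::read_csv(idx_path, show_col_types = FALSE)
  need <- c("image_id", "center_id", "patient_id", "mask_path")
  if (!all(need %in% names(idx))) {
    rlang::abort("mask_png_dir: index.csv must have columns image_id, center_id, patient_id, mask_path",
                 class = "polypval_format_error")
  }
  rows <- purrr::map(seq_len(nrow(idx)), function(i) {
    png_path <- file.path(path, idx$mask_path[i])
    if (!file.exists(png_path)) {
      rlang::abort(paste0("missing mask PNG: ", png_path), class = "polypval_io_error")
    }
    img <- png::readPNG(png_path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    m <- region_from_matrix(img > 0.5)
    list(
      image = tibble::tibble(image_id = as.character(idx$image_id[i]),
                             width = ncol(img), height = nrow(img),
                             center_id = as.character(idx$center_id[i]),
                             patient_id = as.character(idx$patient_id[i])),
      ref = if (length(m$rows)) {
        tibble::tibble(ref_id = paste0(idx$image_id[i], "_r1"),
                       image_id = as.character(idx$image_id[i]), mask = list(m),
                       polyp_type = as.character(idx$polyp_type[i] %||% "protruded"),
                       area_px = region_area(m))
      }
    )
  })
  refs <- purrr::map_dfr(rows, "ref")
  pv_dataset(purrr::map_dfr(rows, "image"), if (nrow(refs)) refs else NULL)
}

#' @rdname dataset_io
#' @param ds a [pv_dataset()].
#' @return [write_dataset()]: `path`, invisibly.
#' @export
write_dataset <- function(ds, path, dialect = c("coco_json", "mask_png_dir")) {
  dialect <- match.arg(dialect)
  validate_dataset(ds)
  switch(dialect,
    coco_json = write_dataset_coco(ds, path),
    mask_png_dir = write_dataset_pngdir(ds, path)
  )
  invisible(path)
}

write_dataset_coco <- function(ds, path) {
  ord <- function(df, key) df[order(df[[key]]), , drop = FALSE]
  im <- ord(ds$images, "image_id")
  rf <- ord(ds$references, "ref_id")
  pr <- ord(ds$predictions, "pred_id")
  dims <- stats::setNames(split(cbind(im$width, im$height), seq_len(nrow(im))), im$image_id)
  doc <- list(
    annotations = purrr::map(seq_len(nrow(rf)), function(i) {
      wh <- dims[[rf$image_id[i]]]
      list(area = rf$area_px[i], id = rf$ref_id[i], image_id = rf$image_id[i],
           polyp_type = rf$polyp_type[i],
           segmentation = list(counts = region_to_rle(rf$mask[[i]]),
                               size = c(wh[2], wh[1])))
    }),
    images = purrr::map(seq_len(nrow(im)), function(i) {
      list(center_id = im$center_id[i], height = im$height[i], id = im$image_id[i],
           patient_id = im$patient_id[i], width = im$width[i])
    }),
    predictions = purrr::map(seq_len(nrow(pr)), function(i) {
      list(bbox = c(pr$x0[i], pr$y0[i], pr$x1[i] - pr$x0[i], pr$y1[i] - pr$y0[i]),
           confidence = pr$confidence[i], id = pr$pred_id[i], image_id = pr$image_id[i])
    })
  )
  if (!is.null(ds$ratings)) {
    rt <- ord(ds$ratings, "pred_id")
    doc$ratings <- purrr::map(seq_len(nrow(rt)), function(i) {
      list(pred_id = rt$pred_id[i], rater_id = rt$rater_id[i], rating = rt$rating[i])
    })
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
}

write_dataset_pngdir <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rf <- ds$references
  by_img <- split(seq_len(nrow(rf)), rf$image_id)
  im <- ds$images[order(ds$images$image_id), ]
  idx <- purrr::map_dfr(seq_len(nrow(im)), function(i) {
    iid <- im$image_id[i]
    ii <- by_img[[iid]]
    if (is.null(ii)) return(NULL)
    m <- purrr::reduce(rf$mask[ii], region_union)
    png_name <- paste0(iid, "_mask.png")
    png::writePNG(as.matrix(m) * 1, file.path(path, png_name))
    tibble::tibble(image_id = iid, center_id = im$center_id[i],
                   patient_id = im$patient_id[i], mask_path = png_name,
                   polyp_type = rf$polyp_type[ii[1]])
  })
  readr::write_csv(idx, file.path(path, "index.csv"))
}

#' Read detector predictions in the COCO results dialect
#'
#' Accepts either a COCO results JSON (array of
#' `{image_id, bbox, score, ...}`) or a CSV with columns
#' `pred_id, image_id, x, y, width, height, confidence`. Missing prediction
#' ids are assigned deterministically in file order.
#'
#' @param ds a [pv_dataset()] whose images the predictions refer to.
#' @param path prediction file.
#' @param format `"coco_json"` or `"csv"`.
#' @return `ds` with the predictions attached.
#' @export
read_predictions <- function(ds, path, format = c("coco_json", "csv")) {
  format <- match.arg(format)
  pr <- if (format == "coco_json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    purrr::imap_dfr(raw, function(pd, i) {
      bb <- as.numeric(pd$bbox)
      tibble::tibble(
        pred_id = as.character(pd$id %||% sprintf("p%06d", i)),
        image_id = as.character(pd$image_id),
        x0 = bb[1], y0 = bb[2], x1 = bb[1] + bb[3], y1 = bb[2] + bb[4],
        confidence = as.numeric(pd$confidence %||% pd$score)
      )
    })
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    tibble::tibble(
      pred_id = as.character(df$pred_id %||% sprintf("p%06d", seq_len(nrow(df)))),
      image_id = as.character(df$image_id),
      x0 = df$x, y0 = df$y, x1 = df$x + df$width, y1 = df$y + df$height,
      confidence = df$confidence
    )
  }
  pv_dataset(ds$images, if (nrow(ds$references)) ds$references else NULL,
             pr, ds$ratings)
}

#' Read clinician usefulness ratings
#'
#' Expects a CSV with header `pred_id, rating, rater_id`; ratings attach to
#' predictions, and an image-level file (an `image_id` column in place of
#' `pred_id`) is rejected rather than coerced.
#'
#' @param ds a [pv_dataset()] with predictions.
#' @param path ratings CSV.
#' @return `ds` with ratings attached.
#' @export
read_ratings <- function(ds, path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"pred_id" %in% names(df)) {
    rlang::abort("ratings file must be prediction-level (columns pred_id, rating, rater_id)",
                 class = "polypval_format_error")
  }
  rt <- tibble::tibble(pred_id = as.character(df$pred_id),
                       rating = as.character(df$rating),
                       rater_id = as.character(df$rater_id))
  pv_dataset(ds$images, if (nrow(ds$references)) ds$references else NULL,
             if (nrow(ds$predictions)) ds$predictions else NULL, rt)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
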