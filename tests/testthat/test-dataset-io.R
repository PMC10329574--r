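minimal_coco_json <- function(path, annotations = NULL) {
  doc <- list(
    images = list(list(id = "img1", width = 10, height = 10,
                       center_id = "c1", patient_id = "pat1")),
    annotations = annotations %||%
      list(list(id = "r1", image_id = "img1", polyp_type = "protruded",
                segmentation = list(list(c(0, 0, 4, 0, 4, 4, 0, 4)))))
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  path
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("a minimal COCO-dialect file loads into a validated dataset", {
  f <- minimal_coco_json(withr::local_tempfile(fileext = ".json"))
  ds <- read_dataset(f, "coco_json")
  expect_s3_class(ds, "pv_dataset")
  expect_equal(nrow(ds$references), 1)
  expect_equal(nrow(ds$predictions), 0)
  expect_equal(ds$references$area_px, 16L)
  expect_equal(prevalence(ds), 1.0)
})

test_that("referential and format problems are classed errors", {
  dangling <- minimal_coco_json(
    withr::local_tempfile(fileext = ".json"),
    annotations = list(list(id = "r1", image_id = "img9", polyp_type = "flat",
                            segmentation = list(list(c(0, 0, 2, 0, 2, 2, 0, 2)))))
  )
  expect_error(read_dataset(dangling, "coco_json"),
               class = "polypval_integrity_error")

  no_dims <- withr::local_tempfile(fileext = ".json")
  writeLines('{"images": [{"id": "img1"}], "annotations": []}', no_dims)
  expect_error(read_dataset(no_dims, "coco_json"), class = "polypval_format_error")

  # degenerate polygon rasterizes to nothing -> validation error naming the ref
  empty_mask <- minimal_coco_json(
    withr::local_tempfile(fileext = ".json"),
    annotations = list(list(id = "r7", image_id = "img1", polyp_type = "flat",
                            segmentation = list(list(c(0, 0, 0.1, 0, 0.1, 0.1)))))
  )
  expect_error(read_dataset(empty_mask, "coco_json"), "r7",
               class = "polypval_validation_error")

  expect_error(read_dataset(file.path(tempdir(), "nope.json")),
               class = "polypval_io_error")
})

test_that("dataset validation enforces the field invariants", {
  img <- one_image()
  ref <- ref_row("r1", "img1", rect_region(30, 30, 5, 5, 10, 10))
  expect_error(pv_dataset(img, ref, pred_row("p1", "img1", 5, 5, 10, 10, 1.2)),
               class = "polypval_validation_error")
  expect_error(pv_dataset(img, ref, pred_row("p1", "img1", 10, 5, 10, 10, 0.5)),
               class = "polypval_validation_error")
  expect_error(pv_dataset(img, ref, pred_row("p1", "img1", 40, 40, 50, 50, 0.5)),
               class = "polypval_validation_error")
  bad_area <- ref; bad_area$area_px <- 7L
  expect_error(pv_dataset(img, bad_area), class = "polypval_validation_error")
  pr <- pred_row("p1", "img1", 5, 5, 10, 10, 0.5)
  expect_error(
    pv_dataset(img, ref, pr, tibble::tibble(pred_id = c("p1", "p1"),
                                            rating = "useful", rater_id = "r1")),
    class = "polypval_validation_error")
})

test_that("write/read round-trips a synthetic dataset to identical bytes", {
  ds <- small_study(seed = 21, scale = 0.03)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_dataset(ds, f1)
  back <- read_dataset(f1)
  write_dataset(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  # masks survive pixel-wise
  expect_equal(nrow(back$references), nrow(ds$references))
  i <- match(ds$references$ref_id, back$references$ref_id)
  for (k in seq_len(nrow(ds$references))) {
    expect_true(polypval:::region_equal(ds$references$mask[[k]],
                                        back$references$mask[[i[k]]]))
  }
  # writing the same dataset twice gives identical bytes
  f3 <- withr::local_tempfile(fileext = ".json")
  write_dataset(ds, f3)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f3)))
})

test_that("empty prediction lists serialize as empty arrays", {
  img <- one_image()
  ds <- pv_dataset(img, ref_row("r1", "img1", rect_region(30, 30, 5, 5, 10, 10)))
  f <- withr::local_tempfile(fileext = ".json")
  write_dataset(ds, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(doc$predictions, 0)
  expect_equal(nrow(read_dataset(f)$predictions), 0)
})

test_that("prevalence counts annotated images and respects center filters", {
  imgs <- dplyr::bind_rows(lapply(1:5, function(i) {
    one_image(sprintf("img%d", i), center_id = if (i < 3) "cA" else "cB")
  }))
  ds_none <- pv_dataset(imgs)
  expect_equal(prevalence(ds_none), 0)
  ds <- pv_dataset(imgs, ref_row("r1", "img1", rect_region(30, 30, 1, 1, 5, 5)))
  expect_equal(prevalence(ds), 0.2)
  expect_equal(prevalence(ds, "cA"), 0.5)
  expect_equal(prevalence(ds, "cB"), 0)
  expect_error(prevalence(ds, "cC"), class = "polypval_usage_error")
  # invariant under permutation of image order
  ds_perm <- pv_dataset(imgs[c(4, 2, 5, 1, 3), ], ds$references)
  expect_equal(prevalence(ds_perm), prevalence(ds))
  # all images annotated
  expect_equal(prevalence(perfect_dataset()), 1)
})

test_that("realized prevalence of a generated center stays in the binomial band", {
  spec <- study_spec(center_profile("c1", n_images = 500, prevalence = 0.9,
                                    resolution = c(320, 180)),
                     seed = 99)
  ds <- generate_references(spec)
  phi <- prevalence(ds)
  half <- 2.576 * sqrt(0.9 * 0.1 / 500)
  expect_gt(phi, 0.9 - half)
  expect_lt(phi, 0.9 + half)
})

test_that("mask PNG directories round-trip masks and metadata", {
  ds <- small_study(seed = 5, scale = 0.02)
  # keep single-polyp images only: the PNG dialect stores one mask per image
  multi <- ds$references$image_id[duplicated(ds$references$image_id)]
  keep <- setdiff(ds$references$image_id, multi)
  sub <- pv_dataset(ds$images[ds$images$image_id %in% keep, ],
                    ds$references[ds$references$image_id %in% keep, ])
  d <- withr::local_tempdir()
  write_dataset(sub, d, "mask_png_dir")
  back <- read_dataset(d, "mask_png_dir")
  expect_equal(nrow(back$references), nrow(sub$references))
  key <- match(sub$references$image_id, back$references$image_id)
  for (k in seq_len(nrow(sub$references))) {
    expect_true(polypval:::region_equal(sub$references$mask[[k]],
                                        back$references$mask[[key[k]]]))
  }
  im <- back$images[match(sub$images$image_id, back$images$image_id), ]
  expect_equal(im$center_id, sub$images$center_id)
  expect_equal(im$patient_id, sub$images$patient_id)
})

test_that("predictions and ratings attach from their own files", {
  ds <- pv_dataset(one_image(),
                   ref_row("r1", "img1", rect_region(30, 30, 5, 5, 10, 10)))
  pf <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(image_id = "img1", bbox = c(5, 5, 5, 5), score = 0.9)
  ), auto_unbox = TRUE), pf)
  ds2 <- read_predictions(ds, pf, "coco_json")
  expect_equal(nrow(ds2$predictions), 1)
  expect_equal(ds2$predictions$x1, 10)
  expect_equal(ds2$predictions$confidence, 0.9)

  rf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pred_id,rating,rater_id", "p000001,useful,r1"), rf)
  ds3 <- read_ratings(ds2, rf)
  expect_equal(ds3$ratings$rating, "useful")

  # image-level rating files are rejected, not coerced
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,rating,rater_id", "img1,useful,r1"), bad)
  expect_error(read_ratings(ds2, bad), class = "polypval_format_error")
})
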