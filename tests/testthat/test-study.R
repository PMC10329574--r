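test_that("size classes follow the resolution-scaled area thresholds", {
  expect_equal(as.character(size_class(9999, 1920, 1080)), "small")
  expect_equal(as.character(size_class(100^2, 1920, 1080)), "medium")  # boundary
  expect_equal(as.character(size_class(200^2, 1920, 1080)), "medium")  # boundary
  expect_equal(as.character(size_class(200^2 + 1, 1920, 1080)), "large")
  # quarter-resolution image: thresholds scale to 2500 / 10000
  expect_equal(as.character(size_class(2501, 960, 540)), "medium")
  expect_equal(as.character(size_class(2499, 960, 540)), "small")
  expect_equal(as.character(size_class(10001, 960, 540)), "large")
  expect_error(size_rule(small_max_area = 300^2, large_min_area = 200^2))
})

test_that("a single-center panel equals the whole-dataset panel", {
  ds <- small_study(seed = 4)
  c1 <- filter_center(ds, "center1")
  panel <- per_center_panel(c1, criterion("box_iou", 0.5), 0.5)
  expect_equal(panel$value[panel$center_id == "center1"],
               panel$value[panel$center_id == "all"])
})

duplicate_center_dataset <- function() {
  base <- small_study(seed = 6)
  c1 <- filter_center(base, "center1")
  clone <- c1
  clone$images$image_id <- paste0("dup_", c1$images$image_id)
  clone$images$center_id <- "center2dup"
  clone$references$image_id <- paste0("dup_", c1$references$image_id)
  clone$references$ref_id <- paste0("dup_", c1$references$ref_id)
  clone$predictions$image_id <- paste0("dup_", c1$predictions$image_id)
  clone$predictions$pred_id <- paste0("dup_", c1$predictions$pred_id)
  rt <- if (!is.null(c1$ratings)) {
    dplyr::bind_rows(c1$ratings,
                     dplyr::mutate(c1$ratings, pred_id = paste0("dup_", pred_id)))
  }
  pv_dataset(dplyr::bind_rows(c1$images, clone$images),
             dplyr::bind_rows(c1$references, clone$references),
             dplyr::bind_rows(c1$predictions, clone$predictions), rt)
}

test_that("identical centers have zero across-center spread", {
  ds <- duplicate_center_dataset()
  panel <- per_center_panel(ds, criterion("box_iou", 0.5), 0.5)
  summ <- across_center_summary(panel)
  expect_true(all(summ$sd == 0))
  strat <- size_stratified_ap(ds, "box_iou")
  sds <- across_center_sd(strat)
  expect_true(all(sds$sd == 0, na.rm = TRUE))
})

test_that("size stratification uses ignore semantics and flags empty classes", {
  # all references large and perfectly predicted
  img <- one_image(width = 1920L, height = 1080L)
  big <- rect_region(1920, 1080, 100, 100, 400, 400)   # 90000 px: large
  ds <- pv_dataset(img, ref_row("r1", "img1", big),
                   pred_row("p1", "img1", 100, 100, 400, 400, 1))
  strat <- size_stratified_ap(ds, "box_iou")
  allrows <- strat[strat$center_id == "all", ]
  expect_equal(allrows$ap50[allrows$size_class == "large"], 1)
  expect_true(is.na(allrows$ap50[allrows$size_class == "small"]))
  expect_true(is.na(allrows$ap50[allrows$size_class == "medium"]))

  # a prediction matched to an out-of-class reference is ignored, not an FP:
  # add a small reference with its own perfect prediction; the large class AP
  # must stay 1 even though the small-object prediction ranks above its class
  small <- rect_region(1920, 1080, 10, 10, 60, 60)     # 2500 px: small
  ds2 <- pv_dataset(img,
                    dplyr::bind_rows(ref_row("r1", "img1", big),
                                     ref_row("r2", "img1", small)),
                    dplyr::bind_rows(pred_row("p1", "img1", 100, 100, 400, 400, 0.7),
                                     pred_row("p2", "img1", 10, 10, 60, 60, 0.9)))
  strat2 <- size_stratified_ap(ds2, "box_iou")
  all2 <- strat2[strat2$center_id == "all", ]
  expect_equal(all2$ap50[all2$size_class == "large"], 1)
  expect_equal(all2$ap50[all2$size_class == "small"], 1)
})

test_that("per-size reference counts sum to the total reference count", {
  ds <- small_study(seed = 19)
  strat <- size_stratified_ap(ds, "box_iou")
  expect_equal(sum(strat$n_ref[strat$center_id == "all"]), nrow(ds$references))
})

test_that("identical predictions and references make every criterion perfect", {
  ds <- perfect_dataset()
  cmp <- criterion_comparison(ds, c(default_outline_criteria(),
                                    default_position_criteria()),
                              confidence_cutoff = 0.5)
  expect_true(all(cmp$sensitivity == 1))
  expect_true(all(cmp$ppv == 1))
  expect_true(all(cmp$f1 == 1))
  expect_true(all(cmp$ap == 1))
})

test_that("point-in-mask sensitivity never exceeds point-in-box sensitivity", {
  for (seed in c(3, 14)) {
    ds <- small_study(seed)
    cmp <- criterion_comparison(ds, list(pim = criterion("point_in_mask"),
                                         pib = criterion("point_in_box")),
                                confidence_cutoff = 0.25)
    expect_lte(cmp$sensitivity[cmp$criterion == "point_in_mask"],
               cmp$sensitivity[cmp$criterion == "point_in_box"])
  }
})

test_that("agreement fractions are exact on self-generated ratings", {
  ds <- small_study(seed = 8)
  crit <- criterion("box_iou", 0.5)
  rated <- simulate_ratings(ds, rating_model(crit, label_noise = 0), seed = 2)
  agr <- agreement_fractions(rated, list(box_iou_0.5 = crit))
  expect_equal(agr$frac_useful_accepted, 1)
  expect_equal(agr$frac_not_useful_rejected, 1)
})

test_that("predictions on reference-free images can never be accepted", {
  imgs <- dplyr::bind_rows(one_image("img1"), one_image("img2"))
  ds <- pv_dataset(imgs,
                   ref_row("r1", "img1", rect_region(30, 30, 5, 5, 15, 15)),
                   dplyr::bind_rows(pred_row("p1", "img1", 20, 20, 25, 25, 0.9),
                                    pred_row("p2", "img2", 5, 5, 15, 15, 0.8)),
                   tibble::tibble(pred_id = c("p1", "p2"), rating = "useful",
                                  rater_id = "r1"))
  agr <- agreement_fractions(ds, list(criterion("box_iou", 0.5)))
  expect_equal(agr$frac_useful_accepted, 0)          # none hit
  expect_true(is.na(agr$frac_not_useful_rejected))   # class empty -> absent
})

test_that("the per-object IoU table carries the modelling hierarchy", {
  ds <- small_study(seed = 12)
  tab <- object_iou_table(ds)
  expect_equal(nrow(tab), nrow(ds$references))
  expect_true(all(c("center_id", "patient_id", "image_id", "polyp_type",
                    "size_class", "iou") %in% names(tab)))
  expect_true(any(is.na(tab$iou)))          # some objects are missed
  expect_true(all(tab$iou >= 0.5, na.rm = TRUE))
})
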