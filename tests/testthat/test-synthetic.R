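test_that("prevalence extremes generate the expected reference counts", {
  full <- generate_references(study_spec(
    center_profile("c1", 10, prevalence = 1, resolution = c(320, 180)), seed = 1))
  expect_equal(nrow(full$images), 10)
  expect_gte(nrow(full$references), 10)
  expect_equal(prevalence(full), 1)

  none <- generate_references(study_spec(
    center_profile("c1", 10, prevalence = 0, resolution = c(320, 180)), seed = 1))
  expect_equal(nrow(none$references), 0)
  expect_equal(prevalence(none), 0)
})

test_that("a pure-large size mixture yields only large references", {
  for (seed in 1:5) {
    ds <- generate_references(study_spec(
      center_profile("c1", 6, prevalence = 1,
                     size_mixture = c(small = 0, medium = 0, large = 1)),
      seed = seed))
    sizes <- size_class(ds$references$area_px, 1920, 1080)
    expect_true(all(sizes == "large"))
  }
})

test_that("polyp types follow the generating shape and crescents are non-convex", {
  ds <- generate_references(study_spec(
    center_profile("c1", 40, prevalence = 1, resolution = c(960, 540),
                   shape_mixture = c(ellipse = 0.5, crescent = 0.5)),
    seed = 3))
  expect_setequal(unique(ds$references$polyp_type), c("flat", "protruded"))
  flat <- ds$references[ds$references$polyp_type == "flat", ]
  hull_bigger <- vapply(flat$mask, function(m) {
    region_area(convex_hull_region(m)) > region_area(m)
  }, logical(1))
  expect_true(mean(hull_bigger) > 0.9)   # crescents are non-convex
})

test_that("generation fails loudly when a shape cannot fit the canvas", {
  expect_error(
    generate_references(study_spec(
      center_profile("c1", 2, prevalence = 1, resolution = c(600, 10),
                     size_mixture = c(small = 0, medium = 0, large = 1)),
      seed = 1)),
    class = "polypval_generation_error")
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- default_six_center_spec(seed = 42, scale = 0.03, resolution = c(640, 360))
  ds1 <- generate_study(spec)
  ds2 <- generate_study(spec)
  expect_identical(ds1$images, ds2$images)
  expect_identical(ds1$references, ds2$references)
  expect_identical(ds1$predictions, ds2$predictions)
  expect_identical(ds1$ratings, ds2$ratings)
  # and a different seed changes the data
  ds3 <- generate_study(default_six_center_spec(seed = 43, scale = 0.03,
                                                resolution = c(640, 360)))
  expect_false(identical(ds1$predictions, ds3$predictions))
})

test_that("a noise-free perturbation reproduces the reference boxes exactly", {
  refs <- generate_references(study_spec(
    center_profile("c1", 15, prevalence = 1, resolution = c(640, 360)), seed = 9))
  clean <- perturbation_model(center_jitter_sd = 0, scale_noise_sd = 0,
                              miss_midpoint_area = 1e-6, fp_per_image = 0,
                              confidence_sd = 0)
  ds <- generate_predictions(refs, clean, seed = 1)
  expect_equal(nrow(ds$predictions), nrow(ds$references))
  # per image, the set of predicted boxes equals the set of reference boxes
  ref_boxes <- vapply(seq_len(nrow(ds$references)), function(i) {
    paste(ds$references$image_id[i],
          paste(as.numeric(bounding_box(ds$references$mask[[i]])), collapse = ","))
  }, character(1))
  pred_boxes <- sprintf("%s %s", ds$predictions$image_id,
                        paste(ds$predictions$x0, ds$predictions$y0,
                              ds$predictions$x1, ds$predictions$y1, sep = ","))
  expect_setequal(pred_boxes, ref_boxes)
  expect_equal(average_precision(ds, criterion("box_iou", 0.95)), 1)
})

test_that("a saturated miss rate leaves only false positives", {
  refs <- generate_references(study_spec(
    center_profile("c1", 20, prevalence = 1, resolution = c(640, 360)), seed = 2))
  only_fp <- generate_predictions(refs, perturbation_model(miss_midpoint_area = 1e12,
                                                           fp_per_image = 0.5),
                                  seed = 3)
  # every reference is missed: nothing left that localizes a polyp
  expect_equal(confusion_counts(only_fp, criterion("box_iou", 0.5), 0)$tp, 0)
  none <- generate_predictions(refs, perturbation_model(miss_midpoint_area = 1e12,
                                                        fp_per_image = 0),
                               seed = 3)
  expect_equal(nrow(none$predictions), 0)
})

test_that("ratings reproduce the generating criterion and flip with label noise", {
  ds <- small_study(seed = 16)
  crit <- criterion("point_in_mask")
  clean <- simulate_ratings(ds, rating_model(crit, 0), seed = 5)
  ps <- pair_scores(ds, crit)
  should <- ds$predictions$pred_id %in% unique(ps$pred_id[ps$hit])
  expect_equal(clean$ratings$rating, ifelse(should, "useful", "not_useful"))

  flipped <- simulate_ratings(ds, rating_model(crit, 1), seed = 5)
  expect_true(all(flipped$ratings$rating != clean$ratings$rating))
})

test_that("the realized flip fraction stays in the binomial band at n ~ 2000", {
  spec <- study_spec(list(
    center_profile("c1", 700, prevalence = 1, resolution = c(320, 180)),
    center_profile("c2", 700, prevalence = 1, resolution = c(320, 180)),
    center_profile("c3", 700, prevalence = 1, resolution = c(320, 180))
  ), seed = 30)
  ds <- generate_predictions(generate_references(spec),
                             perturbation_model(miss_midpoint_area = 1e-6),
                             seed = 31)
  n <- nrow(ds$predictions)
  expect_gte(n, 1500)
  clean <- simulate_ratings(ds, rating_model(criterion("mask_iou", 0), 0), seed = 7)
  noisy <- simulate_ratings(ds, rating_model(criterion("mask_iou", 0), 0.1), seed = 7)
  frac <- mean(clean$ratings$rating != noisy$ratings$rating)
  half <- 2.576 * sqrt(0.1 * 0.9 / n)
  expect_gt(frac, 0.1 - half)
  expect_lt(frac, 0.1 + half)
})

test_that("absolute jitter makes realized mask IoU grow with size class", {
  ds <- small_study(seed = 22, scale = 0.15, resolution = c(1920, 1080))
  tab <- object_iou_table(ds, criterion("mask_iou", 0), confidence_cutoff = 0)
  means <- tapply(tab$iou, tab$size_class, mean, na.rm = TRUE)
  expect_lt(means[["small"]], means[["medium"]])
  expect_lt(means[["medium"]], means[["large"]])
})

test_that("crescents produce point-in-mask vs point-in-hull disagreements", {
  ds <- small_study(seed = 26, scale = 0.15, resolution = c(1920, 1080))
  pm <- pair_scores(ds, criterion("point_in_mask"))
  ph <- pair_scores(ds, criterion("point_in_hull"))
  hm <- unique(pm$pred_id[pm$hit]); hh <- unique(ph$pred_id[ph$hit])
  preds <- ds$predictions$pred_id
  disagreement <- mean((preds %in% hm) != (preds %in% hh))
  expect_gte(disagreement, 0.05)
})
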