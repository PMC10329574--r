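# Fixture builders shared across test files. Everything is generated in
# code; no fixture files are read from disk.

# logical matrix with given foreground pixels; pix is a 2-column matrix of
# 0-based (row, col) pairs
mask_matrix <- function(nrow, ncol, pix) {
  m <- matrix(FALSE, nrow, ncol)
  m[cbind(pix[, 1] + 1L, pix[, 2] + 1L)] <- TRUE
  m
}

# solid rectangle mask on a canvas, rows r0..r1-1 and cols c0..c1-1 (half-open)
rect_region <- function(width, height, c0, r0, c1, r1) {
  rows <- r0:(r1 - 1L)
  polypval:::new_region(rows, rep(c0, length(rows)), rep(c1, length(rows)),
                        width, height)
}

# U-shaped mask: full columns at both sides plus the bottom row; the
# centroid lands in the concavity
u_region <- function() {
  m <- mask_matrix(3, 3, rbind(c(0, 0), c(1, 0), c(2, 0),
                               c(2, 1),
                               c(0, 2), c(1, 2), c(2, 2)))
  region_from_matrix(m, width = 3, height = 3)
}

one_image <- function(image_id = "img1", width = 30L, height = 30L,
                      center_id = "c1", patient_id = "pat1") {
  tibble::tibble(image_id = image_id, width = width, height = height,
                 center_id = center_id, patient_id = patient_id)
}

ref_row <- function(ref_id, image_id, region, polyp_type = "protruded") {
  tibble::tibble(ref_id = ref_id, image_id = image_id, mask = list(region),
                 polyp_type = polyp_type, area_px = region_area(region))
}

pred_row <- function(pred_id, image_id, x0, y0, x1, y1, confidence) {
  tibble::tibble(pred_id = pred_id, image_id = image_id,
                 x0 = x0, y0 = y0, x1 = x1, y1 = y1, confidence = confidence)
}

# dataset in which every reference is a solid rectangle and every
# prediction reproduces its bounding box exactly
perfect_dataset <- function(n_images = 3) {
  images <- dplyr::bind_rows(lapply(seq_len(n_images), function(i) {
    one_image(sprintf("img%d", i))
  }))
  refs <- dplyr::bind_rows(lapply(seq_len(n_images), function(i) {
    ref_row(sprintf("r%d", i), sprintf("img%d", i),
            rect_region(30, 30, 5, 5, 15 + i %% 3, 15))
  }))
  preds <- dplyr::bind_rows(lapply(seq_len(n_images), function(i) {
    pred_row(sprintf("p%d", i), sprintf("img%d", i), 5, 5, 15 + i %% 3, 15, 1.0)
  }))
  pv_dataset(images, refs, preds)
}

# three references, ranked prediction outcomes TP, FP, TP
three_ref_curve_dataset <- function() {
  imgs <- dplyr::bind_rows(lapply(1:3, function(i) one_image(sprintf("img%d", i))))
  refs <- dplyr::bind_rows(lapply(1:3, function(i) {
    ref_row(sprintf("r%d", i), sprintf("img%d", i), rect_region(30, 30, 5, 5, 15, 15))
  }))
  preds <- dplyr::bind_rows(
    pred_row("p1", "img1", 5, 5, 15, 15, 0.9),
    pred_row("p2", "img2", 20, 20, 28, 28, 0.8),
    pred_row("p3", "img3", 5, 5, 15, 15, 0.7)
  )
  pv_dataset(imgs, refs, preds)
}

# small randomized multi-center study for property tests
small_study <- function(seed, scale = 0.06, resolution = c(640, 360), ...) {
  generate_study(default_six_center_spec(seed = seed, scale = scale,
                                         resolution = resolution, ...))
}

# random tiny instance (<= 5 images, <= 4 objects each) with rectangular
# masks and a mix of overlapping/non-overlapping predictions
random_tiny_dataset <- function(seed) {
  set.seed(seed)
  n_img <- sample(1:5, 1)
  images <- dplyr::bind_rows(lapply(seq_len(n_img), function(i) {
    one_image(sprintf("img%d", i), 60L, 60L)
  }))
  refs <- list(); preds <- list()
  for (i in seq_len(n_img)) {
    n_ref <- sample(0:4, 1)
    for (k in seq_len(n_ref)) {
      x0 <- sample(0:40, 1); y0 <- sample(0:40, 1)
      w <- sample(5:18, 1); h <- sample(5:18, 1)
      refs[[length(refs) + 1]] <- ref_row(
        sprintf("img%d_r%d", i, k), sprintf("img%d", i),
        rect_region(60, 60, x0, y0, min(60, x0 + w), min(60, y0 + h))
      )
    }
    n_pred <- sample(0:5, 1)
    for (k in seq_len(n_pred)) {
      x0 <- sample(0:40, 1); y0 <- sample(0:40, 1)
      w <- sample(5:20, 1); h <- sample(5:20, 1)
      preds[[length(preds) + 1]] <- pred_row(
        sprintf("img%d_p%d", i, k), sprintf("img%d", i),
        x0, y0, min(60, x0 + w), min(60, y0 + h),
        round(stats::runif(1), 3)
      )
    }
  }
  if (!length(refs)) {
    refs[[1]] <- ref_row("img1_r1", "img1", rect_region(60, 60, 10, 10, 20, 20))
  }
  pv_dataset(images, dplyr::bind_rows(refs),
             if (length(preds)) dplyr::bind_rows(preds))
}
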