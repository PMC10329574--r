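# Independent brute-force oracles. These deliberately avoid the package's
# run-length region algebra and incremental sweep: regions are materialized
# as logical matrices, matching is a naive double loop, and AP is computed
# from an explicitly constructed interpolated-precision envelope.

o_box_matrix <- function(x0, y0, x1, y1, width, height) {
  m <- matrix(FALSE, height, width)
  cols <- which(seq_len(width) - 0.5 >= x0 & seq_len(width) - 0.5 < x1)
  rows <- which(seq_len(height) - 0.5 >= y0 & seq_len(height) - 0.5 < y1)
  m[rows, cols] <- TRUE
  m
}

o_iou <- function(a, b) sum(a & b) / sum(a | b)

# even-odd point-in-polygon with a boundary tolerance (boundary = inside)
o_point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    L2 <- (bx - ax)^2 + (by - ay)^2
    if (L2 > 0) {
      t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / L2
      t <- min(1, max(0, t))
      d2 <- (px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2
      if (d2 < tol) return(TRUE)
    }
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ay <- poly[i, 2]; by <- poly[j, 2]
    if ((ay > py) != (by > py)) {
      x <- poly[i, 1] + (py - ay) * (poly[j, 1] - poly[i, 1]) / (by - ay)
      if (px < x) inside <- !inside
    }
  }
  inside
}

# brute-force hull raster: hull polygon of all foreground unit-square
# corners, then every pixel whose center is inside/on the polygon
o_hull_matrix <- function(mask_mat) {
  idx <- which(mask_mat, arr.ind = TRUE)
  rows <- idx[, 1] - 1; cols <- idx[, 2] - 1
  px <- c(cols, cols + 1, cols, cols + 1)
  py <- c(rows, rows, rows + 1, rows + 1)
  hull <- grDevices::chull(px, py)
  poly <- cbind(px[hull], py[hull])
  out <- matrix(FALSE, nrow(mask_mat), ncol(mask_mat))
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      out[r, c] <- o_point_in_polygon(c - 0.5, r - 0.5, poly)
    }
  }
  out
}

# pairwise scores plus center distances by matrix arithmetic
o_scores <- function(preds, refs, images, kind) {
  out <- matrix(0, nrow(preds), max(1, nrow(refs)))
  dist <- matrix(Inf, nrow(preds), max(1, nrow(refs)))
  for (i in seq_len(nrow(preds))) {
    im <- images[images$image_id == preds$image_id[i], ]
    pb <- o_box_matrix(preds$x0[i], preds$y0[i], preds$x1[i], preds$y1[i],
                       im$width, im$height)
    pc <- c((preds$x0[i] + preds$x1[i]) / 2, (preds$y0[i] + preds$y1[i]) / 2)
    for (j in seq_len(nrow(refs))) {
      if (refs$image_id[j] != preds$image_id[i]) { out[i, j] <- NA; next }
      mm <- as.matrix(refs$mask[[j]])
      idx <- which(mm, arr.ind = TRUE)
      ctr <- c(mean(idx[, 2] - 0.5), mean(idx[, 1] - 0.5))
      dist[i, j] <- sqrt(sum((pc - ctr)^2))
      rm <- switch(kind,
        box_iou = o_box_matrix(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
                               max(idx[, 2]), max(idx[, 1]), im$width, im$height),
        mask_iou = mm,
        hull_iou = o_hull_matrix(mm)
      )
      out[i, j] <- o_iou(pb, rm)
    }
  }
  list(scores = out, dist = dist)
}

# naive greedy one-to-one matching over a ranked score matrix; score ties
# broken by smaller center distance, then ref_id
o_greedy <- function(preds, refs, scores, threshold, dist = NULL) {
  if (is.null(dist)) dist <- matrix(0, nrow(preds), nrow(refs))
  ord <- order(-preds$confidence, preds$pred_id)
  taken <- rep(FALSE, nrow(refs))
  assigned <- rep(NA_integer_, nrow(preds))
  for (i in ord) {
    s <- scores[i, ]
    hit <- !is.na(s) & (if (threshold > 0) s >= threshold else s > 0) & !taken
    if (!any(hit)) next
    best <- which(hit)[order(-s[hit], dist[i, hit], refs$ref_id[hit])][1]
    taken[best] <- TRUE
    assigned[i] <- best
  }
  assigned[order(-preds$confidence, preds$pred_id)]
}

# 101-point AP from an explicit envelope: sort points by recall, take the
# running max of precision from the right, then read the envelope at each
# grid recall with findInterval
o_ap_envelope <- function(recall, precision) {
  if (!length(recall)) return(0)
  o <- order(recall, precision)
  r <- recall[o]; p <- precision[o]
  env <- rev(cummax(rev(p)))
  grid <- seq(0, 1, by = 0.01)
  vals <- numeric(length(grid))
  for (g in seq_along(grid)) {
    k <- findInterval(grid[g] - 1e-12, r) + 1  # first point with recall >= grid
    vals[g] <- if (k <= length(r)) env[k] else 0
  }
  mean(vals)
}

# full independent AP for a dataset under an overlap criterion
o_average_precision <- function(ds, kind, threshold) {
  preds <- ds$predictions
  refs <- ds$references
  if (!nrow(preds)) return(0)
  sc <- o_scores(preds, refs, ds$images, kind)
  assigned <- o_greedy(preds, refs, sc$scores, threshold, sc$dist)
  tp <- cumsum(!is.na(assigned))
  k <- seq_along(assigned)
  o_ap_envelope(tp / nrow(refs), tp / k)
}
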