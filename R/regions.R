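#' Pixel-region geometry
#'
#' Reference polyps live on an integer pixel grid. A pixel `(r, c)` (0-based
#' row/column) occupies the unit square `[c, c+1) x [r, r+1)` in continuous
#' image coordinates; boxes are half-open `[x0, x1) x [y0, y1)` with integer
#' corners. A `pv_region` stores a binary pixel set as run-length intervals
#' per row: parallel integer vectors `rows`, `xs`, `xe` with each run covering
#' columns `[xs, xe)` of row `rows`.
#'
#' @name regions
#' @keywords internal
NULL

new_region <- function(rows, xs, xe, width, height, kind = "mask") {
  rows <- as.integer(rows); xs <- as.integer(xs); xe <- as.integer(xe)
  keep <- xe > xs
  rows <- rows[keep]; xs <- xs[keep]; xe <- xe[keep]
  if (length(rows)) {
    o <- order(rows, xs)
    rows <- rows[o]; xs <- xs[o]; xe <- xe[o]
    # merge overlapping/touching runs within a row so equality is canonical
    if (length(rows) > 1L) {
      merged_rows <- integer(0); merged_xs <- integer(0); merged_xe <- integer(0)
      cr <- rows[1L]; cs <- xs[1L]; ce <- xe[1L]
      for (i in seq_along(rows)[-1L]) {
        if (rows[i] == cr && xs[i] <= ce) {
          ce <- max(ce, xe[i])
        } else {
          merged_rows <- c(merged_rows, cr); merged_xs <- c(merged_xs, cs)
          merged_xe <- c(merged_xe, ce)
          cr <- rows[i]; cs <- xs[i]; ce <- xe[i]
        }
      }
      merged_rows <- c(merged_rows, cr); merged_xs <- c(merged_xs, cs)
      merged_xe <- c(merged_xe, ce)
      rows <- merged_rows; xs <- merged_xs; xe <- merged_xe
    }
  }
  structure(
    list(kind = kind, width = as.integer(width), height = as.integer(height),
         rows = rows, xs = xs, xe = xe),
    class = "pv_region"
  )
}

is_region <- function(x) inherits(x, "pv_region")

stop_if_empty <- function(r, what = "region") {
  if (!length(r$rows)) {
    rlang::abort(paste0("empty ", what, ": operation requires at least one foreground pixel"),
                 class = "polypval_validation_error")
  }
  invisible(r)
}

#' Build a region from a logical/0-1 matrix
#'
#' Row 1 / column 1 of the matrix map to pixel row 0 / column 0.
#'
#' @param m logical or numeric matrix (`nrow` = image rows).
#' @param width,height canvas size in pixels; defaults to the matrix extent.
#' @param kind region kind label (`"mask"`, `"hull"` or `"box"`).
#' @return a `pv_region`.
#' @export
region_from_matrix <- function(m, width = ncol(m), height = nrow(m), kind = "mask") {
  stopifnot(is.matrix(m))
  m <- m > 0
  rows <- integer(0); xs <- integer(0); xe <- integer(0)
  for (r in seq_len(nrow(m))) {
    v <- m[r, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values)
    rows <- c(rows, rep.int(r - 1L, length(fg)))
    xs <- c(xs, starts[fg] - 1L)
    xe <- c(xe, ends[fg])
  }
  new_region(rows, xs, xe, width, height, kind)
}

#' @export
as.matrix.pv_region <- function(x, ...) {
  m <- matrix(FALSE, nrow = x$height, ncol = x$width)
  for (i in seq_along(x$rows)) {
    m[x$rows[i] + 1L, (x$xs[i] + 1L):x$xe[i]] <- TRUE
  }
  m
}

#' @export
print.pv_region <- function(x, ...) {
  cat(sprintf("<pv_region kind=%s canvas=%dx%d area=%d px>\n",
              x$kind, x$width, x$height, region_area(x)))
  invisible(x)
}

#' Foreground pixel count of a region
#' @param r a `pv_region`.
#' @return integer pixel count.
#' @export
region_area <- function(r) {
  stopifnot(is_region(r))
  sum(r$xe - r$xs)
}

region_equal <- function(a, b) {
  identical(a$rows, b$rows) && identical(a$xs, b$xs) && identical(a$xe, b$xe)
}

# ---- boxes -------------------------------------------------------------

#' Half-open pixel box
#'
#' @param x0,y0,x1,y1 integer corners; the box covers `[x0, x1) x [y0, y1)`.
#' @return named numeric vector of class `pv_box`.
#' @export
box <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0)
  structure(c(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "pv_box")
}

box_area <- function(b) unname((b["x1"] - b["x0"]) * (b["y1"] - b["y0"]))

#' Center point of a box
#' @param b a `pv_box` or numeric vector with names x0, y0, x1, y1.
#' @return numeric `c(x, y)`.
#' @export
box_center <- function(b) {
  unname(c((b["x0"] + b["x1"]) / 2, (b["y0"] + b["y1"]) / 2))
}

#' Closed-form IoU of two axis-aligned boxes
#' @param a,b boxes as produced by [box()].
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  iw <- min(a["x1"], b["x1"]) - max(a["x0"], b["x0"])
  ih <- min(a["y1"], b["y1"]) - max(a["y0"], b["y0"])
  inter <- max(0, iw) * max(0, ih)
  unname(inter / (box_area(a) + box_area(b) - inter))
}

#' Rasterize a box onto a canvas
#' @param b a `pv_box` (integer corners).
#' @param width,height canvas size.
#' @return a `pv_region` of kind `"box"`.
#' @export
box_region <- function(b, width, height) {
  rws <- seq.int(b["y0"], b["y1"] - 1L)
  new_region(rws, rep(b["x0"], length(rws)), rep(b["x1"], length(rws)),
             width, height, kind = "box")
}

#' Minimal bounding box of a region
#' @param r non-empty `pv_region`.
#' @return a `pv_box` (half-open, integer corners).
#' @export
bounding_box <- function(r) {
  stop_if_empty(r, "mask")
  box(min(r$xs), min(r$rows), max(r$xe), max(r$rows) + 1L)
}

# ---- measures ----------------------------------------------------------

#' Centroid of a region's foreground pixel centers
#'
#' Pixel `(r, c)` contributes its center `(c + 0.5, r + 0.5)`.
#'
#' @param r non-empty `pv_region`.
#' @return numeric `c(x, y)`.
#' @export
mask_centroid <- function(r) {
  stop_if_empty(r, "mask")
  len <- r$xe - r$xs
  a <- sum(len)
  # sum over a run of column centers c+0.5, c in [xs, xe): (xe-xs)(xs+xe)/2
  x <- sum((r$xe - r$xs) * (r$xs + r$xe) / 2) / a
  y <- sum(len * (r$rows + 0.5)) / a
  c(x, y)
}

# Foreground area of `r` inside the (possibly non-integer) box `b`.
region_box_intersection_area <- function(r, b) {
  sel <- r$rows >= b["y0"] & r$rows < b["y1"]
  if (!any(sel)) return(0)
  sum(pmax(0, pmin(r$xe[sel], b["x1"]) - pmax(r$xs[sel], b["x0"])))
}

region_intersection_area <- function(a, b) {
  common <- intersect(unique(a$rows), unique(b$rows))
  if (!length(common)) return(0L)
  total <- 0L
  for (rr in common) {
    ia <- which(a$rows == rr); ib <- which(b$rows == rr)
    for (i in ia) {
      total <- total + sum(pmax(0L, pmin(a$xe[i], b$xe[ib]) - pmax(a$xs[i], b$xs[ib])))
    }
  }
  total
}

#' IoU of two pixel regions
#'
#' Intersection over union of the two foreground pixel sets. For a pair of
#' rasterized boxes this equals the closed-form [box_iou()].
#'
#' @param a,b non-empty `pv_region`s on the same canvas.
#' @return IoU in `[0, 1]`.
#' @export
region_iou <- function(a, b) {
  stop_if_empty(a); stop_if_empty(b)
  inter <- region_intersection_area(a, b)
  inter / (region_area(a) + region_area(b) - inter)
}

region_union <- function(a, b, kind = a$kind) {
  new_region(c(a$rows, b$rows), c(a$xs, b$xs), c(a$xe, b$xe),
             max(a$width, b$width), max(a$height, b$height), kind)
}

# a \ b, used by the crescent generator
region_difference <- function(a, b) {
  rows <- integer(0); xs <- integer(0); xe <- integer(0)
  b_by_row <- split(seq_along(b$rows), b$rows)
  for (i in seq_along(a$rows)) {
    rr <- a$rows[i]
    ib <- b_by_row[[as.character(rr)]]
    segs <- cbind(a$xs[i], a$xe[i])
    if (!is.null(ib)) {
      for (j in ib) {
        out <- NULL
        for (k in seq_len(nrow(segs))) {
          s <- segs[k, 1]; e <- segs[k, 2]
          bs <- b$xs[j]; be <- b$xe[j]
          if (be <= s || bs >= e) { out <- rbind(out, c(s, e)); next }
          if (bs > s) out <- rbind(out, c(s, bs))
          if (be < e) out <- rbind(out, c(be, e))
        }
        segs <- if (is.null(out)) matrix(numeric(0), ncol = 2) else out
        if (!nrow(segs)) break
      }
    }
    if (nrow(segs)) {
      rows <- c(rows, rep.int(rr, nrow(segs)))
      xs <- c(xs, segs[, 1]); xe <- c(xe, segs[, 2])
    }
  }
  new_region(rows, xs, xe, a$width, a$height, a$kind)
}

#' Pixel membership of a continuous point
#'
#' The point is assigned to the pixel containing it (floor of both
#' coordinates; a point on an exact pixel boundary belongs to the pixel at
#' its lower right). Points outside the canvas are never members.
#'
#' @param p numeric `c(x, y)`.
#' @param r a `pv_region`.
#' @return logical.
#' @export
point_in_region <- function(p, r) {
  px <- floor(p[1]); py <- floor(p[2])
  if (px < 0 || py < 0 || px >= r$width || py >= r$height) return(FALSE)
  any(r$rows == py & r$xs <= px & px < r$xe)
}

# ---- convex hull -------------------------------------------------------

# Hull polygon vertices (continuous coords) of the union of the foreground
# unit squares: extreme corner candidates are the per-row run endpoints.
convex_hull_polygon <- function(r) {
  stop_if_empty(r, "mask")
  xmin <- tapply(r$xs, r$rows, min)
  xmax <- tapply(r$xe, r$rows, max)
  rws <- as.integer(names(xmin))
  px <- c(xmin, xmin, xmax, xmax)
  py <- c(rws, rws + 1L, rws, rws + 1L)
  idx <- grDevices::chull(px, py)
  cbind(x = px[idx], y = py[idx])
}

# x-extent of the intersection of a convex polygon with the horizontal line
# at y; NULL when the line misses the polygon.
convex_slab_at <- function(poly, y) {
  n <- nrow(poly)
  xsect <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- poly[i, 2]; y2 <- poly[j, 2]
    if ((y1 - y) * (y2 - y) <= 0) {
      if (y1 == y2) {
        if (y1 == y) xsect <- c(xsect, poly[i, 1], poly[j, 1])
      } else {
        xsect <- c(xsect, poly[i, 1] + (y - y1) * (poly[j, 1] - poly[i, 1]) / (y2 - y1))
      }
    }
  }
  if (!length(xsect)) return(NULL)
  range(xsect)
}

#' Convex-hull region of a mask
#'
#' Convex hull of the union of the foreground unit squares, rasterized by
#' pixel-center inclusion (a pixel belongs to the hull iff its center lies
#' inside or on the hull polygon). The result always contains the mask and
#' is contained in its bounding box.
#'
#' @param r non-empty `pv_region` of kind `"mask"`.
#' @return a `pv_region` of kind `"hull"`.
#' @export
convex_hull_region <- function(r) {
  stop_if_empty(r, "mask")
  poly <- convex_hull_polygon(r)
  y0 <- min(r$rows); y1 <- max(r$rows)
  rows <- integer(0); xs <- integer(0); xe <- integer(0)
  eps <- 1e-7
  for (rr in y0:y1) {
    sl <- convex_slab_at(poly, rr + 0.5)
    if (is.null(sl)) next
    c0 <- ceiling(sl[1] - 0.5 - eps)
    c1 <- floor(sl[2] - 0.5 + eps)
    if (c1 >= c0) {
      rows <- c(rows, rr); xs <- c(xs, c0); xe <- c(xe, c1 + 1L)
    }
  }
  new_region(rows, xs, xe, r$width, r$height, kind = "hull")
}

# Point-in-hull without rasterizing: pixel-center test against the hull
# polygon (boundary counts as inside).
point_in_hull <- function(p, r) {
  px <- floor(p[1]); py <- floor(p[2])
  if (px < 0 || py < 0 || px >= r$width || py >= r$height) return(FALSE)
  poly <- convex_hull_polygon(r)
  cx <- px + 0.5; cy <- py + 0.5
  sl <- convex_slab_at(poly, cy)
  !is.null(sl) && cx >= sl[1] - 1e-9 && cx <= sl[2] + 1e-9
}

# ---- general polygon rasterization (COCO polygon segmentations) --------

#' Rasterize a simple polygon by the even-odd rule
#'
#' A pixel is foreground iff its center lies inside the polygon
#' (even-odd crossing rule on the scanline through the center).
#'
#' @param poly two-column matrix of vertices `(x, y)` in continuous
#'   pixel coordinates, or a flat `c(x1, y1, x2, y2, ...)` vector.
#' @param width,height canvas size.
#' @return a `pv_region` of kind `"mask"`.
#' @export
region_from_polygon <- function(poly, width, height) {
  if (is.null(dim(poly))) poly <- matrix(poly, ncol = 2, byrow = TRUE)
  y0 <- max(0L, floor(min(poly[, 2])))
  y1 <- min(height - 1L, ceiling(max(poly[, 2])))
  n <- nrow(poly)
  rows <- integer(0); xs <- integer(0); xe <- integer(0)
  for (rr in y0:y1) {
    y <- rr + 0.5
    xsect <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > y) != (yj > y)) {
        xsect <- c(xsect, poly[i, 1] + (y - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi))
      }
    }
    if (length(xsect) < 2) next
    xsect <- sort(xsect)
    for (k in seq(1, length(xsect) - 1, by = 2)) {
      c0 <- max(0L, ceiling(xsect[k] - 0.5 - 1e-9))
      c1 <- min(width - 1L, floor(xsect[k + 1] - 0.5 + 1e-9))
      if (c1 >= c0) { rows <- c(rows, rr); xs <- c(xs, c0); xe <- c(xe, c1 + 1L) }
    }
  }
  new_region(rows, xs, xe, width, height)
}

# ---- COCO-style uncompressed RLE (column-major) ------------------------

region_to_rle <- function(r) {
  h <- r$height; w <- r$width
  if (!length(r$rows)) return(as.integer(h * w))
  len <- r$xe - r$xs
  cols <- sequence(len, from = r$xs)
  rws <- rep.int(r$rows, len)
  idx <- sort(cols * h + rws)
  brk <- which(diff(idx) > 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))] + 1L
  counts <- integer(0)
  prev <- 0L
  for (i in seq_along(starts)) {
    counts <- c(counts, starts[i] - prev, ends[i] - starts[i])
    prev <- ends[i]
  }
  c(counts, h * w - prev)
}

region_from_rle <- function(counts, width, height) {
  counts <- as.integer(counts)
  if (sum(counts) != width * height) {
    rlang::abort("RLE counts do not sum to width * height",
                 class = "polypval_format_error")
  }
  ends <- cumsum(counts)
  starts <- ends - counts
  fg <- seq_along(counts) %% 2L == 0L  # counts alternate bg, fg, bg, ...
  idx <- unlist(lapply(which(fg & counts > 0L), function(i) starts[i]:(ends[i] - 1L)),
                use.names = FALSE)
  if (!length(idx)) return(new_region(integer(0), integer(0), integer(0), width, height))
  rws <- idx %% height
  cols <- idx %/% height
  o <- order(rws, cols)
  rws <- rws[o]; cols <- cols[o]
  # split sorted pixel list into row runs
  brk <- which(diff(cols) != 1L | diff(rws) != 0L)
  s <- c(1L, brk + 1L); e <- c(brk, length(cols))
  new_region(rws[s], cols[s], cols[e] + 1L, width, height)
}
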