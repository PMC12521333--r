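# Polygon geometry on the pixel grid.
#
# Coordinate convention used throughout: 0-based, origin at the top-left
# pixel, x = column, y = row, and pixel (row r, col c) has its *center* at
# (x = c, y = r). Polygons are matrices with columns x, y; the closing edge
# from the last vertex back to the first is implicit.

#' Signed polygon area (shoelace formula)
#'
#' @param polygon Numeric matrix with columns x, y (one vertex per row).
#' @return Signed area in square pixels; positive for counter-clockwise
#'   vertex order in the image coordinate frame.
#' @export
polygon_area <- function(polygon) {
  polygon <- as_polygon(polygon)
  x <- polygon[, 1]; y <- polygon[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

as_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3 || !is.numeric(polygon)) {
    stop("polygon must be a numeric matrix with columns x, y and >= 3 vertices")
  }
  storage.mode(polygon) <- "double"
  polygon
}

#' Test points against a polygon (even-odd rule)
#'
#' Points exactly on the polygon boundary are counted as inside.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param polygon Vertex matrix, columns x and y.
#' @return Logical vector, one element per point.
#' @export
point_in_polygon <- function(px, py, polygon) {
  polygon <- as_polygon(polygon)
  n <- nrow(polygon)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      hit <- crosses & (px < xint)
      hit[is.na(hit)] <- FALSE
      inside <- xor(inside, hit)
    }
    vx <- xj - xi; vy <- yj - yi
    l2 <- vx * vx + vy * vy
    if (l2 > 0) {
      tt <- pmin(pmax(((px - xi) * vx + (py - yi) * vy) / l2, 0), 1)
      dx <- px - (xi + tt * vx); dy <- py - (yi + tt * vy)
      on_edge <- on_edge | (dx * dx + dy * dy < 1e-18)
    }
    j <- i
  }
  inside | on_edge
}

# Integer pixel centers covered by a polygon, as a two-column matrix of
# 0-based (row, col); clipped to an optional canvas of shape c(nrow, ncol).
polygon_pixels <- function(polygon, canvas_shape = NULL) {
  polygon <- as_polygon(polygon)
  if (abs(polygon_area(polygon)) < .Machine$double.eps * 100) {
    stop("degenerate polygon: zero area")
  }
  x0 <- ceiling(min(polygon[, 1])); x1 <- floor(max(polygon[, 1]))
  y0 <- ceiling(min(polygon[, 2])); y1 <- floor(max(polygon[, 2]))
  if (!is.null(canvas_shape)) {
    y0 <- max(y0, 0); y1 <- min(y1, canvas_shape[1] - 1)
    x0 <- max(x0, 0); x1 <- min(x1, canvas_shape[2] - 1)
  }
  if (x1 < x0 || y1 < y0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  keep <- point_in_polygon(px, py, polygon)
  cbind(row = py[keep], col = px[keep])
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG
# state afterwards (lightweight stand-in for withr::with_seed on hot paths).
with_rng <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Axis-aligned rectangle polygon from half-open bounds.
rect_polygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
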