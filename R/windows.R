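# Observation windows: simple planar polygons in metres. Axis-aligned
# rectangles get exact fast paths throughout; convex polygons are handled by
# generic polygon geometry (Sutherland-Hodgman clipping, arc/chord disc
# intersection).

#' Rectangular observation window
#'
#' @param xrange,yrange numeric length-2 ranges in metres.
#' @return An object of class `sppa_window`.
#' @examples
#' w <- owin_rect(c(0, 10), c(0, 10))
#' window_area(w)
#' @export
owin_rect <- function(xrange, yrange) {
  stopifnot(length(xrange) == 2, length(yrange) == 2,
            xrange[2] > xrange[1], yrange[2] > yrange[1])
  v <- cbind(x = c(xrange[1], xrange[2], xrange[2], xrange[1]),
             y = c(yrange[1], yrange[1], yrange[2], yrange[2]))
  structure(list(vertices = v, is_rect = TRUE,
                 xrange = as.numeric(xrange), yrange = as.numeric(yrange)),
            class = "sppa_window")
}

#' Polygonal observation window
#'
#' Vertices are given in order (either orientation); the polygon must be
#' simple and have positive area. Axis-aligned rectangles are detected and
#' promoted to the exact rectangle representation.
#'
#' @param x,y vertex coordinates in metres (unclosed ring).
#' @return An object of class `sppa_window`.
#' @export
owin_poly <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, all(is.finite(x)),
            all(is.finite(y)))
  if (poly_signed_area(x, y) < 0) { x <- rev(x); y <- rev(y) }
  if (length(x) == 4) {
    xr <- range(x); yr <- range(y)
    on_corners <- all(x %in% xr) && all(y %in% yr) &&
      abs(poly_signed_area(x, y) - diff(xr) * diff(yr)) < 1e-12 * diff(xr) * diff(yr)
    if (on_corners) return(owin_rect(xr, yr))
  }
  w <- structure(list(vertices = cbind(x = x, y = y), is_rect = FALSE,
                      xrange = range(x), yrange = range(y)),
                 class = "sppa_window")
  if (window_area(w) <= 0) stop("window polygon has zero area")
  w
}

#' @export
print.sppa_window <- function(x, ...) {
  cat(sprintf("<sppa_window: %s, area %.4f m2>\n",
              if (x$is_rect) "rectangle" else
                sprintf("polygon (%d vertices)", nrow(x$vertices)),
              window_area(x)))
  invisible(x)
}

poly_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Window area in square metres
#' @param w an `sppa_window`.
#' @export
window_area <- function(w) {
  if (w$is_rect) return(diff(w$xrange) * diff(w$yrange))
  abs(poly_signed_area(w$vertices[, 1], w$vertices[, 2]))
}

#' Bounding box of a window
#' @param w an `sppa_window`.
#' @return numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
window_bbox <- function(w) c(w$xrange[1], w$yrange[1], w$xrange[2], w$yrange[2])

#' Point-in-window test
#'
#' Boundary points count as inside (within a 1e-9 m tolerance).
#'
#' @param w an `sppa_window`.
#' @param x,y coordinates to test.
#' @return logical vector.
#' @export
window_contains <- function(w, x, y) {
  tol <- 1e-9
  if (w$is_rect) {
    return(x >= w$xrange[1] - tol & x <= w$xrange[2] + tol &
           y >= w$yrange[1] - tol & y <= w$yrange[2] + tol)
  }
  vx <- w$vertices[, 1]; vy <- w$vertices[, 2]
  vapply(seq_along(x), function(i) {
    point_in_poly(x[i], y[i], vx, vy, tol)
  }, logical(1))
}

# Ray casting with boundary tolerance.
point_in_poly <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1))
  # boundary check: distance to each edge
  if (min(point_seg_dist(px, py, vx[j], vy[j], vx, vy)) <= tol) return(TRUE)
  inside <- FALSE
  for (k in seq_len(n)) {
    x1 <- vx[j[k]]; y1 <- vy[j[k]]; x2 <- vx[k]; y2 <- vy[k]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# Distance from point (px, py) to segments (x1,y1)-(x2,y2); vectorized over
# segments.
point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Distance from points to the window boundary (used for border corrections).
boundary_dist <- function(w, x, y) {
  if (w$is_rect) {
    return(pmin(x - w$xrange[1], w$xrange[2] - x,
                y - w$yrange[1], w$yrange[2] - y))
  }
  vx <- w$vertices[, 1]; vy <- w$vertices[, 2]
  n <- length(vx); j <- c(n, seq_len(n - 1))
  vapply(seq_along(x), function(i)
    min(point_seg_dist(x[i], y[i], vx[j], vy[j], vx, vy)), numeric(1))
}

# Sutherland-Hodgman: clip subject polygon by a convex clip polygon (CCW).
convex_clip <- function(sx, sy, cx, cy) {
  n <- length(cx)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    ex <- cx[k2] - cx[k]; ey <- cy[k2] - cy[k]
    if (length(sx) == 0) break
    side <- ex * (sy - cy[k]) - ey * (sx - cx[k])  # >= 0 is inside for CCW
    m <- length(sx)
    jprev <- c(m, seq_len(m - 1))
    outx <- numeric(0); outy <- numeric(0)
    for (i in seq_len(m)) {
      p <- jprev[i]
      cur_in <- side[i] >= -1e-14
      prev_in <- side[p] >= -1e-14
      if (cur_in != prev_in) {
        t <- side[p] / (side[p] - side[i])
        outx <- c(outx, sx[p] + t * (sx[i] - sx[p]))
        outy <- c(outy, sy[p] + t * (sy[i] - sy[p]))
      }
      if (cur_in) { outx <- c(outx, sx[i]); outy <- c(outy, sy[i]) }
    }
    sx <- outx; sy <- outy
  }
  list(x = sx, y = sy)
}

# |W ∩ (W + v)| for a convex window (exact for rectangles).
translation_overlap <- function(w, dx, dy) {
  if (w$is_rect) {
    a <- diff(w$xrange) - abs(dx)
    b <- diff(w$yrange) - abs(dy)
    return(ifelse(a > 0 & b > 0, a * b, 0))
  }
  vx <- w$vertices[, 1]; vy <- w$vertices[, 2]
  mapply(function(ddx, ddy) {
    cl <- convex_clip(vx + ddx, vy + ddy, vx, vy)
    if (length(cl$x) < 3) 0 else abs(poly_signed_area(cl$x, cl$y))
  }, dx, dy)
}

# Area of a disc of radius R centred at (cx, cy), clipped to the window.
disc_window_area <- function(w, cx, cy, R) {
  v <- w$vertices
  cpp_circle_poly_area(cx, cy, R, v[, 1], v[, 2])
}

# Largest axis-aligned rectangle inscribed in a window (grid search at the
# given resolution). Rectangular windows return themselves.
largest_inscribed_rect <- function(w, resolution = 0.1) {
  if (w$is_rect) return(w)
  xs <- seq(w$xrange[1], w$xrange[2], by = resolution)
  ys <- seq(w$yrange[1], w$yrange[2], by = resolution)
  best <- NULL; best_area <- 0
  for (i1 in seq_along(xs)) for (i2 in seq_along(xs)) {
    if (xs[i2] - xs[i1] <= 0) next
    wdt <- xs[i2] - xs[i1]
    if (wdt * diff(w$yrange) <= best_area) next
    for (j1 in seq_along(ys)) for (j2 in rev(seq_along(ys))) {
      hgt <- ys[j2] - ys[j1]
      if (hgt <= 0 || wdt * hgt <= best_area) break
      corners_in <- all(window_contains(w, c(xs[i1], xs[i2], xs[i2], xs[i1]),
                                        c(ys[j1], ys[j1], ys[j2], ys[j2])))
      if (corners_in) {
        best_area <- wdt * hgt
        best <- owin_rect(c(xs[i1], xs[i2]), c(ys[j1], ys[j1] + hgt))
        break
      }
    }
  }
  if (is.null(best)) stop("no inscribed rectangle found at this resolution")
  best
}

# Affine map of a window: x' = M x (2x2 matrix), applied to vertices.
transform_window <- function(w, M) {
  v <- w$vertices %*% t(M)
  owin_poly(v[, 1], v[, 2])
}
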