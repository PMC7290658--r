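#' Point-in-polygon test (even-odd rule)
#'
#' Tests whether points fall inside a simple polygon using the even-odd
#' (ray-casting) rule. Points lying on the polygon boundary count as inside,
#' so a nuclear centroid sitting exactly on a hand-drawn region edge is never
#' silently dropped.
#'
#' Coordinates follow the package-wide image frame: origin at the top-left
#' corner, `x` along columns, `y` along rows, both continuous; the centre of
#' the pixel in (0-based) column `c` and row `r` is `(c + 0.5, r + 0.5)`.
#'
#' @param x,y Numeric vectors of point coordinates (recycled to equal length).
#' @param polygon A two-column numeric matrix of polygon vertices `(x, y)` in
#'   order; the polygon is closed implicitly (last vertex connects to first).
#' @param eps Distance tolerance for the boundary-counts-as-inside rule.
#' @return A logical vector, one element per point.
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' point_in_polygon(c(5, 20, 10), c(5, 20, 5), sq)
#' @export
point_in_polygon <- function(x, y, polygon, eps = 1e-9) {
  polygon <- validate_polygon(polygon)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  cpp_points_in_polygon(x, y, polygon[, 1], polygon[, 2], eps)
}

validate_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3 || !is.numeric(polygon)) {
    abort("`polygon` must be a numeric matrix with >= 3 rows and 2 columns (x, y).")
  }
  storage.mode(polygon) <- "double"
  polygon
}

#' Signed area and centroid of a simple polygon
#'
#' Shoelace-formula area (absolute value) and area-weighted centroid, used to
#' resolve nuclei contained in more than one region of interest.
#'
#' @param polygon Two-column vertex matrix as in [point_in_polygon()].
#' @return For `polygon_area()`, a non-negative number (squared pixels); for
#'   `polygon_centroid()`, a length-2 numeric `(x, y)`.
#' @export
polygon_area <- function(polygon) {
  polygon <- validate_polygon(polygon)
  abs(shoelace(polygon))
}

#' @rdname polygon_area
#' @export
polygon_centroid <- function(polygon) {
  polygon <- validate_polygon(polygon)
  a <- shoelace(polygon)
  if (abs(a) < 1e-12) return(colMeans(polygon)) # degenerate: vertex mean
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

shoelace <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# squared distance from points (px, py) to segment (x1,y1)-(x2,y2)
point_segment_dist2 <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  l2 <- vx^2 + vy^2
  t <- if (l2 > 0) pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / l2)) else 0
  (px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2
}

# minimum distance between two segments (a1-a2, b1-b2), each length-2 (x, y)
segment_segment_dist <- function(a1, a2, b1, b2) {
  d2 <- min(
    point_segment_dist2(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2]),
    point_segment_dist2(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2]),
    point_segment_dist2(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2]),
    point_segment_dist2(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2])
  )
  if (segments_intersect(a1, a2, b1, b2)) return(0)
  sqrt(d2)
}

segments_intersect <- function(a1, a2, b1, b2) {
  o <- function(p, q, r) sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- o(a1, a2, b1); o2 <- o(a1, a2, b2)
  o3 <- o(b1, b2, a1); o4 <- o(b1, b2, a2)
  (o1 != o2 && o3 != o4)
}

# TRUE if the closed polyline is simple (no two non-adjacent edges intersect)
polygon_is_simple <- function(polygon) {
  polygon <- validate_polygon(polygon)
  n <- nrow(polygon)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(polygon[idx[i, 1], ], polygon[idx[i, 2], ],
                             polygon[idx[j, 1], ], polygon[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
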