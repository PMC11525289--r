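#' Feret (caliper) diameters of a point set
#'
#' Computes the maximum Feret diameter (FD, the largest distance between two
#' points of the convex hull, found by rotating calipers over antipodal
#' vertex pairs) and the minimum Feret diameter (mFD, the smallest caliper
#' width, which for a convex polygon is always attained with one jaw flush
#' against a hull edge).
#'
#' @param pts two-column matrix of point coordinates (x, y), any units.
#' @return list with elements `FD` (max caliper distance), `mFD` (min
#'   caliper width), and `hull` (hull vertices, counter-clockwise).
#' @export
feret_diameters <- function(pts) {
  pts <- as.matrix(pts)
  if (!is.numeric(pts) || ncol(pts) != 2L) stop("pts must be an n x 2 numeric matrix")
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) return(list(FD = 0, mFD = 0, hull = pts))
  if (n == 2L) {
    d <- sqrt(sum((pts[1, ] - pts[2, ])^2))
    return(list(FD = d, mFD = 0, hull = pts))
  }
  h <- grDevices::chull(pts)          # clockwise
  hull <- pts[rev(h), , drop = FALSE] # counter-clockwise
  m <- nrow(hull)
  if (m == 2L) {
    d <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(list(FD = d, mFD = 0, hull = hull))
  }
  list(FD = .calipers_max(hull), mFD = .calipers_min(hull), hull = hull)
}

# Rotating calipers: walk antipodal vertex pairs of a CCW convex polygon.
# For each edge (i, i+1) advance the opposite vertex j while the triangle
# area keeps growing; the polygon diameter is realised at an antipodal pair.
.calipers_max <- function(hull) {
  m <- nrow(hull)
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  d2 <- function(a, b) sum((a - b)^2)
  best <- 0
  j <- 2L
  for (i in seq_len(m)) {
    ii <- if (i == m) 1L else i + 1L
    repeat {
      jj <- if (j == m) 1L else j + 1L
      if (abs(cross2(hull[i, ], hull[ii, ], hull[jj, ])) >
          abs(cross2(hull[i, ], hull[ii, ], hull[j, ]))) j <- jj else break
    }
    best <- max(best, d2(hull[i, ], hull[j, ]), d2(hull[ii, ], hull[j, ]))
  }
  sqrt(best)
}

# Minimal caliper width: for each hull edge, the width is the maximum
# perpendicular distance of any vertex from the edge's supporting line;
# the minimum over edges is the exact minimum Feret diameter.
.calipers_min <- function(hull) {
  m <- nrow(hull)
  widths <- vapply(seq_len(m), function(i) {
    a <- hull[i, ]
    b <- hull[if (i == m) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) return(Inf)
    # distance of all vertices from line through a with direction e
    max(abs((hull[, 1] - a[1]) * e[2] - (hull[, 2] - a[2]) * e[1]) / len)
  }, numeric(1))
  min(widths)
}

# Corner points of a set of pixels (1-based row/col centre coordinates):
# each pixel contributes its four square corners, so hull-based calipers
# measure the outline of the pixel squares, matching how image platforms
# report Feret diameters (a w x h rectangle of pixels gives mFD = min(w,h)).
#' @keywords internal
pixel_corners <- function(rc) {
  x <- rc[, 2]; y <- rc[, 1]
  cbind(x = c(x - 0.5, x - 0.5, x + 0.5, x + 0.5),
        y = c(y - 0.5, y + 0.5, y - 0.5, y + 0.5))
}

# Area and centroid of a simple polygon (shoelace); vertices in order.
#' @keywords internal
polygon_area_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = abs(a), centroid = c(cx, cy))
}
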