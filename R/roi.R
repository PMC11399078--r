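#' Rectangular region of interest
#'
#' Construct a rectangular ROI in nm coordinates. Areas are reported in
#' square micrometers, the conventional unit for membrane-protein densities.
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds in nm.
#' @return An object of class `roi` with shape `"rectangle"`.
#' @examples
#' r <- roi_rect(0, 0, 10000, 10000)  # a 10 x 10 um cell patch
#' roi_area(r)                        # 100 um^2
#' @export
roi_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(is.numeric(xmin), is.numeric(ymin), is.numeric(xmax), is.numeric(ymax))
  if (!(xmax > xmin && ymax > ymin)) {
    stop("roi_rect: xmax must exceed xmin and ymax must exceed ymin (zero area ROI)")
  }
  structure(
    list(shape = "rectangle",
         xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax)),
    class = "roi"
  )
}

#' Polygonal region of interest
#'
#' Construct a simple-polygon ROI, e.g. a hand-drawn cell outline. The
#' polygon must be simple (non-self-intersecting); vertices are given in nm
#' and the closing edge is implicit.
#'
#' @param x,y Numeric vertex coordinates in nm (equal length, >= 3 vertices).
#' @return An object of class `roi` with shape `"polygon"`.
#' @export
roi_polygon <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("roi_polygon: need at least 3 vertices")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("roi_polygon: non-finite vertex")
  if (.polygon_self_intersects(x, y)) {
    stop("roi_polygon: polygon is self-intersecting; ROI must be simple")
  }
  r <- structure(
    list(shape = "polygon", x = as.numeric(x), y = as.numeric(y)),
    class = "roi"
  )
  if (roi_area(r) <= 0) stop("roi_polygon: polygon has zero area")
  r
}

# Segment intersection test for simplicity checking; O(n^2) over edges,
# polygons here are cell outlines with few vertices.
.polygon_self_intersects <- function(x, y) {
  n <- length(x)
  p1x <- x; p1y <- y
  p2x <- c(x[-1], x[1]); p2y <- c(y[-1], y[1])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross(p1x[i], p1y[i], p2x[i], p2y[i], p1x[j], p1y[j])
      d2 <- cross(p1x[i], p1y[i], p2x[i], p2y[i], p2x[j], p2y[j])
      d3 <- cross(p1x[j], p1y[j], p2x[j], p2y[j], p1x[i], p1y[i])
      d4 <- cross(p1x[j], p1y[j], p2x[j], p2y[j], p2x[i], p2y[i])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' ROI area in square micrometers
#'
#' @param roi An `roi` object.
#' @return Area in um^2 (coordinates are nm; 1 um^2 = 1e6 nm^2).
#' @export
roi_area <- function(roi) {
  stopifnot(inherits(roi, "roi"))
  a_nm2 <- switch(roi$shape,
    rectangle = (roi$xmax - roi$xmin) * (roi$ymax - roi$ymin),
    polygon = {
      x <- roi$x; y <- roi$y
      xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
      abs(sum(x * ys - xs * y)) / 2   # shoelace
    },
    stop("unknown ROI shape")
  )
  a_nm2 / 1e6
}

#' Test whether points fall inside an ROI
#'
#' Boundary points count as inside. Polygon membership uses even-odd ray
#' casting.
#'
#' @param roi An `roi` object.
#' @param x,y Point coordinates in nm.
#' @return Logical vector.
#' @export
roi_contains <- function(roi, x, y) {
  stopifnot(inherits(roi, "roi"), length(x) == length(y))
  if (roi$shape == "rectangle") {
    return(x >= roi$xmin & x <= roi$xmax & y >= roi$ymin & y <= roi$ymax)
  }
  px <- roi$x; py <- roi$y
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  # boundary tolerance: points within eps of an edge are kept
  inside | .on_polygon_edge(px, py, x, y)
}

.on_polygon_edge <- function(px, py, x, y, eps = 1e-9) {
  n <- length(px)
  on <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    ex <- px[i] - px[j]; ey <- py[i] - py[j]
    len2 <- ex^2 + ey^2
    t <- pmin(1, pmax(0, ((x - px[j]) * ex + (y - py[j]) * ey) / len2))
    d2 <- (x - (px[j] + t * ex))^2 + (y - (py[j] + t * ey))^2
    on <- on | d2 <= eps
    j <- i
  }
  on
}

#' Uniform random points inside an ROI
#'
#' Used by the CSR simulators. Polygon ROIs are sampled by rejection from
#' the bounding rectangle. Draws from the current RNG stream.
#'
#' @param roi An `roi` object.
#' @param n Number of points.
#' @return A list with numeric vectors `x` and `y` (nm).
#' @keywords internal
roi_runif <- function(roi, n) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  if (roi$shape == "rectangle") {
    return(list(x = stats::runif(n, roi$xmin, roi$xmax),
                y = stats::runif(n, roi$ymin, roi$ymax)))
  }
  bx <- range(roi$x); by <- range(roi$y)
  xs <- numeric(0); ys <- numeric(0)
  frac <- roi_area(roi) * 1e6 / ((bx[2] - bx[1]) * (by[2] - by[1]))
  while (length(xs) < n) {
    m <- ceiling((n - length(xs)) / max(frac, 0.05)) + 16
    cx <- stats::runif(m, bx[1], bx[2]); cy <- stats::runif(m, by[1], by[2])
    keep <- roi_contains(roi, cx, cy)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  list(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Bounding-rectangle ROI of a point set
#'
#' Default "cell area" when no mask is supplied: the axis-aligned bounding
#' rectangle of the reference-channel molecule centers.
#'
#' @param x,y Point coordinates in nm.
#' @return An `roi` rectangle.
#' @export
roi_from_points <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  roi_rect(min(x), min(y), max(x), max(y))
}

#' @export
print.roi <- function(x, ...) {
  if (x$shape == "rectangle") {
    cat(sprintf("<roi rectangle [%.0f, %.0f] x [%.0f, %.0f] nm, %.2f um^2>\n",
                x$xmin, x$xmax, x$ymin, x$ymax, roi_area(x)))
  } else {
    cat(sprintf("<roi polygon, %d vertices, %.2f um^2>\n", length(x$x), roi_area(x)))
  }
  invisible(x)
}
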