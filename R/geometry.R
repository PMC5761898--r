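# Planar polygon utilities used by slide simulation and core-grid construction.
# All coordinates are micrometres (origin top-left, x rightward, y downward);
# areas are returned in square micrometres unless a function says otherwise.
# Polygons are matrices with columns x, y, vertices in order, not closed
# (the last vertex is implicitly joined to the first).

#' Validate a polygon matrix
#'
#' @param poly numeric matrix with two columns (x, y in micrometres), one row
#'   per vertex, at least 3 rows, finite coordinates.
#' @return the polygon, invisibly, after validation.
#' @keywords internal
validate_polygon <- function(poly) {
  if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
    stop("polygon must be a numeric matrix with 2 columns and >= 3 vertices")
  if (!all(is.finite(poly)))
    stop("polygon coordinates must be finite")
  if (abs(polygon_area(poly)) <= 0)
    stop("polygon has zero area")
  invisible(poly)
}

#' Signed area of a polygon (shoelace formula)
#' @param poly vertex matrix (x, y).
#' @return signed area in the units of the coordinates squared; positive for
#'   counter-clockwise vertex order in a conventional y-up frame.
#' @keywords internal
polygon_area_signed <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Absolute polygon area
#' @inheritParams polygon_area_signed
#' @return non-negative area (square micrometres for micrometre inputs).
#' @keywords internal
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Bounding box of one or more polygons
#' @param polys a polygon matrix or a list of them.
#' @return named numeric vector (xmin, ymin, xmax, ymax).
#' @keywords internal
polygon_bbox <- function(polys) {
  if (is.matrix(polys)) polys <- list(polys)
  xs <- unlist(lapply(polys, function(p) p[, 1L]))
  ys <- unlist(lapply(polys, function(p) p[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Boundary-inclusive point-in-polygon test
#'
#' Cells are treated as points; a point exactly on a polygon edge or vertex
#' counts as inside. Wraps [pracma::inpolygon()] with `boundary = TRUE`.
#'
#' @param x,y numeric vectors of point coordinates (micrometres).
#' @param poly polygon vertex matrix.
#' @return logical vector, TRUE when the point is inside or on the boundary.
#' @export
point_in_polygon <- function(x, y, poly) {
  validate_polygon(poly)
  if (length(x) == 0L) return(logical(0L))
  pracma::inpolygon(x, y, poly[, 1L], poly[, 2L], boundary = TRUE)
}

# Sutherland-Hodgman clip of a polygon against a single half-plane
# {p : a.p <= b}. Returns a vertex matrix (possibly with 0 rows).
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- poly %*% a - b          # <= 0 means inside
  out <- matrix(numeric(0L), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- d[i] <= 0; pj_in <- d[j] <= 0
    if (pi_in) out <- rbind(out, poly[i, ])
    if (xor(pi_in, pj_in)) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four rectangle half-planes. Exact
#' for simple polygons clipped by a convex window, which is the only case the
#' core grid needs.
#'
#' @param poly polygon vertex matrix (micrometres).
#' @param xmin,ymin,xmax,ymax rectangle bounds (micrometres).
#' @return clipped polygon vertex matrix; zero rows when the intersection is
#'   empty.
#' @export
clip_polygon_rect <- function(poly, xmin, ymin, xmax, ymax) {
  p <- poly
  p <- clip_halfplane(p, c(-1, 0), -xmin)
  p <- clip_halfplane(p, c(1, 0), xmax)
  p <- clip_halfplane(p, c(0, -1), -ymin)
  p <- clip_halfplane(p, c(0, 1), ymax)
  p
}

#' Area of the intersection of a rectangle with a set of ROI polygons
#'
#' ROI polygons are assumed pairwise disjoint (separate annotated tumor
#' regions), so their clipped areas add.
#'
#' @param polys list of polygon matrices (or a single matrix).
#' @param xmin,ymin,xmax,ymax rectangle bounds (micrometres).
#' @return intersection area in square micrometres.
#' @export
rect_roi_overlap_area <- function(polys, xmin, ymin, xmax, ymax) {
  if (is.matrix(polys)) polys <- list(polys)
  total <- 0
  for (p in polys) {
    cl <- clip_polygon_rect(p, xmin, ymin, xmax, ymax)
    if (nrow(cl) >= 3L) total <- total + polygon_area(cl)
  }
  total
}

# Distance from points to the nearest point on a polygon's boundary.
# Vectorised over points; loops over edges (polygons have few vertices).
dist_to_boundary <- function(x, y, poly) {
  n <- nrow(poly)
  dmin <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1L]; ay <- poly[i, 2L]
    bx <- poly[j, 1L]; by <- poly[j, 2L]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 > 0) pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2)) else 0
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

# Inward offset ("inset") of a convex polygon by w: intersection of the
# half-planes obtained by shifting every edge inward by w. For a convex
# polygon this is exactly the set of interior points at distance >= w from
# the boundary. Returns a matrix with < 3 rows when the inset is empty.
polygon_inset_convex <- function(poly, w) {
  if (w <= 0) return(poly)
  # orient counter-clockwise in the signed-area sense so inward normals are
  # consistent
  if (polygon_area_signed(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  p <- poly
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1L] - poly[i, 1L]
    ey <- poly[j, 2L] - poly[i, 2L]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    # outward normal for CCW orientation is (ey, -ex)/len; inside is
    # {p : n.(p - v_i) <= 0}; shift inward by w
    a <- c(ey, -ex) / len
    b <- sum(a * poly[i, ]) - w
    p <- clip_halfplane(p, a, b)
    if (nrow(p) < 3L) return(p)
  }
  p
}

# TRUE when every cross product of consecutive edges has the same sign
# (allowing zeros), i.e. the polygon is convex.
is_convex_polygon <- function(poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    k <- if (j == n) 1L else j + 1L
    cr <- (poly[j, 1L] - poly[i, 1L]) * (poly[k, 2L] - poly[j, 2L]) -
      (poly[j, 2L] - poly[i, 2L]) * (poly[k, 1L] - poly[j, 1L])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# Uniform points on a polygon by rejection sampling from its bounding box.
# Deterministic given the R RNG state.
runif_polygon <- function(n, poly) {
  bb <- polygon_bbox(poly)
  out_x <- numeric(0L); out_y <- numeric(0L)
  need <- n
  area_frac <- polygon_area(poly) /
    ((bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"]))
  while (need > 0L) {
    m <- ceiling(need / max(area_frac, 1e-3)) + 16L
    px <- stats::runif(m, bb["xmin"], bb["xmax"])
    py <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- point_in_polygon(px, py, poly)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
    need <- n - length(out_x)
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}
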