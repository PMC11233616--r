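#' Neck (ostium) contour
#'
#' An ordered closed 3D polyline bounding the aneurysm ostium; the first
#' point is not repeated at the end.
#'
#' @param points numeric matrix, k x 3, ordered contour points in mm.
#' @return An object of class `neck_contour`.
#' @export
neck_contour <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("validation error: neck: points must be k x 3")
  if (nrow(points) < 3L) stop("validation error: neck: needs at least 3 points")
  if (anyNA(points)) stop("validation error: neck: non-finite coordinate")
  if (sqrt(sum((points[1, ] - points[nrow(points), ])^2)) < 1e-12)
    stop("validation error: neck: first point must not be repeated")
  structure(list(points = points), class = "neck_contour")
}

#' @export
print.neck_contour <- function(x, ...) {
  cat(sprintf("neck_contour: %d points\n", nrow(x$points)))
  invisible(x)
}

#' Fit the neck plane
#'
#' Total-least-squares plane through the contour points (smallest
#' eigenvector of the point covariance).  The frame origin is the contour
#' centroid; the normal is flipped so that it points toward the sac.
#'
#' @param neck a `neck_contour`.
#' @param sac_centroid 3-vector, a point on the sac side (e.g. the sac
#'   vertex centroid).
#' @return A `plane_frame`: list with `origin`, `normal`, `in_plane_u`,
#'   `in_plane_v` (orthonormal basis).
#' @export
fit_neck_plane <- function(neck, sac_centroid) {
  p <- neck$points
  origin <- colMeans(p)
  cen <- sweep(p, 2, origin)
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300))
    stop("degenerate-geometry error: collinear neck points")
  n <- ev$vectors[, 3]
  if (sum(n * (sac_centroid - origin)) < 0) n <- -n
  u <- ev$vectors[, 1]
  # right-handed frame (u, v, n)
  v <- crossprod3(n, u)
  v <- v / sqrt(sum(v^2))
  structure(list(origin = origin, normal = n / sqrt(sum(n^2)),
                 in_plane_u = u / sqrt(sum(u^2)), in_plane_v = v),
            class = "plane_frame")
}

# contour projected into the (u, v) plane coordinates, k x 2
project_contour <- function(neck, plane) {
  rel <- sweep(neck$points, 2, plane$origin)
  cbind(rel %*% plane$in_plane_u, rel %*% plane$in_plane_v)
}

# simple-polygon check by segment-pair intersection, O(k^2)
is_simple_polygon <- function(xy) {
  k <- nrow(xy)
  a <- xy
  b <- xy[c(2:k, 1), , drop = FALSE]
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (j == i || j == i %% k + 1L || i == j %% k + 1L) next
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Neck area, perimeter and centroid
#'
#' The ostium area NA is the shoelace area of the contour projected onto
#' the neck plane; the neck circumference NC is the length of the original
#' 3D polyline (a curve property, unlike the planar ostium area).
#'
#' @param neck a `neck_contour`.
#' @param plane the `plane_frame` fitted from this contour.
#' @return List with `NA_mm2`, `NC_mm`, `centroid` (3-vector).
#' @export
polygon_metrics <- function(neck, plane) {
  xy <- project_contour(neck, plane)
  if (!is_simple_polygon(xy))
    stop("geometry error: projected neck polygon self-intersects")
  k <- nrow(xy)
  nxt <- c(2:k, 1)
  area <- abs(sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2]) / 2)
  p <- neck$points
  per <- sum(sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2)))
  if (area <= 0 || per <= 0)
    stop("geometry error: degenerate neck polygon")
  list(NA_mm2 = area, NC_mm = per, centroid = plane$origin)
}

#' Neck diameter parallel to blood flow
#'
#' Length of the chord of the projected neck polygon that passes through
#' the neck centroid along the in-plane projection of the inlet flow
#' direction (ND).
#'
#' @param neck a `neck_contour`.
#' @param plane the `plane_frame` fitted from this contour.
#' @param inlet_dir unit 3-vector of the inlet flow direction.
#' @return ND in mm.
#' @export
neck_diameter <- function(neck, plane, inlet_dir) {
  w <- inlet_dir - sum(inlet_dir * plane$normal) * plane$normal
  if (sqrt(sum(w^2)) < 1e-9)
    stop("geometry error: inlet flow is perpendicular to the neck plane, ND undefined")
  g <- c(sum(w * plane$in_plane_u), sum(w * plane$in_plane_v))
  g <- g / sqrt(sum(g^2))
  xy <- project_contour(neck, plane)
  k <- nrow(xy)
  a <- xy
  b <- xy[c(2:k, 1), , drop = FALSE]
  # line through the origin (= projected centroid) with direction g:
  # crossing parameter t solves a + s (b - a) = t g
  tpos <- Inf
  tneg <- -Inf
  for (i in seq_len(k)) {
    e <- b[i, ] - a[i, ]
    den <- g[1] * (-e[2]) - g[2] * (-e[1])
    if (abs(den) < 1e-14) next
    t <- (a[i, 1] * (-e[2]) - a[i, 2] * (-e[1])) / den
    s <- (g[1] * a[i, 2] - g[2] * a[i, 1]) / den
    if (s < -1e-12 || s > 1 + 1e-12) next
    if (t > 1e-12 && t < tpos) tpos <- t
    if (t < -1e-12 && t > tneg) tneg <- t
  }
  if (!is.finite(tpos) || !is.finite(tneg))
    stop("geometry error: neck centroid chord does not meet the contour")
  tpos - tneg
}
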