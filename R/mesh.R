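#' Triangulated surface mesh
#'
#' Constructs and validates a triangulated surface mesh.  Vertices are 3D
#' coordinates in millimetres; faces index vertices (1-based) with
#' consistent counter-clockwise winding viewed from outside.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, vertex indices of each triangle.
#' @return An object of class `surface_mesh` (list with `vertices`, `faces`).
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("validation error: vertices must be n x 3")
  if (ncol(faces) != 3L) stop("validation error: faces must be m x 3")
  if (nrow(vertices) < 4L)
    stop("validation error: vertices: mesh needs at least 4 vertices")
  if (anyNA(vertices)) stop("validation error: vertices: non-finite coordinate")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("validation error: faces: face index out of vertex range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  a <- triangle_areas(m)
  if (any(a <= 1e-12))
    stop("validation error: faces: zero-area face below tolerance 1e-12 mm^2")
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) "watertight" else "open"))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Total surface area of a mesh
#'
#' Sum of the areas of all triangles (the dome area DA when applied to the
#' open sac mesh).
#'
#' @param mesh a `surface_mesh`.
#' @return Area in mm^2.
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  sum(triangle_areas(mesh))
}

# directed edges as a 2-column matrix, one row per half-edge
directed_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))

#' Is a mesh watertight?
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with opposite orientation (each directed edge occurs exactly once).
#'
#' @param mesh a `surface_mesh`.
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  de <- directed_edges(mesh)
  tab <- table(edge_key(de))
  all(tab == 2L) && !anyDuplicated(paste(de[, 1], de[, 2]))
}

# ordered boundary loop (vertex indices); error if closed or if the
# boundary is not a single loop
boundary_loop <- function(mesh) {
  de <- directed_edges(mesh)
  key <- edge_key(de)
  cnt <- table(key)
  b <- de[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  if (nrow(b) == 0L)
    stop("geometry error: mesh is closed, no boundary loop")
  nxt <- structure(b[, 2], names = as.character(b[, 1]))
  if (anyDuplicated(names(nxt)) || anyDuplicated(unname(nxt)))
    stop("geometry error: boundary is not a single simple loop")
  loop <- integer(nrow(b))
  loop[1] <- b[1, 1]
  for (k in seq_len(nrow(b) - 1L)) {
    loop[k + 1L] <- nxt[[as.character(loop[k])]]
  }
  if (nxt[[as.character(loop[length(loop)])]] != loop[1])
    stop("geometry error: boundary loop does not close")
  loop
}

#' Cap the neck opening of a sac mesh
#'
#' Closes the open sac along its neck by fan triangulation from the neck
#' centroid, producing a watertight mesh on which the dome volume DV and
#' the convex-hull quantities are well defined.  The sac boundary loop must
#' coincide with the neck contour points.
#'
#' @param sac open `surface_mesh` (dome only).
#' @param neck a `neck_contour`.
#' @param tol matching tolerance between boundary vertices and contour
#'   points, mm.
#' @return A closed `surface_mesh`.
#' @export
cap_neck <- function(sac, neck, tol = 1e-6) {
  stopifnot(inherits(sac, "surface_mesh"), inherits(neck, "neck_contour"))
  loop <- boundary_loop(sac)
  bp <- sac$vertices[loop, , drop = FALSE]
  np <- neck$points
  if (nrow(bp) != nrow(np))
    stop("geometry error: boundary/contour mismatch (different point counts)")
  # match each boundary vertex to its nearest contour point
  d2 <- outer(rowSums(bp^2), rowSums(np^2), "+") - 2 * bp %*% t(np)
  if (any(sqrt(pmax(apply(d2, 1, min), 0)) > tol))
    stop("geometry error: boundary/contour mismatch (points differ beyond tolerance)")
  centroid <- colMeans(bp)
  v <- rbind(sac$vertices, centroid)
  ci <- nrow(v)
  # boundary directed edges (a -> b) are un-mirrored; the cap supplies the
  # mirror (b -> a -> centroid), which keeps the global orientation coherent
  cap <- cbind(loop[c(seq_along(loop)[-1], 1L)], loop, ci)
  closed <- surface_mesh(v, rbind(sac$faces, cap))
  if (!is_watertight(closed))
    stop("geometry error: capping failed to produce a watertight mesh")
  closed
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem sum of signed tetrahedra spanned by each face and the
#' origin; orientation-insensitive (absolute value is returned).
#'
#' @param mesh a closed `surface_mesh`.
#' @return Volume in mm^3 (the dome volume DV for a capped sac).
#' @export
enclosed_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is_watertight(mesh))
    stop("geometry error: enclosed_volume requires a watertight mesh")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(det6)) / 6
}

#' Maximum pairwise distance between points
#'
#' Exact maximum Euclidean distance over a point set (the maximum diameter
#' MD when applied to the sac vertices).  Computed by an exhaustive scan;
#' ties are broken by the lexicographically smallest index pair.
#'
#' @param points numeric matrix, n x 3.
#' @return List with `distance` (mm) and `endpoints` (2 x 3 matrix).
#' @export
max_pairwise_distance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("input error: need at least 2 points")
  res <- max_pairwise_cpp(points)
  list(distance = res$distance,
       index = c(res$i, res$j),
       endpoints = points[c(res$i, res$j), , drop = FALSE])
}

#' Convex-hull volume and area of a closed sac
#'
#' Computes the convex hull of the capped sac's vertices.  `hull_volume`
#' (DV_CH) and `hull_area` (DA_CH) feed the ellipticity and undulation
#' indices; the hull area includes the cap-side surface because the hull is
#' taken of the closed sac.
#'
#' @param mesh a closed `surface_mesh` (or any point set as an n x 3 matrix).
#' @return List with `hull_volume` (mm^3), `hull_area` (mm^2), `faces`.
#' @export
convex_hull_metrics <- function(mesh) {
  pts <- if (inherits(mesh, "surface_mesh")) mesh$vertices else as.matrix(mesh)
  res <- tryCatch(quickhull3_cpp(pts), error = function(e)
    stop("degenerate-geometry error: ", conditionMessage(e)))
  list(hull_volume = res$volume, hull_area = res$area, faces = res$faces)
}

#' Maximum perpendicular height above the neck plane
#'
#' Largest signed distance of any sac vertex from the neck plane, measured
#' along the plane normal (which points toward the sac).
#'
#' @param sac a `surface_mesh`.
#' @param plane a `plane_frame` from [fit_neck_plane()].
#' @return MPH in mm.
#' @export
max_plane_distance <- function(sac, plane) {
  d <- sweep(sac$vertices, 2, plane$origin) %*% plane$normal
  mph <- max(d)
  if (mph <= 0)
    stop("orientation error: no sac vertex above the neck plane")
  mph
}

# all intersections of ray origin + t*dir with mesh triangles
# (Moller-Trumbore, vectorised over faces); returns sorted positive t
ray_mesh_intersections <- function(mesh, origin, dir) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  s <- matrix(rep(origin, each = nrow(a)), ncol = 3) - a
  u <- rowSums(s * h) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q %*% dir)[, 1] / det
  tt <- rowSums(e2 * q) / det
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tt > 1e-9
  sort(tt[hit])
}

#' Central perpendicular height
#'
#' Distance from the neck centroid to the farthest intersection of the ray
#' cast along the neck-plane normal with the sac mesh.
#'
#' @param sac a `surface_mesh`.
#' @param plane a `plane_frame` whose origin is the neck centroid.
#' @return CPH in mm.
#' @export
central_height <- function(sac, plane) {
  tt <- ray_mesh_intersections(sac, plane$origin, plane$normal)
  if (length(tt) == 0L)
    stop("geometry error: central ray does not intersect the sac (pathologically tilted sac)")
  max(tt)
}

# signed area of the cross-section of a closed oriented mesh with the
# plane at `offset` along its normal, via oriented intersection segments
cross_section_area <- function(mesh, plane, offset) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.numeric(sweep(v, 2, plane$origin) %*% plane$normal) - offset
  # nudge on-plane vertices below the cut so a section at the neck plane
  # itself still captures the ostium polygon
  d[abs(d) < 1e-12] <- -1e-12
  da <- d[f[, 1]]; db <- d[f[, 2]]; dc <- d[f[, 3]]
  crossing <- (pmin(da, db, dc) < 0) & (pmax(da, db, dc) > 0)
  if (!any(crossing)) return(0)
  fi <- f[crossing, , drop = FALSE]
  ds <- cbind(da, db, dc)[crossing, , drop = FALSE]
  u <- plane$in_plane_u; w <- plane$in_plane_v; nrm <- plane$normal
  seg <- matrix(0, nrow(fi), 4)  # (u1, v1, u2, v2) oriented along n x m
  for (k in seq_len(nrow(fi))) {
    dd <- ds[k, ]
    vid <- fi[k, ]
    pts <- matrix(0, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (dd[e[1]] * dd[e[2]] < 0) {
        t <- dd[e[1]] / (dd[e[1]] - dd[e[2]])
        pts <- rbind(pts, (1 - t) * v[vid[e[1]], ] + t * v[vid[e[2]], ])
      }
    }
    if (nrow(pts) != 2L) next
    # orient the segment along cross(n, face normal)
    fn <- crossprod3(v[vid[2], ] - v[vid[1], ], v[vid[3], ] - v[vid[1], ])
    dirv <- crossprod3(nrm, fn)
    if (sum((pts[2, ] - pts[1, ]) * dirv) < 0) pts <- pts[2:1, , drop = FALSE]
    rel1 <- pts[1, ] - plane$origin
    rel2 <- pts[2, ] - plane$origin
    seg[k, ] <- c(sum(rel1 * u), sum(rel1 * w), sum(rel2 * u), sum(rel2 * w))
  }
  abs(sum(seg[, 1] * seg[, 4] - seg[, 3] * seg[, 2]) / 2)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Offset of the largest neck-parallel cross-section
#'
#' Sweeps cut planes parallel to the neck plane across the sac height and
#' returns the offset (distance from the neck plane) of the largest
#' cross-section area; MDPN in Table-style notation.  Ties resolve to the
#' offset closest to the neck.
#'
#' @param sac closed (capped) `surface_mesh`.
#' @param plane a `plane_frame`.
#' @param n_slices number of uniform offsets in `[0, MPH]`; at least 10.
#' @return MDPN in mm.
#' @export
largest_parallel_section <- function(sac, plane, n_slices = 200L) {
  if (n_slices < 10L) stop("validation error: n_slices must be >= 10")
  mph <- max_plane_distance(sac, plane)
  offs <- seq(0, mph, length.out = n_slices)
  areas <- vapply(offs, function(o) cross_section_area(sac, plane, o),
                  numeric(1))
  offs[which.max(areas)]
}

#' Shadow length of the sac along the parent-vessel axis
#'
#' Extent (max minus min) of the scalar projections of the sac vertices
#' onto the parent-vessel axis; PL.
#'
#' @param sac a `surface_mesh`.
#' @param vessel_axis unit vector.
#' @return PL in mm.
#' @export
projection_length <- function(sac, vessel_axis) {
  p <- as.numeric(sac$vertices %*% vessel_axis)
  max(p) - min(p)
}
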