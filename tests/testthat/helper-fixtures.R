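# fixtures and independent oracles shared across the suite

# closed unit cube, outward-oriented
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front
             c(3, 4, 8), c(3, 8, 7),   # back
             c(1, 5, 8), c(1, 8, 4),   # left
             c(2, 3, 7), c(2, 7, 6))   # right
  surface_mesh(v, f)
}

# open box sac: cube with the bottom face removed (square neck)
open_box_sac <- function() {
  cube <- unit_cube_mesh()
  surface_mesh(cube$vertices, cube$faces[-(1:2), ])
}

hemisphere_geometry <- function(resolution = c(64L, 32L), radius = 1,
                                dpvi = 2, ...) {
  make_sac(sac_spec("hemisphere", radius = radius, resolution = resolution,
                    dpvi = dpvi), ...)$geometry
}

# any off-plane point works as the orientation reference for a flat
# contour; use widely spaced points so straight polygon edges cannot make
# the triple collinear
pl_normal_guess <- function(nc) {
  p <- nc$points
  k <- nrow(p)
  i2 <- 1L + k %/% 3L
  i3 <- 1L + (2L * k) %/% 3L
  n <- aneumorph:::crossprod3(p[i2, ] - p[1, ], p[i3, ] - p[1, ])
  n / sqrt(sum(n^2))
}

# circular polyline in the z = 0 plane
circle_contour <- function(r = 1, n = 64L, z = 0) {
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  neck_contour(cbind(r * cos(phi), r * sin(phi), z))
}

rect_contour <- function(hx = 1, hy = 0.5) {
  neck_contour(rbind(c(hx, hy, 0), c(-hx, hy, 0),
                     c(-hx, -hy, 0), c(hx, -hy, 0)))
}

# O(n^2) reference for the maximum pairwise distance
brute_max_distance <- function(pts) {
  best <- -1
  for (i in seq_len(nrow(pts) - 1L))
    for (j in (i + 1L):nrow(pts)) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d > best) best <- d
    }
  best
}

# brute-force pairwise concordance probability (ties counted 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# independent convex-hull oracle (qhull via scipy)
scipy_hull <- function(pts) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.table(pts, f, sep = ",", row.names = FALSE, col.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import sys,numpy as np\n",
    "from scipy.spatial import ConvexHull\n",
    "p=np.loadtxt(sys.argv[1],delimiter=',')\n",
    "h=ConvexHull(p)\n",
    "print(h.volume,h.area)")), f), stdout = TRUE, stderr = FALSE)
  as.numeric(strsplit(out, " ")[[1]])
}

# names of the dimensionless indices (scale-invariant by construction)
dimensionless_params <- function() {
  c("AR", "BR", "NR", "SR", "DNR", "EI", "NSI", "UI", "PR", "CP",
    "IRR", "ISR", "IOR")
}

# labelled table with a wide linear margin planted across every numeric
# morphological feature (so distance-based learners separate it too)
separable_table <- function(n_each = 60L, seed = 5L) {
  tab <- make_cohort(cohort_spec(n_ruptured = n_each, n_unruptured = n_each,
                                 effect_coefficients = numeric(0),
                                 seed = seed))
  for (nm in setdiff(morph_param_names(), c("LB", "I", "ON")))
    tab[[nm]] <- tab[[nm]] + tab$ruptured * 8 * stats::sd(tab[[nm]])
  tab
}
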