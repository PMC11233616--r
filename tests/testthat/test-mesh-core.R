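test_that("capping closes the sac and rejects closed or mismatched input", {
  g <- hemisphere_geometry(resolution = c(64L, 32L))
  capped <- cap_neck(g$sac, g$neck)
  expect_true(is_watertight(capped))
  expect_false(is_watertight(g$sac))
  expect_error(cap_neck(capped, g$neck), "no boundary loop")

  box <- open_box_sac()
  neck <- neck_contour(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  closed <- cap_neck(box, neck)
  expect_true(is_watertight(closed))
  expect_identical(nrow(closed$faces), nrow(box$faces) + 4L)
  expect_equal(enclosed_volume(closed), 1)

  shifted <- neck_contour(neck$points + 0.5)
  expect_error(cap_neck(box, shifted), "mismatch")
})

test_that("enclosed volume matches closed forms and needs watertight input", {
  expect_equal(enclosed_volume(unit_cube_mesh()), 1)
  g <- hemisphere_geometry(resolution = c(128L, 64L))
  capped <- cap_neck(g$sac, g$neck)
  expect_equal(enclosed_volume(capped), 2 * pi / 3, tolerance = 0.005)
  expect_error(enclosed_volume(g$sac), "watertight")
})

test_that("surface area matches closed forms and scales quadratically", {
  expect_equal(surface_area(unit_cube_mesh()), 6)
  g <- hemisphere_geometry(resolution = c(128L, 64L))
  expect_equal(surface_area(g$sac), 2 * pi, tolerance = 0.005)
  scaled <- surface_mesh(g$sac$vertices * sqrt(2), g$sac$faces)
  expect_equal(surface_area(scaled), 2 * surface_area(g$sac),
               tolerance = 1e-12)
})

test_that("volume and area converge monotonically under mesh refinement", {
  res <- list(c(16L, 8L), c(32L, 16L), c(64L, 32L), c(128L, 64L))
  for (fam in c("hemisphere", "half_ellipsoid")) {
    verr <- aerr <- numeric(0)
    for (r in res) {
      s <- make_sac(sac_spec(fam, radius = 1, semi_axes = c(1, 1, 2),
                             resolution = r))
      tr <- s$truth
      capped <- cap_neck(s$geometry$sac, s$geometry$neck)
      verr <- c(verr, abs(enclosed_volume(capped) - tr$DV) / tr$DV)
      aerr <- c(aerr, abs(surface_area(s$geometry$sac) - tr$DA) / tr$DA)
    }
    expect_true(all(diff(verr) < 0), info = fam)
    expect_true(all(diff(aerr) < 0), info = fam)
  }
})

test_that("Monte-Carlo rejection sampling confirms the divergence-theorem volume", {
  set.seed(404)
  s <- make_sac(sac_spec("lobulated", radius = 1.5, amplitude = 0.3,
                         resolution = c(32L, 16L)))
  capped <- cap_neck(s$geometry$sac, s$geometry$neck)
  dv <- enclosed_volume(capped)
  v <- capped$vertices
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  n <- 2e5
  pts <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]),
               stats::runif(n, lo[3], hi[3]))
  inside <- aneumorph:::points_in_mesh_cpp(pts, v, capped$faces)
  p <- mean(inside)
  vbox <- prod(hi - lo)
  se <- vbox * sqrt(p * (1 - p) / n)
  expect_lt(abs(dv - vbox * p), 3 * se)
})

test_that("neck-plane fit is total-least-squares with sac-side orientation", {
  circ <- circle_contour()
  up <- fit_neck_plane(circ, c(0, 0, 5))
  expect_equal(up$normal, c(0, 0, 1), tolerance = 1e-12)
  down <- fit_neck_plane(circ, c(0, 0, -5))
  expect_equal(down$normal, c(0, 0, -1), tolerance = 1e-12)
  # orthonormal right-handed frame
  B <- cbind(up$in_plane_u, up$in_plane_v, up$normal)
  expect_equal(crossprod(B), diag(3), tolerance = 1e-9, ignore_attr = TRUE)

  # tilt 30 degrees about x
  th <- pi / 6
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  tilted <- neck_contour(circ$points %*% t(Rx))
  pl <- fit_neck_plane(tilted, as.numeric(Rx %*% c(0, 0, 5)))
  expect_equal(pl$normal, as.numeric(Rx %*% c(0, 0, 1)), tolerance = 1e-9)

  line <- neck_contour(cbind(1:5, 2 * (1:5), 3 * (1:5)))
  expect_error(fit_neck_plane(line, c(0, 0, 1)), "collinear")
})

test_that("ostium area and perimeter follow shoelace and polyline definitions", {
  circ <- circle_contour(n = 64L)
  pl <- fit_neck_plane(circ, c(0, 0, 1))
  pm <- polygon_metrics(circ, pl)
  expect_equal(pm$NA_mm2, pi, tolerance = 0.002)
  expect_equal(pm$NC_mm, 2 * pi, tolerance = 0.002)

  rect <- rect_contour()
  plr <- fit_neck_plane(rect, c(0, 0, 1))
  pmr <- polygon_metrics(rect, plr)
  expect_equal(pmr$NA_mm2, 2)
  expect_equal(pmr$NC_mm, 6)

  # perimeter is a 3D curve property: warping lengthens it beyond its shadow
  phi <- 2 * pi * (0:63) / 64
  warped <- neck_contour(cbind(cos(phi), sin(phi), 0.3 * sin(3 * phi)))
  plw <- fit_neck_plane(warped, c(0, 0, 3))
  pmw <- polygon_metrics(warped, plw)
  proj_len <- polygon_metrics(circle_contour(n = 64L), pl)$NC_mm
  expect_gt(pmw$NC_mm, proj_len)

  bow <- neck_contour(rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0)))
  plb <- fit_neck_plane(bow, c(0.5, 0.5, 1))
  expect_error(polygon_metrics(bow, plb), "self-intersect")
})

test_that("maximum diameter equals brute force and respects rigid motions", {
  g <- hemisphere_geometry(resolution = c(64L, 32L))
  md <- max_pairwise_distance(g$sac$vertices)
  expect_equal(md$distance, 2)

  set.seed(77)
  for (i in 1:20) {
    pts <- matrix(stats::rnorm(150), ncol = 3)
    expect_equal(max_pairwise_distance(pts)$distance, brute_max_distance(pts))
  }
  rot <- random_rotation()
  expect_equal(max_pairwise_distance(g$sac$vertices %*% t(rot))$distance,
               md$distance, tolerance = 1e-9)
  expect_error(max_pairwise_distance(matrix(1:3, 1)), "2 points")
})

test_that("convex hull dominates the sac and matches an independent qhull oracle", {
  g <- hemisphere_geometry(resolution = c(128L, 64L))
  capped <- cap_neck(g$sac, g$neck)
  h <- convex_hull_metrics(capped)
  expect_equal(h$hull_volume, 2 * pi / 3, tolerance = 0.005)
  expect_equal(h$hull_area, 3 * pi, tolerance = 0.005)
  # convex body: hull == solid within mesh tolerance
  expect_equal(h$hull_volume, enclosed_volume(capped), tolerance = 0.01)

  lob <- make_sac(sac_spec("lobulated", radius = 1.5, amplitude = 0.3,
                           resolution = c(48L, 24L)))
  lcap <- cap_neck(lob$geometry$sac, lob$geometry$neck)
  expect_gt(convex_hull_metrics(lcap)$hull_volume, enclosed_volume(lcap))

  set.seed(12)
  for (i in 1:5) {
    cloud <- matrix(stats::rnorm(60 + 60 * i), ncol = 3)
    mine <- convex_hull_metrics(cloud)
    orac <- scipy_hull(cloud)
    expect_equal(mine$hull_volume, orac[1], tolerance = 1e-9)
    expect_equal(mine$hull_area, orac[2], tolerance = 1e-9)
  }
  flat <- cbind(matrix(stats::rnorm(20), ncol = 2), 0)
  expect_error(convex_hull_metrics(flat), "degenerate")
})

test_that("heights, parallel sections and shadow lengths match cap geometry", {
  g <- hemisphere_geometry(resolution = c(64L, 32L))
  pl <- fit_neck_plane(g$neck, colMeans(g$sac$vertices))
  expect_equal(max_plane_distance(g$sac, pl), 1, tolerance = 1e-9)
  expect_equal(central_height(g$sac, pl), 1, tolerance = 1e-6)

  ell <- make_sac(sac_spec("half_ellipsoid", semi_axes = c(1, 1, 2),
                           resolution = c(64L, 32L)))$geometry
  ple <- fit_neck_plane(ell$neck, colMeans(ell$sac$vertices))
  expect_equal(max_plane_distance(ell$sac, ple), 2, tolerance = 1e-9)

  cap <- make_sac(sac_spec("spherical_cap", radius = 1, cap_offset = 0.5,
                           resolution = c(64L, 32L)))$geometry
  plc <- fit_neck_plane(cap$neck, colMeans(cap$sac$vertices))
  expect_equal(central_height(cap$sac, plc), 1.5, tolerance = 1e-6)
  ccap <- cap_neck(cap$sac, cap$neck)
  step50 <- 1.5 / 49
  expect_lt(abs(largest_parallel_section(ccap, plc, 50L) - 0.5), step50)
  # halving the step moves the answer by less than one coarse step
  expect_lt(abs(largest_parallel_section(ccap, plc, 100L) -
                largest_parallel_section(ccap, plc, 50L)), step50)
  capped_h <- cap_neck(g$sac, g$neck)
  expect_equal(largest_parallel_section(capped_h, pl, 50L), 0)

  # CPH is one sac point's height, so never exceeds MPH
  for (fam in c("hemisphere", "spherical_cap", "lobulated", "undulated")) {
    s <- make_sac(sac_spec(fam, radius = 1.5, cap_offset = 0.6,
                           resolution = c(32L, 16L)))$geometry
    p <- fit_neck_plane(s$neck, colMeans(s$sac$vertices))
    expect_lte(central_height(s$sac, p),
               max_plane_distance(s$sac, p) + 1e-9)
  }

  # rigid tilt of sac + neck together leaves MPH unchanged
  rot <- random_rotation()
  gt <- transform_geometry(g, rot, c(1, -2, 3))
  plt <- fit_neck_plane(gt$neck, colMeans(gt$sac$vertices))
  expect_equal(max_plane_distance(gt$sac, plt), 1, tolerance = 1e-6)

  expect_equal(projection_length(g$sac, c(1, 0, 0)), 2, tolerance = 1e-9)
  expect_equal(projection_length(g$sac, c(0, 0, 1)), 1, tolerance = 1e-9)
  expect_equal(projection_length(g$sac, c(-1, 0, 0)),
               projection_length(g$sac, c(1, 0, 0)))
})

test_that("lengths, areas and volumes obey their scaling laws", {
  g <- hemisphere_geometry(resolution = c(32L, 16L))
  capped <- cap_neck(g$sac, g$neck)
  v0 <- enclosed_volume(capped)
  a0 <- surface_area(g$sac)
  d0 <- max_pairwise_distance(g$sac$vertices)$distance
  for (s in c(0.5, 2, 3)) {
    sm <- surface_mesh(capped$vertices * s, capped$faces)
    expect_equal(enclosed_volume(sm), s^3 * v0, tolerance = 1e-12)
    so <- surface_mesh(g$sac$vertices * s, g$sac$faces)
    expect_equal(surface_area(so), s^2 * a0, tolerance = 1e-12)
    expect_equal(max_pairwise_distance(so$vertices)$distance, s * d0,
                 tolerance = 1e-12)
  }
})
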