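test_that("neck diameter is the flow-aligned centroid chord", {
  circ <- circle_contour(n = 128L)
  pl <- fit_neck_plane(circ, c(0, 0, 1))
  expect_equal(neck_diameter(circ, pl, c(1, 0, 0)), 2, tolerance = 1e-3)

  rect <- rect_contour(hx = 1, hy = 0.5)
  plr <- fit_neck_plane(rect, c(0, 0, 1))
  expect_equal(neck_diameter(rect, plr, c(1, 0, 0)), 2, tolerance = 1e-9)
  d45 <- c(1, 1, 0) / sqrt(2)
  expect_equal(neck_diameter(rect, plr, d45), sqrt(2), tolerance = 1e-9)
  expect_error(neck_diameter(rect, plr, c(0, 0, 1)), "perpendicular")
})

test_that("angle conventions cover in-plane, normal and oblique cases", {
  circ <- circle_contour()
  pl <- fit_neck_plane(circ, c(0, 0, 1))
  ends <- rbind(c(0, 0, 0), c(1, 0, 1))  # 45 degrees off the plane
  a <- angle_metrics(c(1, 0, 0), ends, pl)
  expect_equal(a$INA, 0)
  expect_equal(a$MDNA, 45, tolerance = 1e-9)
  expect_equal(a$IMDA, 45, tolerance = 1e-9)
  expect_equal(angle_metrics(c(0, 0, 1), ends, pl)$INA, 90)
  # MD vector orientation: from the neck-near endpoint outward
  flipped <- angle_metrics(c(1, 0, 0), ends[2:1, ], pl)
  expect_equal(flipped$IMDA, a$IMDA)
  expect_error(angle_metrics(c(1, 0, 0), rbind(c(1, 1, 1), c(1, 1, 1)), pl),
               "zero-length")
})

test_that("ratio indices follow their defining formulas and flag bad input", {
  base <- list(DV = 2 * pi / 3, DA = 2 * pi, MD = 2, CPH = 1, ND = 2,
               NA_ = pi, DPVI = 2, MPH = 1, MDPN = 0)
  hull <- list(hull_volume = 2 * pi / 3, hull_area = 3 * pi)
  r <- ratio_indices(base, hull)
  expect_equal(r$AR, 0.5)
  expect_equal(r$BR, 1)
  expect_equal(r$NR, 1)
  expect_equal(r$SR, 1)
  expect_equal(r$DNR, 2)
  expect_equal(r$VOA, 2 / 3)
  expect_equal(r$PR, 0.5)
  expect_equal(r$CP, 0.5)
  expect_equal(r$NSI, 0, tolerance = 1e-12)  # (18 pi (2 pi/3)^2)^(1/3) = 2 pi
  expect_equal(r$EI, 1 / 3, tolerance = 1e-12)
  expect_equal(r$UI, 0)
  expect_equal(r$SF, 2 * pi / (2 * pi / 3)^(2 / 3))
  base$ND <- 0
  expect_error(ratio_indices(base, hull), "AR")
})

test_that("roundness and sphericity parameters attain their analytic values", {
  nv <- novel_indices(NA_ = pi, NC = 2 * pi, DV = 2 * pi / 3, DA = 2 * pi,
                      outlet_diameters = 2, DPVI = 2)
  expect_equal(nv$IR, 1)
  expect_equal(nv$IRR, 1)
  expect_equal(nv$IS, 2^(-1 / 3))
  expect_equal(nv$ISR, (4 / 3) * 2^(-2 / 3))

  # square neck of any side: IRR = sqrt(pi)/2
  for (a in c(1, 3)) {
    sq <- novel_indices(NA_ = a^2, NC = 4 * a, DV = 1, DA = 1,
                        outlet_diameters = 1, DPVI = 1)
    expect_equal(sq$IRR, sqrt(pi) / 2)
  }

  out <- novel_indices(NA_ = 1, NC = 4, DV = 1, DA = 1,
                       outlet_diameters = c(1.5, 1.2), DPVI = 2.7)
  expect_identical(out$ON, 2L)
  expect_equal(out$COD, 2.7)
  expect_equal(out$IOR, 1)
  expect_error(novel_indices(1, 4, 1, 1, numeric(0), 2), "outlet")
})

test_that("the full record reproduces hemisphere closed forms within 1%", {
  s <- make_sac(sac_spec("hemisphere", radius = 1, resolution = c(128L, 64L)))
  rec <- compute_all(s$geometry, n_slices = 100L)
  expect_length(unclass(rec), 35L)
  expect_identical(names(rec), morph_param_names())
  for (nm in names(s$truth)) {
    tv <- s$truth[[nm]]
    tol <- if (abs(tv) < 0.5) 0.01 else 0.01 * abs(tv)
    expect_lt(abs(rec[[nm]] - tv), tol + 1e-12)
  }
})

test_that("records are invariant under rigid motion and scaling", {
  spec <- sac_spec("lobulated", radius = 1.5, amplitude = 0.25,
                   resolution = c(32L, 16L))
  g <- make_sac(spec)$geometry
  rec <- compute_all(g, n_slices = 60L)

  set.seed(31)
  moved <- transform_geometry(g, random_rotation(), c(4, -1, 2))
  rec2 <- compute_all(moved, n_slices = 60L)
  for (nm in morph_param_names())
    expect_equal(rec2[[nm]], rec[[nm]], tolerance = 1e-5,
                 info = paste("rigid", nm))

  for (s in c(0.5, 2, 3)) {
    recs <- compute_all(scale_geometry(g, s), n_slices = 60L)
    for (nm in dimensionless_params())
      expect_equal(recs[[nm]], rec[[nm]], tolerance = 1e-9,
                   info = paste("scale", s, nm))
    expect_equal(recs$DV, s^3 * rec$DV, tolerance = 1e-9)
    expect_equal(recs$MD, s * rec$MD, tolerance = 1e-12)
  }
})

test_that("nonsphericity rises with elongation and undulation stays bounded", {
  nsis <- vapply(c(1, 1.5, 2, 3), function(cax) {
    s <- make_sac(sac_spec("half_ellipsoid", semi_axes = c(1, 1, cax),
                           resolution = c(48L, 24L)))
    compute_all(s$geometry, n_slices = 40L)$NSI
  }, numeric(1))
  expect_true(all(diff(nsis) > 0))

  und <- make_sac(sac_spec("undulated", radius = 1.5, amplitude = 0.3,
                           resolution = c(48L, 24L)))
  ru <- compute_all(und$geometry, n_slices = 40L)
  expect_gte(ru$UI, 0)
  expect_gt(ru$UI, 0.001)        # ripples carve real concavity
  expect_lt(ru$IRR, 1 + 1e-9)
  expect_lt(ru$ISR, 1)

  hemi <- compute_all(hemisphere_geometry(resolution = c(64L, 32L)),
                      n_slices = 40L)
  expect_lt(hemi$UI, 0.01)       # convex sac: hull adds nothing
})

test_that("irregularity falls back to the undulation proxy when unannotated", {
  und <- make_sac(sac_spec("undulated", radius = 1.5, amplitude = 0.35,
                           resolution = c(32L, 16L)))$geometry
  rec <- compute_all(und, n_slices = 40L)
  expect_identical(rec$I, as.integer(rec$UI > 0.05))
  flagged <- make_sac(sac_spec("hemisphere", radius = 1,
                               resolution = c(32L, 16L)),
                      irregular = TRUE)$geometry
  expect_identical(compute_all(flagged, n_slices = 40L)$I, 1L)
})
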