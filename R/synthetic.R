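#' Specification of a parametric synthetic sac
#'
#' Describes one member of the five synthetic sac families used as
#' fixtures with (partial) closed-form ground truth:
#' `hemisphere`, `spherical_cap` (super-hemispherical cap of a sphere),
#' `half_ellipsoid`, `lobulated` (two-lobed radial modulation) and
#' `undulated` (radial ripple r(1 + a sin(k theta)sin(k phi)), k = 4).
#' All modulations vanish at the rim, so the neck stays a planar circle
#' (or ellipse) and its ostium metrics keep closed forms.
#'
#' @param family one of the five family names.
#' @param radius sphere/base radius, mm.
#' @param semi_axes length-3 semi-axes (a, b, c) for `half_ellipsoid`, mm.
#' @param cap_offset distance from sphere centre down to the neck plane for
#'   `spherical_cap`, mm (0 gives a hemisphere).
#' @param amplitude modulation amplitude fraction in `[0, 0.5)` for the
#'   lobulated/undulated families.
#' @param resolution integer pair (n_theta azimuthal, n_phi polar rings),
#'   at least (16, 8).
#' @param dpvi parent-vessel inlet diameter, mm.
#' @param outlet_diameters outlet diameters, mm.
#' @param seed integer stored with the spec (generation is deterministic).
#' @return An object of class `sac_spec`.
#' @export
sac_spec <- function(family = c("hemisphere", "spherical_cap",
                                "half_ellipsoid", "lobulated", "undulated"),
                     radius = 2, semi_axes = c(2, 2, 3), cap_offset = 1,
                     amplitude = 0.25, resolution = c(64L, 32L), dpvi = 2,
                     outlet_diameters = 2, seed = 1L) {
  family <- match.arg(family)
  resolution <- as.integer(resolution)
  if (length(resolution) != 2L || resolution[1] < 16L || resolution[2] < 8L)
    stop("validation error: resolution must be at least (16, 8)")
  if (radius <= 0 || any(semi_axes <= 0))
    stop("validation error: radii must be positive")
  if (amplitude < 0 || amplitude >= 0.5)
    stop("validation error: amplitude must be in [0, 0.5)")
  if (family == "spherical_cap" && (cap_offset < 0 || cap_offset >= radius))
    stop("validation error: cap_offset must be in [0, radius)")
  structure(list(family = family, radius = radius, semi_axes = semi_axes,
                 cap_offset = cap_offset, amplitude = amplitude,
                 resolution = resolution, dpvi = dpvi,
                 outlet_diameters = outlet_diameters, seed = as.integer(seed)),
            class = "sac_spec")
}

# polar-grid sac mesh: apex + n_phi rings of n_theta points; the last ring
# is the (open) neck rim
sac_grid_mesh <- function(radial_fn, theta_max, n_theta, n_phi,
                          scale = c(1, 1, 1)) {
  theta <- theta_max * seq_len(n_phi) / n_phi
  phi <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  gr <- expand.grid(phi = phi, theta = theta)
  r <- radial_fn(gr$theta, gr$phi)
  v <- cbind(r * sin(gr$theta) * cos(gr$phi) * scale[1],
             r * sin(gr$theta) * sin(gr$phi) * scale[2],
             r * cos(gr$theta) * scale[3])
  apex <- c(0, 0, radial_fn(0, 0) * scale[3])
  v <- rbind(apex, v)
  idx <- function(k, j) 1L + (k - 1L) * n_theta + (j - 1L) %% n_theta + 1L
  f <- matrix(0L, 0L, 3L)
  jv <- seq_len(n_theta)
  f <- rbind(f, cbind(1L, idx(1L, jv), idx(1L, jv + 1L)))
  for (k in seq_len(n_phi - 1L)) {
    a <- idx(k, jv); a2 <- idx(k, jv + 1L)
    b <- idx(k + 1L, jv); b2 <- idx(k + 1L, jv + 1L)
    f <- rbind(f, cbind(a, b, b2), cbind(a, b2, a2))
  }
  list(mesh = surface_mesh(v, f),
       rim = v[idx(n_phi, jv), , drop = FALSE])
}

#' Generate a synthetic sac geometry with ground truth
#'
#' Builds the triangulated sac for a [sac_spec()] together with the
#' closed-form values available for its family (volumes, areas, heights,
#' ostium metrics and derived indices where exact).  Ellipsoid dome area
#' and neck perimeter truths are evaluated by numerical quadrature of the
#' exact surface/arc-length integrals.
#'
#' @param spec a `sac_spec`.
#' @param ... passed to [aneurysm_geometry()] (e.g. `location`, `sex`,
#'   `age`, `lb_status`, `irregular`, `ruptured`).
#' @return List with `geometry` (an `aneurysm_geometry`) and `truth`
#'   (named list of exact parameter values for this family).
#' @export
make_sac <- function(spec, ...) {
  stopifnot(inherits(spec, "sac_spec"))
  nt <- spec$resolution[1]
  np <- spec$resolution[2]
  R <- spec$radius
  dpvi <- spec$dpvi
  truth <- list()
  scale <- c(1, 1, 1)
  theta_max <- pi / 2
  radial <- function(theta, phi) rep(R, length(theta))

  if (spec$family == "hemisphere") {
    truth <- list(DV = 2 * pi * R^3 / 3, DA = 2 * pi * R^2, `NA` = pi * R^2,
                  NC = 2 * pi * R, MD = 2 * R, CPH = R, MPH = R, MDPN = 0,
                  ND = 2 * R, NSI = 0, UI = 0, IRR = 1, EI = 1 / 3,
                  AR = 0.5, BR = 1, DNR = 2, VOA = 2 * R / 3,
                  NR = 2 * R / dpvi, SR = 2 * R / dpvi, PR = R / dpvi,
                  CP = 0.5, IR = R, IS = R * 2^(-1 / 3),
                  ISR = (4 / 3) * 2^(-2 / 3))
  } else if (spec$family == "spherical_cap") {
    cc <- spec$cap_offset
    h <- R + cc
    rim_r <- sqrt(R^2 - cc^2)
    theta_max <- acos(-cc / R)
    truth <- list(DV = pi * h^2 * (3 * R - h) / 3, DA = 2 * pi * R * h,
                  `NA` = pi * rim_r^2, NC = 2 * pi * rim_r, MD = 2 * R,
                  CPH = h, MPH = h, MDPN = cc, ND = 2 * rim_r, IRR = 1,
                  UI = 0, IR = rim_r)
  } else if (spec$family == "half_ellipsoid") {
    a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; cax <- spec$semi_axes[3]
    scale <- spec$semi_axes / R
    truth <- list(DV = 2 * pi * a * b * cax / 3, `NA` = pi * a * b,
                  CPH = cax, MPH = cax, MDPN = 0, CP = 0.5,
                  UI = 0, IR = sqrt(a * b),
                  NC = ellipse_perimeter(a, b))
    if (abs(a - b) < 1e-12) {
      truth$MD <- half_spheroid_diameter(a, cax)
      truth$DA <- half_spheroid_area(a, cax)
      truth$NSI <- 1 - (18 * pi)^(1 / 3) * truth$DV^(2 / 3) / truth$DA
      truth$IRR <- 1
    }
  } else if (spec$family == "lobulated") {
    a <- spec$amplitude
    radial <- function(theta, phi) R * (1 + a * sin(2 * theta)^2 * cos(2 * phi))
    truth <- list(`NA` = pi * R^2, NC = 2 * pi * R, MPH = R, IRR = 1)
  } else if (spec$family == "undulated") {
    a <- spec$amplitude
    radial <- function(theta, phi) R * (1 + a * sin(4 * theta) * sin(4 * phi))
    truth <- list(`NA` = pi * R^2, NC = 2 * pi * R, IRR = 1)
  }

  gm <- sac_grid_mesh(radial, theta_max, nt, np, scale)
  geometry <- aneurysm_geometry(
    sac = gm$mesh, neck = neck_contour(gm$rim),
    inlet_dir = c(1, 0, 0), vessel_axis = c(1, 0, 0), dpvi = dpvi,
    outlet_diameters = spec$outlet_diameters, ...)
  list(geometry = geometry, truth = truth)
}

# exact perimeter of an ellipse by quadrature of the arc-length integral
ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

# maximum distance between two surface points of a half spheroid
# (a = b, cut at the equator): for elongated domes the extremal pair sits
# at antipodal azimuths and generally unequal heights, so maximise
# (rho(z1) + rho(z2))^2 + (z1 - z2)^2 numerically over a fine grid
half_spheroid_diameter <- function(a, cax) {
  z <- seq(0, cax, length.out = 1200L)
  rho <- a * sqrt(pmax(1 - (z / cax)^2, 0))
  d2 <- outer(rho, rho, "+")^2 + outer(z, z, "-")^2
  sqrt(max(d2))
}

# exact dome area of a half spheroid (semi-axes a = b, c), as the surface
# of revolution of z = c sqrt(1 - rho^2/a^2)
half_spheroid_area <- function(a, cax) {
  f <- function(rho) {
    dz <- -cax * rho / (a^2 * sqrt(pmax(1 - rho^2 / a^2, 1e-300)))
    2 * pi * rho * sqrt(1 + dz^2)
  }
  stats::integrate(f, 0, a, rel.tol = 1e-9, subdivisions = 2000L)$value
}

#' Apply a rigid motion to an aneurysm geometry
#'
#' Rotates and translates the sac, neck contour and the two direction
#' vectors together, so every morphological parameter is preserved.
#'
#' @param geometry an `aneurysm_geometry`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 offset, mm.
#' @return The transformed `aneurysm_geometry`.
#' @export
transform_geometry <- function(geometry, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  stopifnot(inherits(geometry, "aneurysm_geometry"))
  g <- geometry
  tr <- function(p) sweep(p %*% t(rotation), 2, -translation)
  g$sac <- surface_mesh(tr(g$sac$vertices), g$sac$faces)
  g$neck <- neck_contour(tr(g$neck$points))
  g$inlet_dir <- as.numeric(rotation %*% g$inlet_dir)
  g$vessel_axis <- as.numeric(rotation %*% g$vessel_axis)
  g
}

#' Uniformly scale an aneurysm geometry
#'
#' @param geometry an `aneurysm_geometry`.
#' @param factor positive scale factor applied to all lengths (including
#'   DPVI and outlet diameters), so dimensionless indices are invariant.
#' @return The scaled `aneurysm_geometry`.
#' @export
scale_geometry <- function(geometry, factor) {
  stopifnot(inherits(geometry, "aneurysm_geometry"), factor > 0)
  g <- geometry
  g$sac <- surface_mesh(g$sac$vertices * factor, g$sac$faces)
  g$neck <- neck_contour(g$neck$points * factor)
  g$dpvi <- g$dpvi * factor
  g$outlet_diameters <- g$outlet_diameters * factor
  g
}

#' Random sac specification
#'
#' Draws a random family and random parameters within the generator's
#' plausible clinical ranges (radii 1--4 mm, moderate amplitudes and
#' elongations).  Uses the current RNG stream.
#'
#' @param resolution passed through to [sac_spec()].
#' @return A `sac_spec`.
#' @export
random_sac_spec <- function(resolution = c(48L, 24L)) {
  fam <- sample(c("hemisphere", "spherical_cap", "half_ellipsoid",
                  "lobulated", "undulated"), 1L)
  R <- stats::runif(1, 1, 4)
  sac_spec(family = fam, radius = R,
           semi_axes = c(R, R * stats::runif(1, 0.7, 1.3),
                         R * stats::runif(1, 0.8, 2.5)),
           cap_offset = stats::runif(1, 0.05, 0.9) * R,
           amplitude = stats::runif(1, 0.05, 0.35),
           resolution = resolution,
           dpvi = stats::runif(1, 1.5, 4),
           outlet_diameters = stats::runif(sample(1:3, 1L), 1, 3))
}

#' Random planar neck contour (non-circular)
#'
#' Generates a simple planar polygonal contour -- a Fourier-perturbed
#' ellipse or a convex polygon -- embedded in 3D with a random rigid
#' motion.  Used to exercise the isoperimetric bound IRR < 1.
#'
#' @param n_points number of polyline points.
#' @return A `neck_contour`.
#' @export
random_neck_contour <- function(n_points = 64L) {
  kind <- sample(c("ellipse", "polygon"), 1L)
  phi <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  if (kind == "ellipse") {
    a <- stats::runif(1, 1, 3)
    b <- a * stats::runif(1, 0.4, 0.9)
    k <- sample(2:5, 1L)
    amp <- stats::runif(1, 0.02, 0.15)
    r <- 1 + amp * cos(k * phi + stats::runif(1, 0, 2 * pi))
    xy <- cbind(a * r * cos(phi), b * r * sin(phi))
  } else {
    ns <- sample(3:9, 1L)
    rad <- stats::runif(1, 1, 3)
    ang <- 2 * pi * (seq_len(ns) - 1L) / ns
    vx <- rad * cos(ang)
    vy <- rad * stats::runif(1, 0.4, 0.9) * sin(ang)
    seg <- findInterval(phi, ang, rightmost.closed = FALSE)
    t <- (phi - ang[seg]) / (2 * pi / ns)
    nxt <- seg %% ns + 1L
    xy <- cbind(vx[seg] + t * (vx[nxt] - vx[seg]),
                vy[seg] + t * (vy[nxt] - vy[seg]))
  }
  rot <- random_rotation()
  p3 <- cbind(xy, 0) %*% t(rot)
  p3 <- sweep(p3, 2, stats::runif(3, -5, 5), "+")
  neck_contour(p3)
}

#' Random 3D rotation matrix
#'
#' Uniform random rotation built from a normalised quaternion drawn from
#' the current RNG stream.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## ---- synthetic cohorts -----------------------------------------------------

#' Specification of a synthetic labelled cohort
#'
#' The defaults reproduce the study conditions the cohort emulates: 253
#' ruptured and 456 unruptured records, rupture risk planted through a
#' logistic model on standardized features with log-odds weights on the
#' ellipticity index, size ratio and irregularity.
#'
#' @param n_ruptured number of ruptured records.
#' @param n_unruptured number of unruptured records.
#' @param effect_coefficients named numeric vector of per-feature log-odds
#'   weights on standardized features (names must be feature columns).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ruptured = 253L, n_unruptured = 456L,
                        effect_coefficients = c(EI = 1.2, SR = 0.8, I = 0.6),
                        seed = 1L) {
  if (n_ruptured < 0L || n_unruptured < 0L)
    stop("validation error: cohort counts must be >= 0")
  if (length(effect_coefficients) &&
      !all(names(effect_coefficients) %in% morph_param_names()))
    stop("validation error: effect coefficients must name morphological features")
  structure(list(n_ruptured = as.integer(n_ruptured),
                 n_unruptured = as.integer(n_unruptured),
                 effect_coefficients = effect_coefficients,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# one batch of plausible morphological + clinical features.  Each
# parameter is drawn from its own clinically plausible marginal, nearly
# independently of the others: the generator aims at marginal
# plausibility and at sharp feature attribution (a planted effect must be
# recoverable from its own column), not at reproducing the inter-feature
# covariance of real measured cohorts.
generate_feature_batch <- function(n) {
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  DPVI <- stats::rlnorm(n, log(3.0), 0.18)
  DV <- stats::rlnorm(n, log(70), 0.6)
  NAv <- stats::rlnorm(n, log(9), 0.45)
  MDPN <- stats::rlnorm(n, log(1.2), 0.5)
  LB <- stats::rbinom(n, 1L, 0.62)
  ON <- ifelse(LB == 1L, sample(2:3, n, replace = TRUE), 1L)
  COD <- ON * stats::rlnorm(n, log(2.4), 0.25)
  df <- data.frame(
    DV = DV,
    DA = stats::rlnorm(n, log(85), 0.5),
    MD = stats::rlnorm(n, log(5.5), 0.35),
    CPH = stats::rlnorm(n, log(4.2), 0.35),
    ND = stats::rlnorm(n, log(3.2), 0.30), check.names = FALSE)
  df[["NA"]] <- NAv
  df$DPVI <- DPVI
  df$MPH <- stats::rlnorm(n, log(4.6), 0.35)
  df$IMDA <- clamp(stats::rnorm(n, 115, 25), 5, 175)
  df$MDNA <- clamp(stats::rnorm(n, 55, 15), 5, 88)
  df$INA <- clamp(stats::rnorm(n, 32, 14), 2, 88)
  df$PL <- stats::rlnorm(n, log(5.5), 0.35)
  df$MDPN <- MDPN
  df$LB <- LB
  df$I <- stats::rbinom(n, 1L, 0.33)
  df$AR <- stats::rlnorm(n, log(1.3), 0.30)
  df$BR <- stats::rlnorm(n, log(1.7), 0.25)
  df$NR <- stats::rlnorm(n, log(1.05), 0.25)
  df$SR <- stats::rlnorm(n, log(1.8), 0.35)
  df$DNR <- stats::rlnorm(n, log(2.2), 0.35)
  df$SF <- stats::rlnorm(n, log(4.5), 0.20)
  df$VOA <- stats::rlnorm(n, log(2.2), 0.40)
  df$EI <- clamp(stats::rnorm(n, 0.35, 0.12), 0.02, 0.90)
  df$NSI <- clamp(stats::rnorm(n, 0.18, 0.08), 0.01, 0.60)
  df$UI <- stats::rbeta(n, 1.1, 8) * 0.5
  df$PR <- stats::rlnorm(n, log(1.5), 0.35)
  df$CP <- clamp(stats::rnorm(n, 0.10, 0.18), -0.80, 0.50)
  df$NC <- stats::rlnorm(n, log(10.5), 0.30)
  df$IR <- stats::rlnorm(n, log(1.7), 0.22)
  df$IRR <- 1 - stats::rbeta(n, 1.2, 10) * 0.5
  df$IS <- stats::rlnorm(n, log(2.55), 0.20)
  df$ISR <- clamp(stats::rnorm(n, 0.75, 0.12), 0.20, 0.999)
  df$ON <- ON
  df$COD <- COD
  df$IOR <- stats::rlnorm(n, log(0.8), 0.30)
  df$age <- clamp(stats::rnorm(n, 55, 12), 18, 90)
  df$sex <- sample(c("female", "male"), n, replace = TRUE,
                   prob = c(0.68, 0.32))
  df$location <- sample(aneurysm_locations(), n, replace = TRUE,
                        prob = c(0.30, 0.26, 0.19, 0.10, 0.08, 0.07))
  df[, setdiff(feature_table_columns(), "ruptured")]
}

#' Generate a labelled synthetic cohort
#'
#' Draws feature records from the structural generator and labels them with
#' a planted logistic model on standardized features, then assembles the
#' requested case-control composition (exactly `n_ruptured` ruptured and
#' `n_unruptured` unruptured rows), mimicking how a retrospective clinical
#' cohort is collected.  Bit-reproducible for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame feature table with the 39 canonical columns.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n_total <- spec$n_ruptured + spec$n_unruptured
  base_rate <- if (n_total > 0) spec$n_ruptured / n_total else 0.5
  base_rate <- min(max(base_rate, 0.05), 0.95)
  pool <- NULL
  labs <- integer(0)
  while (sum(labs == 1L) < spec$n_ruptured ||
         sum(labs == 0L) < spec$n_unruptured) {
    batch <- generate_feature_batch(max(1000L, n_total))
    lp <- rep(stats::qlogis(base_rate), nrow(batch))
    for (nm in names(spec$effect_coefficients)) {
      x <- batch[[nm]]
      s <- stats::sd(x)
      z <- if (s > 0) (x - mean(x)) / s else x * 0
      lp <- lp + spec$effect_coefficients[[nm]] * z
    }
    y <- stats::rbinom(nrow(batch), 1L, stats::plogis(lp))
    pool <- rbind(pool, batch)
    labs <- c(labs, y)
  }
  idx <- c(which(labs == 1L)[seq_len(spec$n_ruptured)],
           which(labs == 0L)[seq_len(spec$n_unruptured)])
  out <- pool[idx, , drop = FALSE]
  out$ruptured <- labs[idx]
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# save/restore the global RNG state so generators are seed-local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
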