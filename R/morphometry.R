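#' Angle metrics of an aneurysm
#'
#' Three angles, in degrees, relating the inlet flow, the maximum-diameter
#' axis and the neck plane: `IMDA` (inlet flow vs MD vector, 0--180),
#' `MDNA` (MD vector vs neck plane, 0--90) and `INA` (inlet flow vs neck
#' plane, 0--90).  The MD vector is oriented from the endpoint nearer the
#' neck centroid to the farther one.
#'
#' @param inlet_dir unit 3-vector.
#' @param md_endpoints 2 x 3 matrix from [max_pairwise_distance()].
#' @param plane a `plane_frame`.
#' @return Named list `IMDA`, `MDNA`, `INA` (degrees).
#' @export
angle_metrics <- function(inlet_dir, md_endpoints, plane) {
  d <- sqrt(rowSums(sweep(md_endpoints, 2, plane$origin)^2))
  ends <- if (d[1] <= d[2]) md_endpoints else md_endpoints[2:1, , drop = FALSE]
  md_vec <- ends[2, ] - ends[1, ]
  L <- sqrt(sum(md_vec^2))
  if (L < 1e-12) stop("geometry error: zero-length MD vector")
  md_vec <- md_vec / L
  clamp1 <- function(x) pmin(1, pmax(-1, x))
  imda <- acos(clamp1(sum(inlet_dir * md_vec))) * 180 / pi
  mdna <- asin(clamp1(abs(sum(md_vec * plane$normal)))) * 180 / pi
  ina <- asin(clamp1(abs(sum(inlet_dir * plane$normal)))) * 180 / pi
  list(IMDA = imda, MDNA = mdna, INA = ina)
}

#' Derived ratio indices
#'
#' The 12 dimensionless (or scale-carrying) indices built from the measured
#' quantities and the convex-hull result:
#' \deqn{AR = CPH/ND,\; BR = MD/ND,\; NR = ND/DPVI,\; SR = MD/DPVI,}
#' \deqn{DNR = DA/NA,\; SF = DA/DV^{2/3},\; VOA = DV/NA,}
#' \deqn{EI = 1 - (18\pi)^{1/3} DV_{CH}^{2/3}/DA_{CH},\quad
#'       NSI = 1 - (18\pi)^{1/3} DV^{2/3}/DA,}
#' \deqn{UI = 1 - DV/DV_{CH},\; PR = MPH/DPVI,\; CP = 0.5 - MDPN/DPVI.}
#' NSI is normalised so that a hemispherical dome scores zero; EI uses the
#' hull of the closed sac, so a hemisphere scores 1/3.
#'
#' @param base named list with `DV`, `DA`, `MD`, `CPH`, `ND`, `NA_`, `DPVI`,
#'   `MPH`, `MDPN` (NA_ is the neck area; trailing underscore avoids R's
#'   missing-value literal).
#' @param hull list with `hull_volume`, `hull_area` from
#'   [convex_hull_metrics()].
#' @return Named list of the 12 indices.
#' @export
ratio_indices <- function(base, hull) {
  need <- c("DV", "DA", "MD", "CPH", "ND", "NA_", "DPVI", "MPH", "MDPN")
  for (nm in need) if (is.null(base[[nm]]))
    stop("computation error: missing base quantity ", nm)
  div <- function(num, den, index) {
    if (!is.finite(den) || den == 0)
      stop("computation error: zero denominator in ", index)
    num / den
  }
  k <- (18 * pi)^(1 / 3)
  list(
    AR = div(base$CPH, base$ND, "AR"),
    BR = div(base$MD, base$ND, "BR"),
    NR = div(base$ND, base$DPVI, "NR"),
    SR = div(base$MD, base$DPVI, "SR"),
    DNR = div(base$DA, base$NA_, "DNR"),
    SF = div(base$DA, base$DV^(2 / 3), "SF"),
    VOA = div(base$DV, base$NA_, "VOA"),
    EI = 1 - k * div(hull$hull_volume^(2 / 3), hull$hull_area, "EI"),
    NSI = 1 - k * div(base$DV^(2 / 3), base$DA, "NSI"),
    # the hull dominates the solid exactly; clamp away hull-tolerance dust
    UI = max(0, 1 - div(base$DV, hull$hull_volume, "UI")),
    PR = div(base$MPH, base$DPVI, "PR"),
    CP = 0.5 - div(base$MDPN, base$DPVI, "CP"))
}

#' Isoperimetric roundness, sphericity and outlet parameters
#'
#' The eight parameters extending the classical battery:
#' \deqn{IR = \sqrt{NA/\pi},\quad IRR = 2\pi\,IR/NC,}
#' \deqn{IS = (3 DV/4\pi)^{1/3},\quad ISR = 4\pi\,IS^2/(DA + NA),}
#' ON = number of outlets, COD = sum of outlet diameters, IOR = DPVI/COD.
#' IRR and ISR are isoperimetric scores bounded above by 1: among planar
#' shapes of equal area the circle has the smallest perimeter, and among
#' solids of equal volume the sphere has the smallest surface.
#'
#' @param NA_ neck area, mm^2.
#' @param NC neck perimeter, mm.
#' @param DV dome volume, mm^3.
#' @param DA dome area, mm^2.
#' @param outlet_diameters numeric vector of outlet diameters, mm.
#' @param DPVI parent-vessel inlet diameter, mm.
#' @return Named list `IR`, `IRR`, `IS`, `ISR`, `ON`, `COD`, `IOR`.
#' @export
novel_indices <- function(NA_, NC, DV, DA, outlet_diameters, DPVI) {
  if (any(c(NA_, NC, DV, DA, DPVI) <= 0))
    stop("computation error: NA, NC, DV, DA, DPVI must be positive")
  if (length(outlet_diameters) < 1L)
    stop("validation error: outlet_diameters: empty outlet list")
  ir <- sqrt(NA_ / pi)
  is_ <- (3 * DV / (4 * pi))^(1 / 3)
  cod <- sum(outlet_diameters)
  list(IR = ir,
       IRR = 2 * pi * ir / NC,
       IS = is_,
       ISR = 4 * pi * is_^2 / (DA + NA_),
       ON = length(outlet_diameters),
       COD = cod,
       IOR = DPVI / cod)
}

#' Compute the full morphological record of an aneurysm
#'
#' Orchestrates the geometric primitives into the complete battery of 35
#' named morphological parameters (measured quantities, ratio indices and
#' the roundness/sphericity/outlet parameters).  Deterministic for a fixed
#' input.
#'
#' @param geometry a validated `aneurysm_geometry`.
#' @param n_slices slice count for the largest-parallel-section sweep.
#' @return An object of class `morphometrics_record`: a named list with
#'   exactly the 35 fields of [morph_param_names()], plus attributes
#'   carrying the clinical fields (`age`, `sex`, `location`, `ruptured`).
#' @export
compute_all <- function(geometry, n_slices = 200L) {
  stopifnot(inherits(geometry, "aneurysm_geometry"))
  g <- geometry
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, ": ", conditionMessage(e), call. = FALSE))
  }
  capped <- step("DV", cap_neck(g$sac, g$neck))
  DV <- step("DV", enclosed_volume(capped))
  DA <- step("DA", surface_area(g$sac))
  sac_centroid <- colMeans(g$sac$vertices)
  plane <- step("MPH", fit_neck_plane(g$neck, sac_centroid))
  pm <- step("NA", polygon_metrics(g$neck, plane))
  md <- step("MD", max_pairwise_distance(g$sac$vertices))
  MPH <- step("MPH", max_plane_distance(g$sac, plane))
  CPH <- step("CPH", central_height(g$sac, plane))
  MDPN <- step("MDPN", largest_parallel_section(capped, plane, n_slices))
  PL <- step("PL", projection_length(g$sac, g$vessel_axis))
  ND <- step("ND", neck_diameter(g$neck, plane, g$inlet_dir))
  ang <- step("IMDA", angle_metrics(g$inlet_dir, md$endpoints, plane))
  hull <- step("EI", convex_hull_metrics(capped))
  base <- list(DV = DV, DA = DA, MD = md$distance, CPH = CPH, ND = ND,
               NA_ = pm$NA_mm2, DPVI = g$dpvi, MPH = MPH, MDPN = MDPN)
  ratios <- ratio_indices(base, hull)
  novel <- novel_indices(pm$NA_mm2, pm$NC_mm, DV, DA, g$outlet_diameters,
                         g$dpvi)
  irregular <- if (is.null(g$irregular)) ratios$UI > 0.05 else isTRUE(g$irregular)
  rec <- c(list(DV = DV, DA = DA, MD = md$distance, CPH = CPH, ND = ND),
           stats::setNames(list(pm$NA_mm2), "NA"),
           list(DPVI = g$dpvi, MPH = MPH, IMDA = ang$IMDA, MDNA = ang$MDNA,
                INA = ang$INA, PL = PL, MDPN = MDPN,
                LB = as.integer(g$lb_status == "bifurcation"),
                I = as.integer(irregular)),
           ratios, list(NC = pm$NC_mm), novel)
  rec <- rec[morph_param_names()]
  structure(rec, class = "morphometrics_record",
            age = g$age, sex = g$sex, location = g$location,
            ruptured = if (is.null(g$ruptured)) NA_integer_ else
              as.integer(g$ruptured))
}

#' @export
print.morphometrics_record <- function(x, digits = 4, ...) {
  cat("morphometrics_record (35 parameters):\n")
  print(vapply(unclass(x), function(v) signif(as.numeric(v), digits),
               numeric(1)))
  invisible(x)
}

#' @export
as.data.frame.morphometrics_record <- function(x, ...) {
  df <- as.data.frame(unclass(x), check.names = FALSE)
  df$age <- attr(x, "age")
  df$sex <- attr(x, "sex")
  df$location <- attr(x, "location")
  df$ruptured <- attr(x, "ruptured")
  df
}
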