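#' Aneurysm geometry container
#'
#' Bundles the open sac mesh, neck contour and the clinical / vessel
#' annotations that the morphological battery consumes.
#'
#' @param sac open `surface_mesh` (dome surface only, open along the neck).
#' @param neck a `neck_contour`.
#' @param inlet_dir unit 3-vector, flow direction at the inlet.
#' @param vessel_axis unit 3-vector, parent-vessel axis.
#' @param dpvi parent-vessel diameter before the aneurysm, mm (> 0).
#' @param outlet_diameters numeric vector of outlet diameters, mm (>= 1 outlet).
#' @param lb_status `"lateral"` or `"bifurcation"`.
#' @param irregular logical irregularity flag, or `NULL` to fall back to the
#'   undulation proxy `UI > 0.05` at measurement time.
#' @param location one of `"ICA"`, `"MCA"`, `"ACA"`, `"PCA"`, `"BA/VA"`, `"other"`.
#' @param sex `"female"` or `"male"`.
#' @param age patient age in years.
#' @param ruptured optional logical rupture label.
#' @return An object of class `aneurysm_geometry`.
#' @export
aneurysm_geometry <- function(sac, neck, inlet_dir, vessel_axis, dpvi,
                              outlet_diameters, lb_status = "lateral",
                              irregular = NULL, location = "other",
                              sex = "female", age = NA_real_,
                              ruptured = NULL) {
  stopifnot(inherits(sac, "surface_mesh"), inherits(neck, "neck_contour"))
  inlet_dir <- as.numeric(inlet_dir)
  vessel_axis <- as.numeric(vessel_axis)
  if (length(inlet_dir) != 3L || abs(sqrt(sum(inlet_dir^2)) - 1) > 1e-9)
    stop("validation error: inlet_dir: must be a unit 3-vector")
  if (length(vessel_axis) != 3L || abs(sqrt(sum(vessel_axis^2)) - 1) > 1e-9)
    stop("validation error: vessel_axis: must be a unit 3-vector")
  dpvi <- as.numeric(dpvi)
  if (length(dpvi) != 1L || !is.finite(dpvi) || dpvi <= 0)
    stop("validation error: dpvi: must be a positive scalar (mm)")
  outlet_diameters <- as.numeric(outlet_diameters)
  if (length(outlet_diameters) < 1L || any(!is.finite(outlet_diameters)) ||
      any(outlet_diameters <= 0))
    stop("validation error: outlet_diameters: need >= 1 positive diameter")
  lb_status <- match.arg(lb_status, c("lateral", "bifurcation"))
  location <- match.arg(location, aneurysm_locations())
  sex <- match.arg(sex, c("female", "male"))
  structure(list(sac = sac, neck = neck, inlet_dir = inlet_dir,
                 vessel_axis = vessel_axis, dpvi = dpvi,
                 outlet_diameters = outlet_diameters, lb_status = lb_status,
                 irregular = irregular, location = location, sex = sex,
                 age = as.numeric(age), ruptured = ruptured),
            class = "aneurysm_geometry")
}

#' Location vocabulary for aneurysms in the Circle of Willis
#' @return Character vector of the six recognised location codes.
#' @export
aneurysm_locations <- function() {
  c("ICA", "MCA", "ACA", "PCA", "BA/VA", "other")
}

#' @export
print.aneurysm_geometry <- function(x, ...) {
  cat(sprintf(paste0("aneurysm_geometry: %d sac vertices, %d neck points, ",
                     "%s, %s, DPVI %.2f mm, %d outlet(s)\n"),
              nrow(x$sac$vertices), nrow(x$neck$points), x$lb_status,
              x$location, x$dpvi, length(x$outlet_diameters)))
  invisible(x)
}

## ---- mesh file formats ----------------------------------------------------

#' Read a triangulated mesh file
#'
#' Supports STL (ASCII and binary), Wavefront OBJ and ASCII PLY.  The
#' format is inferred from the file extension.
#'
#' @param path path to the mesh file.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("input error: mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         obj = read_obj(path),
         ply = read_ply(path),
         stop("input error: unsupported mesh format: .", ext))
}

#' Write a triangulated mesh file
#'
#' @param mesh a `surface_mesh`.
#' @param path output path; extension selects the format (`.stl` ASCII,
#'   `.obj`, `.ply` ASCII).
#' @param binary write binary STL instead of ASCII (STL only).
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stop("input error: unsupported mesh format: .", ext))
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  fsize <- file.info(path)$size
  if (length(ntri) == 1L && is.finite(ntri) && fsize == 84 + 50 * ntri) {
    raw <- readBin(con, "raw", n = 50L * ntri)
    m <- matrix(raw, nrow = 50L)
    tri <- vapply(seq_len(ntri), function(i)
      readBin(m[1:48, i], "numeric", n = 12L, size = 4L, endian = "little"),
      numeric(12))
    verts <- matrix(as.numeric(tri[4:12, ]), ncol = 3L, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("input error: unparseable STL file: ", path)
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  }
  if (anyNA(verts)) stop("input error: unparseable STL file: ", path)
  mesh_from_triangle_soup(verts)
}

# weld duplicate vertices of a triangle soup (STL stores 3 verts/face)
mesh_from_triangle_soup <- function(verts, digits = 9L) {
  key <- apply(round(verts, digits), 1, paste, collapse = ",")
  uid <- !duplicated(key)
  vmap <- match(key, key[uid])
  v <- verts[uid, , drop = FALSE]
  f <- matrix(vmap, ncol = 3L, byrow = TRUE)
  surface_mesh(v, f)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid aneumorph", con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- crossprod3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    n <- n / max(sqrt(sum(n^2)), 1e-300)
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         tri[, 1], tri[, 2], tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid aneumorph", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- crossprod3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    n <- n / max(sqrt(sum(n^2)), 1e-300)
    writeBin(as.numeric(c(n, t(tri))), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("input error: unparseable OBJ file: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- vapply(strsplit(x[-1], "/"), function(p) as.integer(p[1]), integer(1))
    if (length(idx) != 3L) stop("input error: OBJ faces must be triangles")
    idx
  }))
  surface_mesh(v, f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.12g %.12g %.12g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3L || txt[1] != "ply" || !grepl("ascii", txt[2]))
    stop("input error: only ASCII PLY is supported: ", path)
  hend <- match("end_header", txt)
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", txt, value = TRUE)[1]))
  if (is.na(hend) || is.na(nv) || is.na(nf))
    stop("input error: unparseable PLY header: ", path)
  body <- txt[(hend + 1L):length(txt)]
  v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                             function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("input error: PLY faces must be triangles")
    x[2:4] + 1L
  }))
  surface_mesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

## ---- annotation sidecar ----------------------------------------------------

#' Read an aneurysm geometry (mesh + JSON annotation sidecar)
#'
#' The annotation is a JSON document with keys `neck_points` (k x 3 array),
#' `inlet_dir`, `vessel_axis`, `dpvi_mm`, `outlet_diameters_mm`,
#' `lb_status`, `irregular`, `location`, `sex`, `age`, `ruptured`.
#'
#' @param mesh_path path to the sac mesh (STL/OBJ/PLY).
#' @param annotation_path path to the JSON sidecar.
#' @return A validated `aneurysm_geometry`.
#' @export
read_geometry <- function(mesh_path, annotation_path) {
  sac <- read_mesh(mesh_path)
  if (!file.exists(annotation_path))
    stop("input error: annotation file not found: ", annotation_path)
  ann <- tryCatch(jsonlite::read_json(annotation_path, simplifyVector = TRUE),
                  error = function(e)
                    stop("input error: unparseable annotation JSON: ",
                         conditionMessage(e)))
  need <- c("neck_points", "inlet_dir", "vessel_axis", "dpvi_mm",
            "outlet_diameters_mm")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("validation error: ", sub("_points|_dir|_axis|_mm.*", "",
                                   miss[1]),
         ": annotation missing required key(s): ",
         paste(miss, collapse = ", "))
  np <- ann$neck_points
  if (!is.matrix(np)) np <- do.call(rbind, lapply(np, as.numeric))
  neck <- neck_contour(np)
  aneurysm_geometry(
    sac = sac, neck = neck, inlet_dir = ann$inlet_dir,
    vessel_axis = ann$vessel_axis, dpvi = ann$dpvi_mm,
    outlet_diameters = ann$outlet_diameters_mm,
    lb_status = ann$lb_status %||% "lateral",
    irregular = ann$irregular,
    location = ann$location %||% "other",
    sex = ann$sex %||% "female",
    age = ann$age %||% NA_real_,
    ruptured = ann$ruptured)
}

#' Write an aneurysm geometry as mesh file + JSON annotation sidecar
#'
#' @param geometry an `aneurysm_geometry`.
#' @param mesh_path output mesh path (format from extension).
#' @param annotation_path output JSON path.
#' @return Invisibly, the two paths.
#' @export
write_geometry <- function(geometry, mesh_path, annotation_path) {
  stopifnot(inherits(geometry, "aneurysm_geometry"))
  write_mesh(geometry$sac, mesh_path)
  ann <- list(neck_points = geometry$neck$points,
              inlet_dir = geometry$inlet_dir,
              vessel_axis = geometry$vessel_axis,
              dpvi_mm = geometry$dpvi,
              outlet_diameters_mm = geometry$outlet_diameters,
              lb_status = geometry$lb_status,
              irregular = geometry$irregular,
              location = geometry$location,
              sex = geometry$sex,
              age = geometry$age,
              ruptured = geometry$ruptured)
  drop <- vapply(ann, function(v)
    is.null(v) || (length(v) == 1L && !is.character(v) && is.na(v)),
    logical(1))
  jsonlite::write_json(ann[!drop], annotation_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(mesh_path, annotation_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- feature tables --------------------------------------------------------

#' Canonical morphological parameter names
#'
#' The 35 parameter abbreviations in canonical column order: the 15 measured
#' quantities, the 12 derived ratio indices, and the 8 neck/sac roundness,
#' sphericity and outlet parameters.
#'
#' @return Character vector of length 35.
#' @export
morph_param_names <- function() {
  c("DV", "DA", "MD", "CPH", "ND", "NA", "DPVI", "MPH", "IMDA", "MDNA",
    "INA", "PL", "MDPN", "LB", "I",
    "AR", "BR", "NR", "SR", "DNR", "SF", "VOA", "EI", "NSI", "UI", "PR", "CP",
    "NC", "IR", "IRR", "IS", "ISR", "ON", "COD", "IOR")
}

feature_table_columns <- function() {
  c(morph_param_names(), "age", "sex", "location", "ruptured")
}

#' Write a cohort feature table to CSV
#'
#' Column order is fixed: the 35 morphological parameters in canonical
#' order, then `age`, `sex`, `location`, `ruptured` (39 columns).
#'
#' @param records a data.frame with the canonical columns, or a list of
#'   `morphometrics_record` objects each carrying clinical fields.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(records, path) {
  if (!is.data.frame(records)) records <- do.call(rbind, lapply(records, as.data.frame))
  cols <- feature_table_columns()
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(records), cols)
  if (length(extra))
    stop("schema error: unexpected column(s): ", paste(extra, collapse = ", "))
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a cohort feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return A data.frame with the 39 canonical columns; numeric fields are
#'   numeric, `sex`/`location` character, `ruptured` integer 0/1.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("input error: feature table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- feature_table_columns()
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[, cols]
  num <- setdiff(cols, c("sex", "location"))
  for (cn in num) tab[[cn]] <- as.numeric(tab[[cn]])
  tab$ruptured <- as.integer(tab$ruptured)
  bad <- setdiff(unique(tab$location), aneurysm_locations())
  if (length(bad))
    stop("schema error: unknown location(s): ", paste(bad, collapse = ", "))
  tab
}
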