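# Voxel phantom construction: HU -> density and HU -> elemental composition
# calibrations, plain-text slice-series voxelization, couch merging, and the
# fixture-phantom generators.

#' HU to mass density calibration
#'
#' Piecewise-linear mapping from Hounsfield units to g/cm3, anchored so that
#' HU 0 maps to water (1.000) and HU -1000 to standard air density. The
#' packaged default follows the four-group stoichiometric scheme; HU outside
#' the node range are clamped.
#'
#' @param path CSV with columns `hu,density_g_cm3` (default: packaged
#'   calibration).
#' @return a `density_calibration`.
#' @export
density_calibration <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "density_calibration.csv",
                        package = "ctdosim")
  df <- read.csv(path, comment.char = "#")
  stopifnot(!is.unsorted(df$hu), all(df$density_g_cm3 >= 0))
  structure(list(hu = df$hu, density = df$density_g_cm3),
            class = "density_calibration")
}

#' Convert HU to density
#' @param hu Hounsfield units (vectorized); clamped to the calibration range.
#' @param cal a `density_calibration` (default packaged).
#' @return densities, g/cm3.
#' @export
hu_to_density <- function(hu, cal = density_calibration()) {
  approx(cal$hu, cal$density, xout = pmin(pmax(hu, min(cal$hu)),
                                          max(cal$hu)), rule = 2)$y
}

# inverse on the nondecreasing branch (HU >= -1000); used by fixtures
.density_to_hu <- function(density, cal = density_calibration()) {
  keep <- cal$hu >= -1000
  approx(cal$density[keep], cal$hu[keep],
         xout = pmin(pmax(density, min(cal$density[keep])),
                     max(cal$density[keep])), rule = 2, ties = "ordered")$y
}

#' HU to elemental composition table
#'
#' Inclusive integer HU ranges mapping to weight fractions over
#' {H, O, C, N, Cl, Ca, P, Mg}. Validated at load: ranges ordered,
#' non-overlapping and gap-free over [-1500, 2000]; row sums within
#' [0.985, 1.005] (published stoichiometric tables round each fraction to
#' three decimals, and two soft-tissue rows of the packaged default sum to
#' 0.994 and 0.988 as printed).
#'
#' @param path CSV (default: packaged calibration).
#' @return a `composition_table` with `hu_min`, `hu_max` and `fractions`
#'   (rows x elements matrix).
#' @export
composition_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hu_composition.csv", package = "ctdosim")
  df <- read.csv(path, comment.char = "#")
  els <- setdiff(names(df), c("hu_min", "hu_max"))
  fr <- as.matrix(df[, els])
  if (any(fr < 0)) stop("negative weight fraction", call. = FALSE)
  rs <- rowSums(fr)
  if (any(rs < 0.985 | rs > 1.005))
    stop("composition row sums outside [0.985, 1.005]: ",
         paste(which(rs < 0.985 | rs > 1.005), collapse = ", "),
         call. = FALSE)
  if (is.unsorted(df$hu_min) || any(df$hu_min[-1] != head(df$hu_max, -1) + 1))
    stop("HU ranges must be ordered, non-overlapping and gap-free",
         call. = FALSE)
  structure(list(hu_min = df$hu_min, hu_max = df$hu_max, fractions = fr),
            class = "composition_table")
}

#' Look up the elemental composition for HU values
#'
#' Non-integer HU are rounded half-away-from-zero; values outside
#' [min, max] are clamped to the end rows.
#'
#' @param hu Hounsfield units (vectorized).
#' @param table a `composition_table`.
#' @return for scalar input a named fraction vector; otherwise the row
#'   indices' fraction matrix.
#' @export
hu_to_composition <- function(hu, table = composition_table()) {
  idx <- hu_to_material_index(hu, table)
  table$fractions[idx, , drop = length(hu) == 1]
}

#' @rdname hu_to_composition
#' @return `hu_to_material_index()`: integer row indices into the table.
#' @export
hu_to_material_index <- function(hu, table = composition_table()) {
  h <- sign(hu) * floor(abs(hu) + 0.5)       # round half away from zero
  h <- pmin(pmax(h, min(table$hu_min)), max(table$hu_max))
  findInterval(h, c(table$hu_min, max(table$hu_max) + 1L),
               rightmost.closed = TRUE)
}

#' Construct a voxel phantom from an HU grid
#'
#' Voxel indices are 0-based with world coordinates at voxel centers;
#' `origin` is the center of voxel (0,0,0). Density and composition row
#' index grids are derived through the two calibrations.
#'
#' @param hu integer 3-d array (nx x ny x nz) of Hounsfield units.
#' @param spacing_mm length-3 voxel size.
#' @param origin_mm length-3 world position of the first voxel center.
#' @param cal a `density_calibration`.
#' @param comp a `composition_table`.
#' @return a `voxel_phantom` with `hu`, `density`, `material_index`, `dims`,
#'   `spacing_mm`, `origin_mm` and the calibrations used.
#' @export
voxel_phantom <- function(hu, spacing_mm, origin_mm,
                          cal = density_calibration(),
                          comp = composition_table()) {
  stopifnot(length(dim(hu)) == 3, length(spacing_mm) == 3,
            length(origin_mm) == 3, all(spacing_mm > 0))
  dens <- array(hu_to_density(as.vector(hu), cal), dim = dim(hu))
  midx <- array(hu_to_material_index(as.vector(hu), comp), dim = dim(hu))
  structure(list(hu = hu, density = dens, material_index = midx,
                 dims = dim(hu), spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm), cal = cal, comp = comp),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing_mm[1],
              x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

# world coordinates of voxel centers along one axis
.axis_coords <- function(ph, axis) {
  ph$origin_mm[axis] + (seq_len(ph$dims[axis]) - 1) * ph$spacing_mm[axis]
}

#' Generate a fixture phantom
#'
#' Desk-scale stand-ins for the physical test geometries, emitted as HU
#' grids so the calibration path is exercised. Material HU values are chosen
#' by inverting the density calibration at the material's nominal density
#' (PMMA 1.19, carbon fiber 1.60, foam 0.03 g/cm3).
#'
#' * `ctdi_body`: PMMA cylinder, 320 mm diameter x 150 mm, with a 13 mm
#'   air-filled center hole, axis along z.
#' * `air_chamber`: all-air volume for in-air kerma runs (pair with
#'   [chamber_tally()]).
#' * `water_cylinder`: water (HU 0) cylinder, default 200 mm diameter.
#' * `couch`: carbon-fiber shell over a foam core, slab along z.
#' * `block_phantom`: layered lung / soft tissue / bone slab.
#'
#' @param name fixture name.
#' @param spacing_mm voxel size (default 4 mm isotropic).
#' @param cal,comp calibrations passed to [voxel_phantom()].
#' @param ... overrides: `diameter_mm`, `length_mm`, `hole_diameter_mm`
#'   (ctdi_body); `extent_mm` (air_chamber); etc.
#' @return a `voxel_phantom`.
#' @export
make_fixture <- function(name = c("ctdi_body", "air_chamber",
                                  "water_cylinder", "couch", "block_phantom"),
                         spacing_mm = c(4, 4, 4),
                         cal = density_calibration(),
                         comp = composition_table(), ...) {
  name <- match.arg(name)
  opts <- list(...)
  opt <- function(k, d) if (!is.null(opts[[k]])) opts[[k]] else d
  air_hu <- -1000
  grid3 <- function(extent, spacing) {
    dims <- pmax(3L, as.integer(ceiling(extent / spacing)))
    origin <- -(dims - 1) / 2 * spacing
    list(dims = dims, origin = origin)
  }
  if (name == "ctdi_body") {
    dia <- opt("diameter_mm", 320); len <- opt("length_mm", 150)
    hole <- opt("hole_diameter_mm", 13)
    g <- grid3(c(dia + 40, dia + 40, len), spacing_mm)
    x <- g$origin[1] + (seq_len(g$dims[1]) - 1) * spacing_mm[1]
    y <- g$origin[2] + (seq_len(g$dims[2]) - 1) * spacing_mm[2]
    r2 <- outer(x^2, y^2, `+`)
    pmma_hu <- round(.density_to_hu(1.19, cal))
    slice <- matrix(air_hu, g$dims[1], g$dims[2])
    slice[r2 < (dia / 2)^2] <- pmma_hu
    slice[r2 < (hole / 2)^2] <- air_hu
    hu <- array(rep(slice, g$dims[3]), dim = g$dims)
  } else if (name == "air_chamber") {
    ext <- opt("extent_mm", c(320, 320, 240))
    g <- grid3(ext, spacing_mm)
    hu <- array(air_hu, dim = g$dims)
  } else if (name == "water_cylinder") {
    dia <- opt("diameter_mm", 200); len <- opt("length_mm", 150)
    g <- grid3(c(dia + 40, dia + 40, len), spacing_mm)
    x <- g$origin[1] + (seq_len(g$dims[1]) - 1) * spacing_mm[1]
    y <- g$origin[2] + (seq_len(g$dims[2]) - 1) * spacing_mm[2]
    r2 <- outer(x^2, y^2, `+`)
    slice <- matrix(air_hu, g$dims[1], g$dims[2])
    slice[r2 < (dia / 2)^2] <- 0
    hu <- array(rep(slice, g$dims[3]), dim = g$dims)
  } else if (name == "couch") {
    wid <- opt("width_mm", 480); thick <- opt("thickness_mm", 80)
    len <- opt("length_mm", 240); shell <- opt("shell_mm", 8)
    g <- grid3(c(wid, thick, len), spacing_mm)
    cf_hu <- round(.density_to_hu(1.60, cal))
    foam_hu <- round(.density_to_hu(0.03, cal))
    x <- g$origin[1] + (seq_len(g$dims[1]) - 1) * spacing_mm[1]
    y <- g$origin[2] + (seq_len(g$dims[2]) - 1) * spacing_mm[2]
    hu <- array(foam_hu, dim = g$dims)
    edge <- outer(abs(x) > wid / 2 - shell, rep(TRUE, g$dims[2]), `&`) |
            outer(rep(TRUE, g$dims[1]), abs(y) > thick / 2 - shell, `&`)
    for (k in seq_len(g$dims[3])) hu[, , k][edge] <- cf_hu
  } else {  # block_phantom
    ext <- opt("extent_mm", c(160, 120, 160))
    g <- grid3(ext, spacing_mm)
    y <- g$origin[2] + (seq_len(g$dims[2]) - 1) * spacing_mm[2]
    layer_hu <- rep(40L, g$dims[2])              # soft tissue
    layer_hu[y > ext[2] / 6] <- -700L            # lung
    layer_hu[y < -ext[2] / 6] <- 1000L           # bone
    hu <- array(rep(rep(layer_hu, each = g$dims[1]), g$dims[3]),
                dim = g$dims)
  }
  voxel_phantom(hu, spacing_mm, g$origin, cal, comp)
}

#' Merge a couch phantom under a patient phantom
#'
#' Output voxels keep the patient HU wherever it exceeds the air threshold;
#' elsewhere the couch HU (sampled at the vertically offset position, nearest
#' voxel) is used. Dims follow the patient grid. Truncated-couch voxels in
#' the patient volume should be pre-cleared to air by the caller.
#'
#' @param patient,couch `voxel_phantom`s with compatible spacing.
#' @param vertical_offset_mm +y shift applied to the couch before sampling.
#' @param air_threshold_hu HU at or below which a patient voxel counts as air
#'   (default -900).
#' @return merged `voxel_phantom` on the patient grid.
#' @export
merge_couch <- function(patient, couch, vertical_offset_mm = 0,
                        air_threshold_hu = -900) {
  if (any(abs(patient$spacing_mm - couch$spacing_mm) > 1e-6))
    stop("patient and couch spacing differ; resample first", call. = FALSE)
  px <- .axis_coords(patient, 1); py <- .axis_coords(patient, 2)
  pz <- .axis_coords(patient, 3)
  cy <- .axis_coords(couch, 2) + vertical_offset_mm
  # nearest couch voxel, rounding half up (grids may sit half a voxel apart)
  ix <- floor((px - couch$origin_mm[1]) / couch$spacing_mm[1] + 0.5) + 1L
  iy <- floor((py - cy[1]) / couch$spacing_mm[2] + 0.5) + 1L
  iz <- floor((pz - couch$origin_mm[3]) / couch$spacing_mm[3] + 0.5) + 1L
  okx <- ix >= 1 & ix <= couch$dims[1]
  oky <- iy >= 1 & iy <= couch$dims[2]
  okz <- iz >= 1 & iz <= couch$dims[3]
  if (!any(okx) || !any(oky) || !any(okz))
    stop("couch grid does not overlap the patient grid", call. = FALSE)
  hu <- patient$hu
  for (k in which(okz)) {
    ck <- couch$hu[, , iz[k]]
    sub <- hu[, , k]
    airmask <- sub <= air_threshold_hu
    cvals <- matrix(-1000L, length(px), length(py))
    cvals[okx, oky] <- ck[ix[okx], iy[oky]]
    sub[airmask] <- cvals[airmask]
    hu[, , k] <- sub
  }
  voxel_phantom(hu, patient$spacing_mm, patient$origin_mm, patient$cal,
                patient$comp)
}

#' Voxelize a plain-text CT slice series
#'
#' Reads the package's slice-series interchange format: a directory holding
#' `series.json` (per-slice metadata: pixel file, z position, rescale slope
#' and intercept, pixel spacing, orientation tag) plus one CSV of raw pixel
#' values per slice. Slices are sorted by z position, HU = slope * raw +
#' intercept, and the density / composition grids are derived through the
#' calibrations. Inconsistent spacing or orientation across slices is an
#' error. (A DICOM series must be converted to this format externally; no
#' DICOM reader is available in the supported stack.)
#'
#' @param series_path directory containing `series.json`.
#' @param cal,comp calibrations.
#' @return a `voxel_phantom`.
#' @export
voxelize_series <- function(series_path, cal = density_calibration(),
                            comp = composition_table()) {
  meta <- jsonlite::read_json(file.path(series_path, "series.json"),
                              simplifyVector = TRUE)
  sl <- meta$slices
  if (length(unique(sl$orientation)) > 1)
    stop("inconsistent slice orientation", call. = FALSE)
  if (length(unique(sl$pixel_spacing_mm)) > 1 &&
      !all(vapply(sl$pixel_spacing_mm, identical, TRUE,
                  sl$pixel_spacing_mm[[1]])))
    stop("inconsistent pixel spacing", call. = FALSE)
  ord <- order(sl$z_mm)
  sl <- sl[ord, , drop = FALSE]
  z <- sl$z_mm
  dz <- if (length(z) > 1) diff(z) else meta$slice_thickness_mm
  if (length(z) > 2 && any(abs(diff(z) - dz[1]) > 1e-6))
    stop("inconsistent slice spacing", call. = FALSE)
  slices <- lapply(seq_len(nrow(sl)), function(i) {
    raw <- as.matrix(read.csv(file.path(series_path, sl$file[i]),
                              header = FALSE))
    sl$rescale_slope[i] * raw + sl$rescale_intercept[i]
  })
  dims <- dim(slices[[1]])
  if (any(vapply(slices, function(s) any(dim(s) != dims), TRUE)))
    stop("inconsistent slice dimensions", call. = FALSE)
  hu <- array(0L, dim = c(dims[1], dims[2], length(slices)))
  for (i in seq_along(slices)) hu[, , i] <- as.integer(round(slices[[i]]))
  sp <- c(unlist(sl$pixel_spacing_mm[[1]]),
          if (length(z) > 1) dz[1] else meta$slice_thickness_mm)
  voxel_phantom(hu, sp, c(meta$origin_x_mm, meta$origin_y_mm, z[1]),
                cal, comp)
}

#' @rdname voxelize_series
#' @param phantom a `voxel_phantom` to export.
#' @param slope,intercept rescale applied in reverse when writing raw values.
#' @export
write_series <- function(phantom, series_path, slope = 1, intercept = 0) {
  dir.create(series_path, recursive = TRUE, showWarnings = FALSE)
  nz <- phantom$dims[3]
  files <- sprintf("slice_%03d.csv", seq_len(nz))
  for (k in seq_len(nz)) {
    raw <- (phantom$hu[, , k] - intercept) / slope
    write.table(raw, file.path(series_path, files[k]), sep = ",",
                row.names = FALSE, col.names = FALSE)
  }
  z <- .axis_coords(phantom, 3)
  meta <- list(
    origin_x_mm = phantom$origin_mm[1], origin_y_mm = phantom$origin_mm[2],
    slice_thickness_mm = phantom$spacing_mm[3],
    slices = data.frame(file = files, z_mm = z, rescale_slope = slope,
                        rescale_intercept = intercept,
                        orientation = "axial")
  )
  meta$slices$pixel_spacing_mm <- rep(list(phantom$spacing_mm[1:2]), nz)
  jsonlite::write_json(meta, file.path(series_path, "series.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(series_path)
}

#' Binary phantom serialization
#'
#' Writes the HU grid as little-endian int16 with a JSON sidecar (dims,
#' spacing, origin, dtype); reads it back bit-exactly.
#'
#' @param phantom a `voxel_phantom`.
#' @param path base path; `<path>.raw` and `<path>.json` are written.
#' @export
write_phantom <- function(phantom, path) {
  con <- file(paste0(path, ".raw"), "wb")
  writeBin(as.integer(phantom$hu), con, size = 2, endian = "little")
  close(con)
  jsonlite::write_json(list(dims = phantom$dims,
                            spacing_mm = phantom$spacing_mm,
                            origin_mm = phantom$origin_mm, dtype = "int16"),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phantom
#' @param cal,comp calibrations applied on read.
#' @export
read_phantom <- function(path, cal = density_calibration(),
                         comp = composition_table()) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".raw"), "rb")
  v <- readBin(con, "integer", n = prod(meta$dims), size = 2,
               endian = "little")
  close(con)
  voxel_phantom(array(v, dim = meta$dims), meta$spacing_mm, meta$origin_mm,
                cal, comp)
}
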