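# Scanner characterization: bowtie filter thickness profile and sampling PDF,
# z-axis beam profile (heel effect) with FWHM, source geometry and the total
# source strength Q.

#' Fit the bowtie thickness profile from normalized exposure measurements
#'
#' For each 1-cm radial bin, solves a one-dimensional root find for the filter
#' thickness whose air-kerma transmission matches the measured normalized
#' exposure ratio. Measurements are taken from isocenter outward on one side;
#' by default the profile is mirrored about isocenter (physical bowties are
#' symmetric). The post-bowtie spectrum in every bin is stored.
#'
#' @param measurement data.frame with columns `distance_cm` (0, 1, 2, ... from
#'   isocenter) and `normalized_exposure` in (0, 1], 1 at the central bin.
#' @param base_spectrum `energy_spectrum` entering the bowtie (at isocenter
#'   distance).
#' @param xs an `attenuation_table`.
#' @param material bowtie material (default `"aluminum"`).
#' @param mirror mirror the one-sided measurement about isocenter
#'   (default TRUE).
#' @return a `bowtie_profile`: `bin_edges` (cm, isocenter plane),
#'   `thickness_mm`, `per_bin_spectrum` (energy-bin x bowtie-bin fluence
#'   matrix), `pdf`, `base_spectrum`, `material`.
#' @export
fit_bowtie_thickness <- function(measurement, base_spectrum, xs,
                                 material = "aluminum", mirror = TRUE) {
  r <- measurement$normalized_exposure
  d <- measurement$distance_cm
  if (any(r <= 0 | r > 1))
    stop("normalized exposures must lie in (0, 1]", call. = FALSE)
  stopifnot(!is.unsorted(d), length(r) >= 1)
  k0 <- air_kerma(base_spectrum, xs)
  m <- .xs_material(xs, material)
  ec <- bin_centers(base_spectrum)
  mu_lin_mm <- mu_rho(xs, material, ec) * m$density / 10   # 1/mm
  kerma_w <- ec * mu_rho(xs, "air", ec, "en")
  t_for_ratio <- function(ratio) {
    if (ratio >= 1) return(0)
    f <- function(t) sum(base_spectrum$fluence * exp(-mu_lin_mm * t) *
                           kerma_w) * .KERMA_UGY / k0 - ratio
    upper <- 1
    while (f(upper) > 0 && upper < 1e4) upper <- upper * 2
    uniroot(f, c(0, upper), tol = 1e-9 * max(upper, 1))$root
  }
  th <- vapply(r, t_for_ratio, numeric(1))
  if (mirror) {
    th <- c(rev(th[-1]), th)
    d_lo <- c(rev(-d[-1]) - 0.5, d - 0.5)
  } else {
    d_lo <- d - 0.5
  }
  edges <- c(d_lo, max(d_lo) + 1)
  spec_mat <- matrix(vapply(th, function(t) base_spectrum$fluence *
                              exp(-mu_lin_mm * t),
                            numeric(length(ec))),
                     nrow = length(ec))
  bt <- structure(list(bin_edges = edges, thickness_mm = th,
                       per_bin_spectrum = spec_mat, pdf = NULL,
                       base_spectrum = base_spectrum, material = material),
                  class = "bowtie_profile")
  build_bowtie_pdf(bt)
}

#' Populate the bowtie sampling PDF
#'
#' The probability of emitting through bowtie bin i is proportional to the
#' total number of photons exiting that bin (sum of the post-bowtie spectrum
#' times the bin width).
#'
#' @param profile a `bowtie_profile`.
#' @return the profile with `pdf` populated (sums to 1).
#' @export
build_bowtie_pdf <- function(profile) {
  w <- diff(profile$bin_edges)
  tot <- colSums(profile$per_bin_spectrum) * w
  if (sum(tot) <= 0) stop("degenerate bowtie PDF: all spectra zero",
                          call. = FALSE)
  profile$pdf <- tot / sum(tot)
  profile
}

#' Sample bowtie exit coordinates and fan angles
#'
#' Draws a bowtie bin from the profile PDF, then a uniform exit coordinate
#' within the bin (isocenter plane), and converts it to the fan angle (angle
#' in the rotation plane) seen from the focal spot.
#'
#' @param profile a `bowtie_profile` with `pdf` populated.
#' @param n number of samples.
#' @param tube_to_iso_mm focal spot to isocenter distance, mm.
#' @return list with `bin` (index), `x_cm` (exit coordinate), `fan_angle`
#'   (rad; 0 at the isocenter projection).
#' @export
sample_bowtie_exit <- function(profile, n, tube_to_iso_mm) {
  if (is.null(profile$pdf)) stop("bowtie PDF not populated", call. = FALSE)
  bin <- sample.int(length(profile$pdf), n, replace = TRUE,
                    prob = profile$pdf)
  lo <- profile$bin_edges[bin]
  x <- lo + runif(n) * diff(profile$bin_edges)[bin]
  list(bin = bin, x_cm = x, fan_angle = atan(x * 10 / tube_to_iso_mm))
}

#' Build a z-axis beam profile (heel effect) from measured intensities
#'
#' Computes the FWHM of the measured profile (the effective collimation) and
#' discretizes the profile into 1-cm bins over its support, converting the
#' normalized intensities into a discrete sampling PDF.
#'
#' @param z_mm measurement positions along z (mm, increasing).
#' @param intensity normalized intensities (max scaled to 1 internally).
#' @param support_frac bins are kept where the binned intensity exceeds this
#'   fraction of the maximum (default 0.01).
#' @return a `beam_profile`: `z_edges` (cm), `intensity` (mean normalized
#'   intensity per bin), `pdf`, `fwhm_mm`.
#' @export
beam_profile <- function(z_mm, intensity, support_frac = 0.01) {
  stopifnot(length(z_mm) == length(intensity), !is.unsorted(z_mm))
  intensity <- intensity / max(intensity)
  w <- fwhm(z_mm, intensity)
  edges_cm <- seq(floor(min(z_mm) / 10), ceiling(max(z_mm) / 10), by = 1)
  mids <- (edges_cm[-1] + edges_cm[-length(edges_cm)]) * 10 / 2
  h <- approx(z_mm, intensity, xout = mids, rule = 2)$y
  keep <- h > support_frac * max(h)
  i1 <- which(keep)[1]; i2 <- tail(which(keep), 1)
  h <- h[i1:i2]
  edges_cm <- edges_cm[i1:(i2 + 1)]
  structure(list(z_edges = edges_cm, intensity = h, pdf = h / sum(h),
                 fwhm_mm = w),
            class = "beam_profile")
}

#' Sample z offsets and cone angles from a beam profile
#'
#' Bin-then-uniform-within-bin sampling of the z offset; the cone angle
#' (toward z) is `atan(z / tube_to_iso)`.
#'
#' @param profile a `beam_profile`.
#' @param n number of samples.
#' @param tube_to_iso_mm focal spot to isocenter distance, mm.
#' @return list with `bin`, `z_mm` (offset from beam center), `cone_angle`
#'   (rad).
#' @export
sample_heel_z <- function(profile, n, tube_to_iso_mm) {
  bin <- sample.int(length(profile$pdf), n, replace = TRUE,
                    prob = profile$pdf)
  lo <- profile$z_edges[bin]
  z <- (lo + runif(n) * diff(profile$z_edges)[bin]) * 10
  list(bin = bin, z_mm = z, cone_angle = atan(z / tube_to_iso_mm))
}

#' Full width at half maximum of a sampled profile
#'
#' Linear interpolation of the two half-maximum crossings around the unique
#' maximum region.
#'
#' @param z positions (mm), increasing, at least 3.
#' @param intensity intensities.
#' @return width in mm.
#' @export
fwhm <- function(z, intensity) {
  stopifnot(length(z) >= 3, length(z) == length(intensity))
  half <- max(intensity) / 2
  imax <- which.max(intensity)
  left <- which(intensity[seq_len(imax)] < half)
  right <- which(intensity[imax:length(intensity)] < half) + imax - 1L
  if (length(left) == 0 || length(right) == 0)
    stop("profile never falls below half maximum on one side",
         call. = FALSE)
  i <- tail(left, 1)       # crossing between i and i+1
  xl <- z[i] + (half - intensity[i]) / (intensity[i + 1] - intensity[i]) *
    (z[i + 1] - z[i])
  j <- right[1]            # crossing between j-1 and j
  xr <- z[j - 1] + (half - intensity[j - 1]) /
    (intensity[j] - intensity[j - 1]) * (z[j] - z[j - 1])
  xr - xl
}

#' Source geometry for the strength formula
#'
#' @param tube_to_iso_mm focal spot to isocenter distance (SDD), mm.
#' @return a `source_geometry` object.
#' @export
source_geometry <- function(tube_to_iso_mm) {
  stopifnot(tube_to_iso_mm > 0)
  structure(list(tube_to_iso_mm = tube_to_iso_mm), class = "source_geometry")
}

#' Total source strength Q
#'
#' Double sum over bowtie bins i and beam-profile bins j of the normalized
#' beam intensity, an area-distance geometry factor, and the per-bin photon
#' fluence summed over energy groups, scaled linearly by mAs. The default
#' geometry factor is the printed form \eqn{A_{ij} D_{ij} / SDD^2}
#' (dimensionally odd but kept verbatim); `"inverse_square"` substitutes
#' \eqn{A_{ij} (SDD/D_{ij})^2}.
#'
#' @param bowtie a `bowtie_profile` (per-bin spectra in photons/mm2/mAs at
#'   isocenter).
#' @param beam a `beam_profile`.
#' @param geom a `source_geometry`.
#' @param mAs tube current-time product.
#' @param geometry `"as_printed"` (default) or `"inverse_square"`.
#' @return total photon strength Q (scalar).
#' @export
source_strength <- function(bowtie, beam, geom, mAs,
                            geometry = c("as_printed", "inverse_square")) {
  geometry <- match.arg(geometry)
  stopifnot(mAs > 0)
  if (is.null(bowtie$pdf)) stop("bowtie PDF not populated", call. = FALSE)
  sdd <- geom$tube_to_iso_mm
  xi <- (bowtie$bin_edges[-1] + head(bowtie$bin_edges, -1)) * 10 / 2  # mm
  wi <- diff(bowtie$bin_edges) * 10
  zj <- (beam$z_edges[-1] + head(beam$z_edges, -1)) * 10 / 2
  wj <- diff(beam$z_edges) * 10
  qi <- colSums(bowtie$per_bin_spectrum) * mAs   # photons/mm2 per bowtie bin
  tot <- 0
  for (j in seq_along(zj)) {
    d_ij <- sqrt(sdd^2 + xi^2 + zj[j]^2)
    a_ij <- wi * wj[j]
    gf <- switch(geometry,
                 as_printed = a_ij * d_ij / sdd^2,
                 inverse_square = a_ij * (sdd / d_ij)^2)
    tot <- tot + beam$intensity[j] * sum(gf * qi)
  }
  tot
}

#' Bundle and serialize a fitted scanner model
#'
#' A `scanner_model` bundles the fitted bowtie profile, beam profile and
#' source geometry for reuse across runs; [write_scanner_model()] /
#' [read_scanner_model()] round-trip it through a single JSON document.
#'
#' @param bowtie a `bowtie_profile`.
#' @param beam a `beam_profile`.
#' @param geom a `source_geometry`.
#' @return a `scanner_model`.
#' @export
scanner_model <- function(bowtie, beam, geom) {
  structure(list(bowtie = bowtie, beam = beam, geometry = geom),
            class = "scanner_model")
}

#' @rdname scanner_model
#' @param model a `scanner_model`.
#' @param path JSON file path.
#' @export
write_scanner_model <- function(model, path) {
  doc <- list(
    bowtie = list(bin_edges = model$bowtie$bin_edges,
                  thickness_mm = model$bowtie$thickness_mm,
                  per_bin_spectrum = model$bowtie$per_bin_spectrum,
                  pdf = model$bowtie$pdf,
                  material = model$bowtie$material,
                  base_edges = model$bowtie$base_spectrum$energy_edges,
                  base_fluence = model$bowtie$base_spectrum$fluence,
                  base_distance = model$bowtie$base_spectrum$reference_distance,
                  base_kv = model$bowtie$base_spectrum$kv),
    beam = list(z_edges = model$beam$z_edges,
                intensity = model$beam$intensity, pdf = model$beam$pdf,
                fwhm_mm = model$beam$fwhm_mm),
    geometry = list(tube_to_iso_mm = model$geometry$tube_to_iso_mm))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname scanner_model
#' @export
read_scanner_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- energy_spectrum(doc$bowtie$base_edges, doc$bowtie$base_fluence,
                          doc$bowtie$base_distance, kv = doc$bowtie$base_kv)
  bt <- structure(list(bin_edges = doc$bowtie$bin_edges,
                       thickness_mm = doc$bowtie$thickness_mm,
                       per_bin_spectrum = as.matrix(doc$bowtie$per_bin_spectrum),
                       pdf = doc$bowtie$pdf, base_spectrum = base,
                       material = doc$bowtie$material),
                  class = "bowtie_profile")
  bm <- structure(list(z_edges = doc$beam$z_edges,
                       intensity = doc$beam$intensity, pdf = doc$beam$pdf,
                       fwhm_mm = doc$beam$fwhm_mm),
                  class = "beam_profile")
  scanner_model(bt, bm, source_geometry(doc$geometry$tube_to_iso_mm))
}

#' Synthetic scanner characterization measurements
#'
#' Generators emulating the two bench measurements that characterize a
#' wide-beam scanner: the radial in-air exposure scan across the bowtie
#' (parabolic thickness profile, thinnest at isocenter) and the z-axis beam
#' profile film scan (flat-topped profile of the nominal collimation width
#' with sloped penumbra and a mild anode-side heel tilt). Defaults state the
#' conditions of a 120 kV large-body-filter acquisition.
#'
#' @param base_spectrum spectrum entering the bowtie.
#' @param xs an `attenuation_table`.
#' @param n_bins radial bins from isocenter (default 25, i.e. 25 cm).
#' @param max_thickness_mm bowtie edge thickness (default 30 mm Al).
#' @param material bowtie material.
#' @return `synthetic_bowtie_measurement()`: data.frame
#'   (`distance_cm`, `normalized_exposure`); the attribute
#'   `"thickness_mm"` carries the generating thickness profile.
#' @export
synthetic_bowtie_measurement <- function(base_spectrum, xs, n_bins = 25,
                                         max_thickness_mm = 30,
                                         material = "aluminum") {
  d <- 0:n_bins
  th <- max_thickness_mm * (d / n_bins)^2
  ec <- bin_centers(base_spectrum)
  m <- .xs_material(xs, material)
  mu_lin_mm <- mu_rho(xs, material, ec) * m$density / 10
  kerma_w <- ec * mu_rho(xs, "air", ec, "en")
  k0 <- sum(base_spectrum$fluence * kerma_w)
  ratio <- vapply(th, function(t)
    sum(base_spectrum$fluence * exp(-mu_lin_mm * t) * kerma_w) / k0,
    numeric(1))
  structure(data.frame(distance_cm = d, normalized_exposure = ratio),
            thickness_mm = th)
}

#' @rdname synthetic_bowtie_measurement
#' @param collimation_mm nominal collimation (flat-top width), mm.
#' @param penumbra_mm width of the linear penumbra on each side (default 6).
#' @param heel_slope fractional intensity tilt across the flat top emulating
#'   the heel effect (default 0.08).
#' @param step_mm sampling step of the synthetic film scan (default 1).
#' @return `synthetic_beam_profile_scan()`: data.frame (`z_mm`,
#'   `normalized_intensity`).
#' @export
synthetic_beam_profile_scan <- function(collimation_mm = 80, penumbra_mm = 6,
                                        heel_slope = 0.08, step_mm = 1) {
  half <- collimation_mm / 2
  z <- seq(-half - 3 * penumbra_mm, half + 3 * penumbra_mm, by = step_mm)
  core <- pmin(1, pmax(0, (half + penumbra_mm / 2 - abs(z)) / penumbra_mm))
  tilt <- 1 - heel_slope * (z + half) / collimation_mm
  y <- core * pmax(tilt, 0)
  data.frame(z_mm = z, normalized_intensity = y / max(y))
}
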