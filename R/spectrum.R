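# Energy-spectrum representation, filtration, air kerma, HVL and the
# two-parameter equivalent-filter fit.

# kerma conversion: fluence [1/mm2] * E [keV] * mu_en/rho [cm2/g] -> uGy
.KERMA_UGY <- 1.60218e-5

#' Construct a binned x-ray energy spectrum
#'
#' Contiguous 1-keV (or other uniform width) energy bins with photon fluence
#' per bin, tied to a reference distance from the focal spot.
#'
#' @param energy_edges keV, strictly increasing bin edges.
#' @param fluence photons/mm2/mAs per bin, non-negative,
#'   `length(energy_edges) - 1`.
#' @param reference_distance cm from the focal spot.
#' @param kv tube potential (kV); highest edge must not exceed it.
#' @return an `energy_spectrum` object.
#' @export
energy_spectrum <- function(energy_edges, fluence, reference_distance,
                            kv = max(energy_edges)) {
  stopifnot(length(energy_edges) == length(fluence) + 1L,
            all(diff(energy_edges) > 0), all(fluence >= 0),
            reference_distance > 0)
  if (max(energy_edges) > kv + 1e-9)
    stop("highest bin edge exceeds tube potential", call. = FALSE)
  structure(list(energy_edges = as.numeric(energy_edges),
                 fluence = as.numeric(fluence),
                 reference_distance = reference_distance, kv = kv),
            class = "energy_spectrum")
}

#' Bin-center energies of a spectrum
#' @param spec an `energy_spectrum`.
#' @return keV vector, one per bin.
#' @export
bin_centers <- function(spec) {
  e <- spec$energy_edges
  (e[-1] + e[-length(e)]) / 2
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf(
    "<energy_spectrum> %d bins [%.4g, %.4g] keV, %.4g photons/mm2/mAs at %.4g cm\n",
    length(x$fluence), min(x$energy_edges), max(x$energy_edges),
    sum(x$fluence), x$reference_distance))
  invisible(x)
}

#' Analytic fallback bremsstrahlung spectrum
#'
#' Kramers-law photon-number shape \eqn{\phi(E) \propto (E_{max}-E)/E} in
#' 1-keV bins, with optional tungsten characteristic K lines at 58, 59, 67
#' and 69 keV (added when the tube potential exceeds the W K edge). Intended
#' as a download-free stand-in for a measured or vendor spectrum; total
#' fluence is normalized to `total_fluence` at the reference distance.
#'
#' @param kv tube potential, kV.
#' @param min_keV lowest bin edge (default 5, the attenuation-table floor).
#' @param reference_distance cm (default 100).
#' @param total_fluence photons/mm2/mAs in the unfiltered beam (default 1e6,
#'   a stated package constant; absolute normalization of a real tube must
#'   come from measurement).
#' @param characteristic add tungsten K lines (default TRUE).
#' @return an `energy_spectrum`.
#' @export
fallback_spectrum <- function(kv = 120, min_keV = 5, reference_distance = 100,
                              total_fluence = 1e6, characteristic = TRUE) {
  stopifnot(kv > min_keV + 1)
  edges <- seq(min_keV, kv, by = 1)
  ec <- (edges[-1] + edges[-length(edges)]) / 2
  phi <- pmax(kv - ec, 0) / ec
  if (characteristic && kv > 69.5) {
    lines <- c(`58` = 0.30, `59` = 0.30, `67` = 0.25, `69` = 0.15)
    line_total <- 0.08 * sum(phi)       # fixed 8% K-line fluence share
    for (le in names(lines)) {
      i <- findInterval(as.numeric(le), edges, rightmost.closed = TRUE)
      phi[i] <- phi[i] + line_total * lines[[le]]
    }
  }
  phi <- phi / sum(phi) * total_fluence
  energy_spectrum(edges, phi, reference_distance, kv = kv)
}

#' Beer-Lambert filtration of a spectrum
#'
#' Attenuates each bin by \eqn{\exp(-\sum_l (\mu/\rho)_l \rho_l t_l)} with the
#' layer coefficients log-log interpolated at bin centers.
#'
#' @param spec an `energy_spectrum`.
#' @param layers list of filter layers, each `list(material=, thickness_mm=)`;
#'   zero thickness is allowed.
#' @param xs an `attenuation_table` containing every layer material.
#' @return the filtered `energy_spectrum`.
#' @export
apply_filtration <- function(spec, layers, xs) {
  ec <- bin_centers(spec)
  atten <- rep(0, length(ec))
  for (ly in layers) {
    stopifnot(ly$thickness_mm >= 0)
    m <- .xs_material(xs, ly$material)
    atten <- atten + mu_rho(xs, ly$material, ec) * m$density *
      (ly$thickness_mm / 10)
  }
  spec$fluence <- spec$fluence * exp(-atten)
  spec
}

#' Filter layer constructor
#' @param material material name.
#' @param thickness_mm thickness in mm, `>= 0`.
#' @return a list usable in [apply_filtration()].
#' @export
filter_layer <- function(material, thickness_mm) {
  stopifnot(thickness_mm >= 0)
  list(material = material, thickness_mm = thickness_mm)
}

#' Rescale a spectrum to a new distance
#'
#' Inverse-square geometric scaling of the fluence.
#' @param spec an `energy_spectrum`.
#' @param new_distance cm, `> 0`.
#' @return the rescaled `energy_spectrum`.
#' @export
rescale_distance <- function(spec, new_distance) {
  if (new_distance <= 0) stop("distance must be positive", call. = FALSE)
  spec$fluence <- spec$fluence * (spec$reference_distance / new_distance)^2
  spec$reference_distance <- new_distance
  spec
}

#' Air kerma of a spectrum
#'
#' \eqn{K = \sum_k \phi_k E_k (\mu_{en}/\rho)_{air}(E_k)} evaluated at bin
#' centers; linear in the fluence.
#'
#' @param spec an `energy_spectrum`.
#' @param xs an `attenuation_table` with an `air` entry.
#' @return air kerma in uGy/mAs at the spectrum's reference distance.
#' @export
air_kerma <- function(spec, xs) {
  ec <- bin_centers(spec)
  sum(spec$fluence * ec * mu_rho(xs, "air", ec, "en")) * .KERMA_UGY
}

#' Half value layer of a spectrum
#'
#' Thickness of `material` halving the air kerma, found by bracketed root
#' finding to a relative tolerance of 1e-6.
#'
#' @param spec a non-empty `energy_spectrum`.
#' @param xs an `attenuation_table`.
#' @param material filter material (default `"aluminum"`).
#' @return thickness in mm.
#' @export
half_value_layer <- function(spec, xs, material = "aluminum") {
  k0 <- air_kerma(spec, xs)
  if (k0 <= 0) stop("spectrum has zero kerma; no HVL", call. = FALSE)
  f <- function(t) air_kerma(apply_filtration(
    spec, list(filter_layer(material, t)), xs), xs) / k0 - 0.5
  upper <- 1
  while (f(upper) > 0 && upper < 1e4) upper <- upper * 2
  if (f(upper) > 0) stop("no bracket for HVL root", call. = FALSE)
  uniroot(f, c(0, upper), tol = 1e-6 * upper)$root
}

#' Fit an equivalent carbon/aluminum filter
#'
#' Finds thicknesses \eqn{(t_C, t_{Al}) \ge 0} such that the filtered
#' spectrum's air kerma and HVL match measured targets, by bounded
#' least-squares on the relative residuals with multistart at (0, 0) and
#' (5, 10) mm.
#'
#' @param unfiltered an `energy_spectrum` (unfiltered tube output).
#' @param target_kerma uGy/mAs at the spectrum's reference distance.
#' @param target_hvl mm Al; must be at least the unfiltered spectrum's HVL.
#' @param xs an `attenuation_table`.
#' @param tol relative residual tolerance for success (default 0.005).
#' @return list with `carbon_mm`, `aluminum_mm`, `residuals` (relative, kerma
#'   and HVL), `converged`.
#' @export
fit_equivalent_filter <- function(unfiltered, target_kerma, target_hvl, xs,
                                  tol = 0.005) {
  stopifnot(target_kerma > 0, target_hvl > 0)
  hvl0 <- half_value_layer(unfiltered, xs)
  if (target_hvl < hvl0 * (1 - 1e-9))
    stop("infeasible target: HVL below the unfiltered spectrum's HVL (",
         signif(hvl0, 4), " mm)", call. = FALSE)
  resid <- function(th) {
    sp <- apply_filtration(unfiltered, list(filter_layer("carbon", th[1]),
                                            filter_layer("aluminum", th[2])),
                           xs)
    k <- air_kerma(sp, xs)
    if (k <= 0) return(c(1e3, 1e3))
    c(k / target_kerma - 1, half_value_layer(sp, xs) / target_hvl - 1)
  }
  obj <- function(th) sum(resid(th)^2)
  best <- NULL
  for (st in list(c(0, 0), c(5, 10))) {
    fit <- optim(st, obj, method = "L-BFGS-B", lower = c(0, 0),
                 upper = c(100, 100),
                 control = list(factr = 1e4, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  r <- resid(best$par)
  out <- list(carbon_mm = best$par[1], aluminum_mm = best$par[2],
              residuals = c(kerma = r[1], hvl = r[2]),
              converged = all(abs(r) < tol))
  if (!out$converged)
    warning(sprintf(
      "equivalent-filter fit did not reach tolerance (kerma %.3g, HVL %.3g)",
      r[1], r[2]), call. = FALSE)
  out
}

#' Read / write the spectrum CSV interchange format
#'
#' Header `energy_keV,fluence_per_mm2_per_mAs`, one row per bin (row energy =
#' lower bin edge, uniform 1-keV bins assumed), preceded by a metadata line
#' `# reference_distance_cm=<v>`.
#'
#' @param path file path.
#' @return [read_spectrum()] returns an `energy_spectrum`.
#' @export
read_spectrum <- function(path) {
  hdr <- readLines(path, n = 1L)
  rd <- as.numeric(sub(".*reference_distance_cm=([0-9.eE+-]+).*", "\\1", hdr))
  df <- read.csv(path, comment.char = "#")
  e <- df$energy_keV
  w <- if (length(e) > 1) diff(e)[1] else 1
  energy_spectrum(c(e, max(e) + w), df$fluence_per_mm2_per_mAs, rd,
                  kv = max(e) + w)
}

#' @rdname read_spectrum
#' @param spec an `energy_spectrum` to write.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w")
  writeLines(sprintf("# reference_distance_cm=%.6g", spec$reference_distance),
             con)
  write.csv(data.frame(energy_keV = head(spec$energy_edges, -1),
                       fluence_per_mm2_per_mAs = spec$fluence),
            con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}
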