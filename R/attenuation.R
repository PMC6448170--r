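#' @useDynLib ctdosim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx optim rexp runif uniroot sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Built-in compound recipes: weight fractions over packaged elements.
.compound_recipes <- list(
  air          = list(fractions = c(N = 0.7552, O = 0.2318, Ar = 0.0128,
                                    C = 0.0002), density = 1.205e-3),
  water        = list(fractions = c(H = 0.1119, O = 0.8881), density = 1.000),
  pmma         = list(fractions = c(H = 0.0805, C = 0.5998, O = 0.3196),
                      density = 1.190),
  carbon       = list(fractions = c(C = 1.0), density = 1.700),
  aluminum     = list(fractions = c(Al = 1.0), density = 2.699),
  carbon_fiber = list(fractions = c(C = 0.90, H = 0.03, O = 0.07),
                      density = 1.600),
  foam         = list(fractions = c(C = 0.54, H = 0.08, N = 0.10, O = 0.28),
                      density = 0.030)
)

.channels <- c("total", "pe", "incoh", "coh", "en")

#' Load the packaged photon attenuation tables
#'
#' Reads the packaged elemental mass attenuation (\eqn{\mu/\rho}) and mass
#' energy-absorption (\eqn{\mu_{en}/\rho}) coefficient tables and derives the
#' built-in compounds (air, water, pmma, carbon, aluminum, carbon_fiber, foam)
#' by the weight-fraction mixture rule, so compound tables are consistent with
#' their constituent elements by construction.
#'
#' @param extra_compounds optional named list; each entry is a list with
#'   elements `fractions` (named weight fractions over packaged elements) and
#'   `density` (g/cm3), added to the table.
#' @return An object of class `attenuation_table`: named list of materials,
#'   each with `energy` (keV), the five coefficient channels (cm2/g) and
#'   `density` (g/cm3).
#' @export
load_attenuation <- function(extra_compounds = list()) {
  dir <- system.file("extdata", "attenuation", package = "ctdosim")
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  mats <- list()
  for (f in files) {
    hdr <- readLines(f, n = 1L)
    dens <- as.numeric(sub(".*density_g_cm3=([0-9.eE+-]+).*", "\\1", hdr))
    df <- read.csv(f, comment.char = "#")
    stopifnot(all(diff(df$energy_keV) > 0), all(df$mu_total > 0))
    mats[[sub("\\.csv$", "", basename(f))]] <- list(
      energy = df$energy_keV, total = df$mu_total, pe = df$mu_pe,
      incoh = df$mu_incoh, coh = df$mu_coh, en = df$mu_en, density = dens)
  }
  for (nm in names(.compound_recipes)) {
    mats[[nm]] <- .mix_material(mats, .compound_recipes[[nm]]$fractions,
                                .compound_recipes[[nm]]$density)
  }
  for (nm in names(extra_compounds)) {
    mats[[nm]] <- .mix_material(mats, extra_compounds[[nm]]$fractions,
                                extra_compounds[[nm]]$density)
  }
  structure(mats, class = "attenuation_table")
}

.mix_material <- function(mats, fractions, density) {
  stopifnot(all(names(fractions) %in% names(mats)))
  e <- mats[[names(fractions)[1]]]$energy
  out <- list(energy = e, density = density)
  for (ch in .channels) {
    v <- 0
    for (el in names(fractions)) v <- v + fractions[[el]] * mats[[el]][[ch]]
    out[[ch]] <- v
  }
  out
}

.xs_material <- function(xs, material) {
  m <- xs[[material]]
  if (is.null(m)) stop("unknown material '", material,
                       "' in attenuation table", call. = FALSE)
  m
}

#' Interpolate a mass attenuation coefficient
#'
#' Log-log interpolation of \eqn{\mu/\rho} (or \eqn{\mu_{en}/\rho}) in energy,
#' clamped to the grid end values outside the tabulated range.
#'
#' @param xs an `attenuation_table`.
#' @param material material name present in `xs`.
#' @param energy keV, vectorized.
#' @param channel one of `"total"`, `"pe"`, `"incoh"`, `"coh"`, `"en"`.
#' @return coefficient(s) in cm2/g.
#' @export
mu_rho <- function(xs, material, energy, channel = "total") {
  m <- .xs_material(xs, material)
  channel <- match.arg(channel, .channels)
  y <- m[[channel]]
  pos <- y > 0
  if (!all(pos)) {  # zero channels (clamped photoelectric): linear interp
    return(approx(m$energy, y, xout = pmin(pmax(energy, min(m$energy)),
                                           max(m$energy)), rule = 2)$y)
  }
  e <- pmin(pmax(energy, min(m$energy)), max(m$energy))
  exp(approx(log(m$energy), log(y), xout = log(e), rule = 2)$y)
}

#' Linear attenuation coefficient of an elemental mixture
#'
#' Applies the standard weight-fraction mixture rule
#' \eqn{\mu = \rho \sum_e w_e (\mu/\rho)_e(E)} with log-log interpolation of
#' the elemental coefficients. Fractions are used as given (no
#' renormalization), matching calibration tables whose rows sum to 1 within
#' 0.005.
#'
#' @param composition named numeric vector of weight fractions over materials
#'   in `xs` (usually elements).
#' @param density g/cm3.
#' @param energy keV, vectorized.
#' @param xs an `attenuation_table`.
#' @param channel coefficient channel, as in [mu_rho()].
#' @return linear attenuation coefficient(s), 1/cm.
#' @export
mixture_mu <- function(composition, density, energy, xs, channel = "total") {
  s <- sum(composition)
  if (abs(s - 1) > 0.05)
    stop("composition fractions sum to ", signif(s, 4), ", expected ~1",
         call. = FALSE)
  v <- 0
  for (el in names(composition)) {
    if (composition[[el]] == 0) next
    v <- v + composition[[el]] * mu_rho(xs, el, energy, channel)
  }
  density * v
}

# mu/rho matrix [n_materials x n_energies] for transport (rows = composition
# rows / named materials), one channel.
.mu_rho_matrix <- function(xs, comps, egrid, channel) {
  out <- matrix(0, nrow = length(comps), ncol = length(egrid))
  for (i in seq_along(comps)) {
    cmp <- comps[[i]]
    for (el in names(cmp)) {
      if (cmp[[el]] == 0) next
      out[i, ] <- out[i, ] + cmp[[el]] * mu_rho(xs, el, egrid, channel)
    }
  }
  out
}
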