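# R-side transport orchestration: run configuration, tallies, material cross
# section preparation, batched simulation with independent seeded streams,
# batch statistics and the fluence -> kerma conversion.

# energy deposited [keV] -> dose [Gy] given mass [g]
.KEV_PER_G_TO_GY <- 1.60218e-13

#' Simulation run configuration
#'
#' @param n_histories total photon histories.
#' @param n_batches independent batches for the error estimate (default 10).
#' @param seed master seed; batch b uses `seed + b` (stated splitting rule),
#'   so results are independent of batch execution order and reproducible.
#' @param cutoff_keV photon cutoff; photons below it deposit locally
#'   (default 1).
#' @param chunk_size photons per kernel call within a batch (memory control).
#' @return a `run_config`.
#' @export
run_config <- function(n_histories, n_batches = 10, seed = 1,
                       cutoff_keV = 1, chunk_size = 1e6) {
  stopifnot(n_histories >= n_batches, n_batches >= 2)
  structure(list(n_histories = n_histories, n_batches = n_batches,
                 seed = seed, cutoff_keV = cutoff_keV,
                 chunk_size = chunk_size),
            class = "run_config")
}

#' Tally specifications
#'
#' Axis-aligned cylindrical tallies score either deposited energy
#' (`score = "edep"`) or track-length photon fluence in uniform energy bins
#' (`score = "efluence"`); a voxel-mask tally scores deposited energy in a
#' set of voxels (at most one mask tally per run).
#'
#' @param center length-3 world position, mm.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param radius_mm,length_mm cylinder dimensions, positive.
#' @param score `"edep"` or `"efluence"`.
#' @param nbins energy bins for `"efluence"` (default 30).
#' @param emin_keV,emax_keV fluence bin range; defaults `(cutoff, kV]` are
#'   filled in by [run_simulation()] when NULL.
#' @param name tally label.
#' @return a `tally_spec`.
#' @export
tally_cylinder <- function(center, axis = "z", radius_mm, length_mm,
                           score = c("edep", "efluence"), nbins = 30,
                           emin_keV = NULL, emax_keV = NULL,
                           name = "cylinder") {
  score <- match.arg(score)
  stopifnot(radius_mm > 0, length_mm > 0, length(center) == 3)
  structure(list(kind = score, center = as.numeric(center),
                 axis = match(axis, c("x", "y", "z")) - 1L,
                 radius = radius_mm, half_length = length_mm / 2,
                 nbins = as.integer(nbins), emin = emin_keV, emax = emax_keV,
                 name = name),
            class = "tally_spec")
}

#' @rdname tally_cylinder
#' @param mask logical or 0/1 array matching the phantom dims.
#' @export
tally_mask <- function(mask, name = "mask") {
  structure(list(kind = "mask", mask = as.integer(mask != 0), name = name),
            class = "tally_spec")
}

#' The 3 cc pencil-chamber tally
#'
#' Axis-aligned air-chamber fixture tally: a 3 cm3 cylinder (100 mm active
#' length) at isocenter with its axis along z, scoring track-length photon
#' fluence in `nbins` energy bins.
#'
#' @param nbins energy bins (default 30).
#' @param center chamber center (default isocenter).
#' @return a `tally_spec`.
#' @export
chamber_tally <- function(nbins = 30, center = c(0, 0, 0)) {
  len <- 100
  r <- sqrt(3000 / (pi * len))
  tally_cylinder(center, "z", radius_mm = r, length_mm = len,
                 score = "efluence", nbins = nbins, name = "chamber")
}

# Prepare per-composition-row mu/rho matrices on a uniform 1-keV grid and the
# Woodcock majorant over the phantom.
.prepare_xs <- function(phantom, xs, emax) {
  egrid <- seq(1, max(emax, 20), by = 1)
  comps <- lapply(seq_len(nrow(phantom$comp$fractions)), function(i) {
    fr <- phantom$comp$fractions[i, ]
    as.list(fr[fr > 0])
  })
  # mass coefficients are cm2/g; scale by 0.1 so that (mu/rho) * density
  # [g/cm3] yields linear mu in 1/mm, matching the mm geometry
  tot <- .mu_rho_matrix(xs, comps, egrid, "total") * 0.1
  pe <- .mu_rho_matrix(xs, comps, egrid, "pe") * 0.1
  inc <- .mu_rho_matrix(xs, comps, egrid, "incoh") * 0.1
  rows <- sort(unique(as.vector(phantom$material_index)))
  maxrho <- vapply(rows, function(r)
    max(phantom$density[phantom$material_index == r]), numeric(1))
  maj <- apply(tot[rows, , drop = FALSE] * maxrho, 2, max)
  list(egrid = egrid, tot = tot, pe = pe, inc = inc, majorant = maj)
}

#' Run a batched Monte Carlo simulation
#'
#' Emits source photons from the protocol + scanner model, transports them
#' through the phantom with Woodcock delta tracking, and scores the tallies.
#' Histories are split into `n_batches` batches with independent seeded
#' streams (seed + batch index), so results are reproducible and invariant
#' to batch ordering.
#'
#' @param config a `run_config`.
#' @param protocol a `scan_protocol`.
#' @param scanner a fitted `scanner_model`.
#' @param phantom a `voxel_phantom`.
#' @param tallies list of `tally_spec`s.
#' @param xs an `attenuation_table` (default [load_attenuation()]).
#' @return a `tally_result_set`: per-tally `tally_result` objects (batch
#'   means per history, overall mean, absolute/relative standard error) plus
#'   an energy-accounting block (`emitted`, `deposited`, `escaped` keV per
#'   batch).
#' @export
run_simulation <- function(config, protocol, scanner, phantom, tallies,
                           xs = load_attenuation()) {
  if (is.null(scanner$bowtie$pdf))
    stop("scanner model is not fitted", call. = FALSE)
  if (config$n_histories <= 0) stop("zero histories", call. = FALSE)
  prep <- .prepare_xs(phantom, xs, protocol$kv)
  tl <- lapply(tallies, function(t) {
    if (t$kind == "efluence") {
      if (is.null(t$emin)) t$emin <- config$cutoff_keV
      if (is.null(t$emax)) t$emax <- protocol$kv
    }
    t
  })
  n_mask <- sum(vapply(tl, function(t) t$kind == "mask", TRUE))
  if (n_mask > 1) stop("at most one mask tally per run", call. = FALSE)
  per_batch <- ceiling(config$n_histories / config$n_batches)
  nb <- config$n_batches
  batch_scores <- vector("list", nb)
  acct <- matrix(0, nb, 3, dimnames = list(NULL,
                 c("emitted", "deposited", "escaped")))
  mat0 <- as.integer(phantom$material_index) - 1L
  dens <- as.numeric(phantom$density)
  for (b in seq_len(nb)) {
    set.seed(config$seed + b)
    left <- per_batch
    acc <- NULL
    while (left > 0) {
      nchunk <- min(left, config$chunk_size)
      ph <- emit_photons(protocol, scanner, nchunk)
      res <- transport_kernel(ph$position, ph$direction, ph$energy,
                              ph$weight, as.integer(phantom$dims),
                              phantom$spacing_mm, phantom$origin_mm,
                              mat0, dens, prep$egrid[1], 1.0,
                              prep$tot, prep$pe, prep$inc, prep$majorant,
                              config$cutoff_keV, tl, FALSE)
      acct[b, ] <- acct[b, ] + c(sum(ph$energy * ph$weight),
                                 res$total_edep, res$escape_energy)
      sc <- res$scores
      acc <- if (is.null(acc)) sc else mapply(`+`, acc, sc, SIMPLIFY = FALSE)
      left <- left - nchunk
    }
    batch_scores[[b]] <- lapply(acc, `/`, per_batch)   # per-history means
  }
  results <- vector("list", length(tl))
  for (i in seq_along(tl)) {
    bm <- do.call(rbind, lapply(batch_scores, function(s)
      as.numeric(s[[i]])))
    results[[i]] <- .tally_result(tl[[i]], bm, per_batch * nb, nb,
                                  config$seed)
  }
  names(results) <- vapply(tl, `[[`, "", "name")
  structure(list(tallies = results, accounting = acct,
                 n_histories = per_batch * nb, n_batches = nb,
                 seed = config$seed),
            class = "tally_result_set")
}

.tally_result <- function(spec, batch_means, n_histories, n_batches, seed) {
  mean_v <- colMeans(batch_means)
  structure(list(spec = spec, batch_means = batch_means, mean = mean_v,
                 n_histories = n_histories, n_batches = n_batches,
                 seed = seed),
            class = "tally_result")
}

#' Batch statistics
#'
#' Sample mean and Monte Carlo standard error
#' \eqn{\sigma_{MC} = SD(\text{batch means}) / \sqrt{n}} from at least two
#' batch means.
#'
#' @param batch_means numeric vector of per-batch means.
#' @return list with `mean`, `sigma`, `rel_sigma`.
#' @export
batch_statistics <- function(batch_means) {
  if (length(batch_means) < 2) stop("need at least 2 batches", call. = FALSE)
  m <- mean(batch_means)
  s <- sd(batch_means) / sqrt(length(batch_means))
  list(mean = m, sigma = s, rel_sigma = if (m != 0) s / abs(m) else NA_real_)
}

#' Summarize a scalar tally
#'
#' Applies [batch_statistics()] to a scalar (edep or mask) tally; for
#' multi-bin fluence tallies use [fluence_to_kerma()] first.
#'
#' @param tr a `tally_result`.
#' @return list with `mean`, `sigma`, `rel_sigma` (per-history units).
#' @export
tally_statistics <- function(tr) {
  stopifnot(ncol(tr$batch_means) == 1)
  batch_statistics(tr$batch_means[, 1])
}

#' Convert an energy-fluence tally to air kerma
#'
#' \eqn{K = \sum_k \Phi_k E_k (\mu_{en}/\rho)_{air}(E_k)} with bin-center
#' energies; \eqn{\Phi_k} is the per-history track-length estimate divided by
#' the tally volume. The conversion is applied per batch so the standard
#' error propagates exactly linearly.
#'
#' @param tr a `tally_result` from an `"efluence"` tally.
#' @param xs an `attenuation_table`.
#' @return list with `kerma_Gy` (per history), `sigma_Gy`, `rel_sigma`,
#'   `batch_kerma_Gy`.
#' @export
fluence_to_kerma <- function(tr, xs) {
  sp <- tr$spec
  if (sp$kind != "efluence")
    stop("tally is not an energy-fluence tally", call. = FALSE)
  nb <- sp$nbins
  if (ncol(tr$batch_means) != nb)
    stop("bin count mismatch between tally and result", call. = FALSE)
  edges <- seq(sp$emin, sp$emax, length.out = nb + 1)
  ec <- (edges[-1] + edges[-(nb + 1)]) / 2
  vol <- pi * sp$radius^2 * (2 * sp$half_length)      # mm3
  muen <- mu_rho(xs, "air", ec, "en")
  # track length [mm] / volume [mm3] -> fluence [1/mm2]; then as in air_kerma
  w <- ec * muen * .KERMA_UGY * 1e-6                  # -> Gy per (1/mm2)
  bk <- as.numeric(tr$batch_means %*% w) / vol
  st <- batch_statistics(bk)
  list(kerma_Gy = st$mean, sigma_Gy = st$sigma, rel_sigma = st$rel_sigma,
       batch_kerma_Gy = bk)
}

#' Sample Compton scattering events
#'
#' Draws (scattered energy, polar angle) pairs from the free-electron
#' Klein-Nishina differential cross section at a given incident energy,
#' using the same rejection sampler as the transport kernel.
#'
#' @param n number of draws.
#' @param energy_keV incident photon energy.
#' @return data.frame with `energy_keV` (scattered) and `theta_rad`.
#' @export
sample_compton <- function(n, energy_keV) {
  stopifnot(energy_keV > 0)
  m <- kn_sample_cpp(as.integer(n), energy_keV)
  data.frame(energy_keV = m[, 1], theta_rad = acos(pmin(1, pmax(-1, m[, 2]))))
}

#' Low-level tracking interface
#'
#' Transports explicit photons through a phantom (no protocol/scanner
#' needed); used for analytic benchmark tests such as slab transmission and
#' free-path distribution checks.
#'
#' @param position,direction n x 3 matrices (mm; unit directions).
#' @param energy_keV photon energies.
#' @param phantom a `voxel_phantom`.
#' @param tallies list of `tally_spec`s (may be empty).
#' @param xs an `attenuation_table`.
#' @param cutoff_keV photon cutoff (default 1).
#' @param record_first_collision record the distance to the first real
#'   collision per photon.
#' @return kernel output list: `scores`, `total_edep`, `escape_energy`,
#'   `n_escaped`, optionally `first_collision_mm`.
#' @export
track_photons <- function(position, direction, energy_keV, phantom,
                          tallies = list(), xs = load_attenuation(),
                          cutoff_keV = 1, record_first_collision = FALSE) {
  prep <- .prepare_xs(phantom, xs, max(energy_keV) + 1)
  tl <- lapply(tallies, function(t) {
    if (t$kind == "efluence") {
      if (is.null(t$emin)) t$emin <- cutoff_keV
      if (is.null(t$emax)) t$emax <- max(energy_keV) + 1
    }
    t
  })
  transport_kernel(position, direction, energy_keV,
                   rep(1, nrow(position)), as.integer(phantom$dims),
                   phantom$spacing_mm, phantom$origin_mm,
                   as.integer(phantom$material_index) - 1L,
                   as.numeric(phantom$density), prep$egrid[1], 1.0,
                   prep$tot, prep$pe, prep$inc, prep$majorant,
                   cutoff_keV, tl, record_first_collision)
}

#' Convert a deposited-energy tally to absorbed dose
#'
#' @param edep_keV deposited energy per history (keV).
#' @param volume_mm3 tally volume.
#' @param density_g_cm3 medium density in the tally.
#' @return dose per history, Gy.
#' @export
edep_to_dose <- function(edep_keV, volume_mm3, density_g_cm3) {
  mass_g <- volume_mm3 * 1e-3 * density_g_cm3
  edep_keV * .KEV_PER_G_TO_GY / mass_g
}
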