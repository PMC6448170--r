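# Dose reporting: CTDI and table-attenuation correction factors, start-angle
# averaging with error propagation, and measurement-set statistics.

#' CTDI correction factor
#'
#' Ratio of measured to simulated air kerma at the center of the CTDI
#' phantom; applied post hoc (opt-in) to simulations in comparable
#' scattering environments.
#'
#' @param measured,simulated kerma values (same units, e.g. cGy);
#'   `simulated > 0`.
#' @return dimensionless factor.
#' @export
ctdi_correction_factor <- function(measured, simulated) {
  if (simulated <= 0) stop("simulated kerma must be positive", call. = FALSE)
  measured / simulated
}

#' Table attenuation correction factor
#'
#' Ratio of the simulated detector tally with the patient table present to
#' the tally without it; applied multiplicatively to analytic-geometry
#' results that cannot include the voxelized table.
#'
#' @param sim_with_table,sim_without_table positive simulated kerma values.
#' @return dimensionless factor.
#' @export
table_attenuation_factor <- function(sim_with_table, sim_without_table) {
  if (sim_with_table <= 0 || sim_without_table <= 0)
    stop("inputs must be positive", call. = FALSE)
  sim_with_table / sim_without_table
}

#' Average a helical run over tube start angles
#'
#' Runs the simulation at each start angle (default 0, 90, 180, 270 degrees),
#' averages the per-tally doses and propagates the statistical errors as
#' \eqn{\sigma = \sqrt{\sum_i \sigma_i^2} / n}. Axial protocols warn and run
#' once (the start angle has no effect there).
#'
#' @param protocol a `scan_protocol` (helical).
#' @param runner function(protocol) returning a list/data.frame with columns
#'   `dose` and `sigma` (one row per tally).
#' @param angles_deg start angles in degrees.
#' @return data.frame with averaged `dose`, propagated `sigma`, and the
#'   per-angle doses as an attribute.
#' @export
average_over_start_angles <- function(protocol, runner,
                                      angles_deg = c(0, 90, 180, 270)) {
  if (protocol$mode != "helical") {
    warning("start-angle averaging applies to helical mode; running once",
            call. = FALSE)
    r <- runner(protocol)
    return(data.frame(dose = r$dose, sigma = r$sigma))
  }
  runs <- lapply(angles_deg, function(a) {
    p <- protocol
    p$start_angle_rad <- a * pi / 180
    runner(p)
  })
  doses <- vapply(runs, function(r) r$dose, numeric(length(runs[[1]]$dose)))
  sigmas <- vapply(runs, function(r) r$sigma,
                   numeric(length(runs[[1]]$sigma)))
  doses <- matrix(doses, ncol = length(angles_deg))
  sigmas <- matrix(sigmas, ncol = length(angles_deg))
  out <- data.frame(dose = rowMeans(doses),
                    sigma = sqrt(rowSums(sigmas^2)) / length(angles_deg))
  attr(out, "per_angle") <- doses
  out
}

#' Average repeated dose measurements
#'
#' \eqn{D_{avg} = \bar D} and
#' \eqn{\sigma_{avg} = \frac{1}{n}\sqrt{\sum_i (D_i r_{cf})^2}}, propagating
#' the detector's relative calibration error through the mean of repeated
#' measurements.
#'
#' @param doses repeated dose readings (cGy), `n >= 1`.
#' @param r_cf relative calibration error of the detector (e.g. 0.10).
#' @return list with `D_avg`, `sigma_avg`.
#' @export
average_measured_dose <- function(doses, r_cf) {
  if (length(doses) < 1) stop("empty measurement set", call. = FALSE)
  stopifnot(r_cf >= 0)
  list(D_avg = mean(doses),
       sigma_avg = sqrt(sum((doses * r_cf)^2)) / length(doses))
}

#' Assemble a dose report
#'
#' Carries per-tally doses with uncertainties, applied correction factors and
#' run provenance. Correction factors are applied at most once each
#' (idempotence guard).
#'
#' @param doses data.frame with `tally`, `dose_cGy`, `sigma_cGy`.
#' @param protocol the `scan_protocol` used.
#' @param seed,n_histories provenance.
#' @param model_hash hash of the scanner model (optional).
#' @return a `dose_report`.
#' @export
dose_report <- function(doses, protocol, seed, n_histories,
                        model_hash = NA_character_) {
  stopifnot(all(doses$dose_cGy >= 0))
  structure(list(doses = doses, protocol = protocol, seed = seed,
                 n_histories = n_histories, model_hash = model_hash,
                 corrections = list()),
            class = "dose_report")
}

#' @rdname dose_report
#' @param report a `dose_report`.
#' @param factor multiplicative correction.
#' @param type `"ctdi"` or `"table"`; each may be applied only once.
#' @export
apply_correction <- function(report, factor,
                             type = c("ctdi", "table")) {
  type <- match.arg(type)
  if (!is.null(report$corrections[[type]]))
    stop("correction '", type, "' already applied", call. = FALSE)
  report$doses$dose_cGy <- report$doses$dose_cGy * factor
  report$doses$sigma_cGy <- report$doses$sigma_cGy * factor
  report$corrections[[type]] <- factor
  report
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>", nrow(x$doses), "tallies,",
      format(x$n_histories, big.mark = ","), "histories, seed", x$seed, "\n")
  df <- x$doses
  df$dose_cGy <- round(df$dose_cGy, 2)     # display rounding only
  df$sigma_cGy <- signif(df$sigma_cGy, 3)
  print(df, row.names = FALSE)
  if (length(x$corrections))
    cat("corrections:",
        paste(names(x$corrections), "=",
              sprintf("%.2f", unlist(x$corrections)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a dose report to JSON (full precision) and CSV
#' @param report a `dose_report`.
#' @param path base path; `<path>.json` and `<path>.csv` are written.
#' @export
write_dose_report <- function(report, path) {
  jsonlite::write_json(list(doses = report$doses,
                            corrections = report$corrections,
                            seed = report$seed,
                            n_histories = report$n_histories,
                            model_hash = report$model_hash,
                            protocol = unclass(report$protocol)),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE,
                       null = "null")
  write.csv(report$doses, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
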