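# Acquisition sampling: scan protocol, table travel, tube trajectory for
# axial / helical / TCM modes, and source-photon emission.

#' Scan protocol
#'
#' Acquisition parameters for one scan. The frame is right-handed with the
#' origin at isocenter, +z along table travel and +y up; the gantry angle
#' beta is measured from the +y axis. The phantom is static and the tube
#' translates.
#'
#' @param mode `"axial"` or `"helical"`.
#' @param kv tube potential (kV).
#' @param mA fixed tube current (ignored when `tcm` given).
#' @param tcm optional [tcm_table()] for tube current modulation (helical).
#' @param rotation_time_s time per gantry rotation.
#' @param exposure_time_s total exposure time.
#' @param pitch helical pitch (table travel per rotation / collimation).
#' @param collimation_mm nominal beam collimation.
#' @param start_angle_rad initial tube angle from +y.
#' @param start_z_mm initial tube z.
#' @param direction +1 (head-first) or -1 (feet-first) table direction.
#' @param tube_to_iso_mm focal spot to isocenter distance.
#' @param rotating FALSE parks the tube at `start_angle_rad` (service-mode
#'   measurements); default TRUE.
#' @return a `scan_protocol`.
#' @export
scan_protocol <- function(mode = c("axial", "helical"), kv = 120, mA = 300,
                          tcm = NULL, rotation_time_s = 1,
                          exposure_time_s = 1, pitch = 1,
                          collimation_mm = 80, start_angle_rad = 0,
                          start_z_mm = 0, direction = 1,
                          tube_to_iso_mm = 625.6, rotating = TRUE) {
  mode <- match.arg(mode)
  stopifnot(kv > 0, rotation_time_s > 0, exposure_time_s > 0,
            collimation_mm > 0, direction %in% c(-1, 1), tube_to_iso_mm > 0)
  if (mode == "helical") stopifnot(pitch > 0)
  if (is.null(tcm)) stopifnot(mA > 0)
  structure(list(mode = mode, kv = kv, mA = mA, tcm = tcm,
                 rotation_time_s = rotation_time_s,
                 exposure_time_s = exposure_time_s, pitch = pitch,
                 collimation_mm = collimation_mm,
                 start_angle_rad = start_angle_rad, start_z_mm = start_z_mm,
                 direction = direction, tube_to_iso_mm = tube_to_iso_mm,
                 rotating = rotating),
            class = "scan_protocol")
}

#' Tube current modulation table
#'
#' Per reconstructed slice: z position and average tube current.
#' @param slice_z_mm sorted slice positions.
#' @param mA positive average currents, one per slice.
#' @return a `tcm_table`.
#' @export
tcm_table <- function(slice_z_mm, mA) {
  stopifnot(length(slice_z_mm) == length(mA), all(mA > 0),
            !is.unsorted(slice_z_mm))
  structure(list(slice_z_mm = as.numeric(slice_z_mm), mA = as.numeric(mA)),
            class = "tcm_table")
}

#' Helical table travel
#'
#' \eqn{T_z = P \cdot Col \cdot Exp_{time} / Rot_{time}}. Axial protocols
#' return 0 with a warning.
#'
#' @param protocol a `scan_protocol`.
#' @return travel in mm.
#' @export
table_travel <- function(protocol) {
  if (protocol$mode != "helical") {
    warning("table travel is defined for helical mode; returning 0",
            call. = FALSE)
    return(0)
  }
  protocol$pitch * protocol$collimation_mm * protocol$exposure_time_s /
    protocol$rotation_time_s
}

#' Build the TCM z-sampling PDF
#'
#' Slice bins are histogram bins; the probability of a slice is proportional
#' to its average mA, uniform within a slice.
#'
#' @param tcm a `tcm_table`.
#' @param scan_range_mm length-2 interval the table must cover.
#' @return list with `z_edges` (mm) and `pdf` per slice bin (sums to 1).
#' @export
build_tcm_pdf <- function(tcm, scan_range_mm = range(tcm$slice_z_mm)) {
  if (length(tcm$mA) == 0) stop("empty TCM table", call. = FALSE)
  z <- tcm$slice_z_mm
  w <- if (length(z) > 1) diff(z)[1] else 1
  edges <- c(z - w / 2, max(z) + w / 2)
  if (scan_range_mm[1] < min(edges) - 1e-9 ||
      scan_range_mm[2] > max(edges) + 1e-9)
    stop("TCM table does not cover the scan range", call. = FALSE)
  list(z_edges = edges, pdf = tcm$mA / sum(tcm$mA))
}

#' Sample tube states
#'
#' Axial: z fixed at the station, beta uniform on the circumference (or
#' parked when `rotating = FALSE`). Helical fixed-current: z uniform over the
#' table travel, beta advancing deterministically by
#' \eqn{2\pi |z_p - z_i| / (P \cdot Col)}. Helical TCM: z drawn from the TCM
#' PDF, beta from the same helix relation. Tube (x, y) lie on the circle of
#' radius `tube_to_iso_mm`.
#'
#' @param protocol a `scan_protocol`.
#' @param n number of states.
#' @return data.frame with `z_p`, `beta_p`, `x_p`, `y_p`.
#' @export
sample_tube_state <- function(protocol, n) {
  r <- protocol$tube_to_iso_mm
  zi <- protocol$start_z_mm
  if (protocol$mode == "axial") {
    z <- rep(zi, n)
    beta <- if (protocol$rotating) runif(n, 0, 2 * pi)
            else rep(protocol$start_angle_rad, n)
  } else {
    if (is.null(protocol$tcm)) {
      tz <- table_travel(protocol)
      z <- zi + protocol$direction * tz * runif(n)
    } else {
      p <- build_tcm_pdf(protocol$tcm)
      bin <- sample.int(length(p$pdf), n, replace = TRUE, prob = p$pdf)
      z <- p$z_edges[bin] + runif(n) * diff(p$z_edges)[bin]
    }
    beta <- protocol$start_angle_rad + abs(z - zi) * 2 * pi /
      (protocol$pitch * protocol$collimation_mm)
    if (!protocol$rotating) beta <- rep(protocol$start_angle_rad, n)
  }
  data.frame(z_p = z, beta_p = beta, x_p = r * sin(beta), y_p = r * cos(beta))
}

#' Emit source photons
#'
#' Composes the tube-state, bowtie-exit and heel samplers: the photon starts
#' at the focal spot, its direction passes through the sampled (fan, cone)
#' exit point in the isocenter plane, and its energy is drawn from the chosen
#' bowtie bin's post-filtration spectrum (uniform within the 1-keV bin).
#' Weight is 1.
#'
#' @param protocol a `scan_protocol`.
#' @param scanner a fitted `scanner_model`.
#' @param n number of photons.
#' @return list of matrices/vectors: `position` (n x 3, mm), `direction`
#'   (n x 3, unit), `energy` (keV), `weight`.
#' @export
emit_photons <- function(protocol, scanner, n) {
  if (is.null(scanner$bowtie$pdf))
    stop("scanner model is not fitted (bowtie PDF missing)", call. = FALSE)
  r <- protocol$tube_to_iso_mm
  st <- sample_tube_state(protocol, n)
  bw <- sample_bowtie_exit(scanner$bowtie, n, r)
  hz <- sample_heel_z(scanner$beam, n, r)
  # energies: group photons by bowtie bin, draw from that bin's spectrum
  edges <- scanner$bowtie$base_spectrum$energy_edges
  energy <- numeric(n)
  for (b in unique(bw$bin)) {
    idx <- which(bw$bin == b)
    p <- scanner$bowtie$per_bin_spectrum[, b]
    eb <- sample.int(length(p), length(idx), replace = TRUE, prob = p)
    energy[idx] <- edges[eb] + runif(length(idx)) * (edges[eb + 1] - edges[eb])
  }
  sb <- sin(st$beta_p); cb <- cos(st$beta_p)
  pos <- cbind(r * sb, r * cb, st$z_p)
  x_mm <- bw$x_cm * 10
  tgt <- cbind(x_mm * cb, -x_mm * sb, st$z_p + hz$z_mm)
  d <- tgt - pos
  d <- d / sqrt(rowSums(d^2))
  list(position = pos, direction = d, energy = energy, weight = rep(1, n))
}

#' Read a scan protocol from a flat key=value config file
#'
#' Recognized keys: `mode, kv, ma, tcm_file, rotation_time_s,
#' exposure_time_s, pitch, collimation_mm, start_angle_deg, start_z_mm,
#' direction, tube_to_iso_mm, rotating`. `tcm_file` points to a CSV with
#' columns `slice_z_mm,ma`.
#'
#' @param path config file path.
#' @return a `scan_protocol`.
#' @export
read_protocol <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(vapply(kv, `[`, "", 2), trimws(vapply(kv, `[`, "", 1)))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  tcm <- NULL
  if ("tcm_file" %in% names(vals)) {
    df <- read.csv(file.path(dirname(path), vals[["tcm_file"]]))
    tcm <- tcm_table(df$slice_z_mm, df$ma)
  }
  scan_protocol(
    mode = if ("mode" %in% names(vals)) vals[["mode"]] else "axial",
    kv = num("kv", 120), mA = num("ma", 300), tcm = tcm,
    rotation_time_s = num("rotation_time_s", 1),
    exposure_time_s = num("exposure_time_s", 1),
    pitch = num("pitch", 1), collimation_mm = num("collimation_mm", 80),
    start_angle_rad = num("start_angle_deg", 0) * pi / 180,
    start_z_mm = num("start_z_mm", 0), direction = num("direction", 1),
    tube_to_iso_mm = num("tube_to_iso_mm", 625.6),
    rotating = num("rotating", 1) != 0)
}
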