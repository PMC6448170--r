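helical <- scan_protocol("helical", kv = 120, mA = 300,
                         rotation_time_s = 0.5, exposure_time_s = 1.05,
                         pitch = 1.531, collimation_mm = 80,
                         start_angle_rad = 0.3, start_z_mm = -50)

test_that("table travel follows pitch * collimation * time ratio", {
  p <- scan_protocol("helical", pitch = 1, collimation_mm = 80,
                     exposure_time_s = 1, rotation_time_s = 1)
  expect_equal(table_travel(p), 80)
  # helical protocol of the wide-beam chest scan: hand-evaluated value
  expect_equal(table_travel(helical), 1.531 * 80 * 1.05 / 0.5)
  expect_equal(table_travel(helical), 257.208)
  p2 <- p; p2$pitch <- 2
  expect_equal(table_travel(p2), 2 * table_travel(p))
  expect_warning(tz <- table_travel(scan_protocol("axial")), "helical")
  expect_equal(tz, 0)
})

test_that("tube states: limits, helix closure, circle invariant", {
  set.seed(11)
  st <- sample_tube_state(helical, 1e5)
  tz <- table_travel(helical)
  # epsilon = 0 limit: z starts at z_i with beta_i
  expect_true(all(st$z_p >= helical$start_z_mm - 1e-9 &
                    st$z_p <= helical$start_z_mm + tz + 1e-9))
  # helix closure: delta beta / delta z = 2 pi / (P * Col) exactly
  dz <- abs(st$z_p - helical$start_z_mm)
  expect_equal(st$beta_p, helical$start_angle_rad +
                 dz * 2 * pi / (1.531 * 80), tolerance = 1e-12)
  # one full rotation per P * Col of travel
  k <- 2 * pi / (1.531 * 80)
  expect_equal((1.531 * 80) * k, 2 * pi)
  # circle invariant in every mode
  r2 <- st$x_p^2 + st$y_p^2
  expect_equal(r2, rep(helical$tube_to_iso_mm^2, 1e5), tolerance = 1e-9)
  # z uniform over the travel range
  ks <- stats::ks.test((st$z_p - helical$start_z_mm) / tz, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("axial states: fixed z, uniform or parked angle", {
  set.seed(12)
  ax <- scan_protocol("axial", start_z_mm = 25)
  st <- sample_tube_state(ax, 2e4)
  expect_true(all(st$z_p == 25))
  expect_gt(stats::ks.test(st$beta_p / (2 * pi), "punif")$p.value, 0.001)
  parked <- scan_protocol("axial", start_angle_rad = 1.2, rotating = FALSE)
  stp <- sample_tube_state(parked, 100)
  expect_true(all(stp$beta_p == 1.2))
})

test_that("TCM pdf: arithmetic, uniformity, sampling", {
  tcm <- tcm_table(c(0, 10), c(100, 300))
  p <- build_tcm_pdf(tcm)
  expect_equal(p$pdf, c(0.25, 0.75))
  expect_equal(sum(p$pdf), 1, tolerance = 1e-12)
  const <- build_tcm_pdf(tcm_table(seq(0, 90, 10), rep(250, 10)))
  expect_equal(const$pdf, rep(0.1, 10))
  expect_error(build_tcm_pdf(tcm_table(c(0, 10), c(100, 300)),
                             scan_range_mm = c(-50, 50)), "cover")
  # sampled slice frequencies match the pdf
  set.seed(13)
  tcm2 <- tcm_table(seq(5, 95, 10), c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1) * 60)
  prot <- scan_protocol("helical", tcm = tcm2, pitch = 1.531,
                        collimation_mm = 80, start_z_mm = 0)
  st <- sample_tube_state(prot, 1e5)
  pdf <- build_tcm_pdf(tcm2)
  bin <- findInterval(st$z_p, pdf$z_edges, rightmost.closed = TRUE)
  obs <- tabulate(bin, nbins = 10)
  chi <- sum((obs - 1e5 * pdf$pdf)^2 / (1e5 * pdf$pdf))
  expect_gt(stats::pchisq(chi, df = 9, lower.tail = FALSE), 0.001)
})

test_that("constant-mA TCM sampling equals fixed-current sampling", {
  set.seed(14)
  fixed <- scan_protocol("helical", pitch = 1.531, collimation_mm = 80,
                         exposure_time_s = 1.05, rotation_time_s = 0.5,
                         start_z_mm = 0)
  tz <- table_travel(fixed)
  nslice <- 50
  w <- tz / nslice
  tcm <- tcm_table(seq(w / 2, tz - w / 2, length.out = nslice),
                   rep(300, nslice))
  tcmp <- fixed; tcmp$tcm <- tcm
  z1 <- sample_tube_state(fixed, 1e5)$z_p
  z2 <- sample_tube_state(tcmp, 1e5)$z_p
  # float ties are possible at 1e5 draws; the approximate p is fine here
  ks <- suppressWarnings(stats::ks.test(z1, z2))
  expect_gt(ks$p.value, 0.001)
})

test_that("emitted photons: energy bounds, spectrum histogram, geometry", {
  set.seed(15)
  ph <- emit_photons(PROT_STATIC, SCANNER80, 1e5)
  expect_true(all(ph$energy > 1 & ph$energy <= 120))
  expect_equal(rowSums(ph$direction^2), rep(1, 1e5), tolerance = 1e-12)
  expect_true(all(ph$weight == 1))
  # energy histogram vs the fluence-weighted mixture over bowtie bins
  bt <- SCANNER80$bowtie
  norm_spec <- sweep(bt$per_bin_spectrum, 2,
                     colSums(bt$per_bin_spectrum), "/")
  mix <- as.numeric(norm_spec %*% bt$pdf)   # pdf-weighted bin spectra
  mix <- mix / sum(mix)
  edges <- bt$base_spectrum$energy_edges
  obs <- tabulate(findInterval(ph$energy, edges, rightmost.closed = TRUE),
                  nbins = length(mix))
  keep <- mix * 1e5 >= 5
  chi <- sum((obs[keep] - 1e5 * mix[keep])^2 / (1e5 * mix[keep]))
  expect_gt(stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE),
            0.001)
})

test_that("degenerate single-bin profiles aim every ray at isocenter", {
  mono <- mono_spectrum(60)
  eps <- 5e-4
  bt <- structure(list(bin_edges = c(-eps, eps), thickness_mm = 0,
                       per_bin_spectrum = matrix(1, 1, 1), pdf = 1,
                       base_spectrum = mono, material = "aluminum"),
                  class = "bowtie_profile")
  bp <- structure(list(z_edges = c(-eps, eps), intensity = 1, pdf = 1,
                       fwhm_mm = 1), class = "beam_profile")
  sm <- scanner_model(bt, bp, source_geometry(625.6))
  prot <- scan_protocol("axial", kv = 61, rotating = TRUE)
  set.seed(16)
  ph <- emit_photons(prot, sm, 500)
  # distance from each ray to the z axis (isocenter axis)
  p <- ph$position; d <- ph$direction
  dist <- abs(p[, 1] * d[, 2] - p[, 2] * d[, 1]) /
    sqrt(d[, 1]^2 + d[, 2]^2)
  expect_lt(max(dist), 0.1)
})

test_that("protocol config file round-trip", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("mode = helical", "kv = 120", "ma = 300",
               "rotation_time_s = 0.5", "exposure_time_s = 1.05",
               "pitch = 1.531", "collimation_mm = 80",
               "start_angle_deg = 90", "start_z_mm = -50",
               "tcm_file = tcm.csv"),
             file.path(dir, "prot.cfg"))
  write.csv(data.frame(slice_z_mm = c(0, 10), ma = c(100, 300)),
            file.path(dir, "tcm.csv"), row.names = FALSE)
  p <- read_protocol(file.path(dir, "prot.cfg"))
  expect_equal(p$mode, "helical")
  expect_equal(p$pitch, 1.531)
  expect_equal(p$start_angle_rad, pi / 2)
  expect_equal(p$tcm$mA, c(100, 300))
})
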