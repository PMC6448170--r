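test_that("bowtie fit: trivial ratios and monoenergetic closed form", {
  meas <- data.frame(distance_cm = 0, normalized_exposure = 1)
  bt <- fit_bowtie_thickness(meas, SPEC_ISO, XS)
  expect_equal(bt$thickness_mm, 0)
  mono <- mono_spectrum(60)
  meas2 <- data.frame(distance_cm = c(0, 1),
                      normalized_exposure = c(1, 0.5))
  bt2 <- fit_bowtie_thickness(meas2, mono, XS, material = "aluminum")
  analytic <- log(2) * 10 /
    (mu_rho(XS, "aluminum", 60) * XS$aluminum$density)
  # mirrored: thickness vector is (t, 0, t)
  expect_equal(bt2$thickness_mm, c(analytic, 0, analytic),
               tolerance = 1e-6)
})

test_that("bowtie fit round-trips a known thickness profile within 0.5%", {
  meas <- synthetic_bowtie_measurement(SPEC_ISO, XS)
  truth <- attr(meas, "thickness_mm")
  bt <- fit_bowtie_thickness(meas, SPEC_ISO, XS)
  n <- length(bt$thickness_mm)
  fitted <- bt$thickness_mm[((n + 1) / 2):n]      # center outward
  rel <- abs(fitted - truth) / pmax(truth, 1)     # guard the zero center
  expect_lt(max(rel), 0.005)
  expect_error(fit_bowtie_thickness(
    data.frame(distance_cm = 0, normalized_exposure = 1.2), SPEC_ISO, XS),
    "0, 1")
})

test_that("bowtie PDF: normalization, symmetry, opacity, summation oracle", {
  bt <- SCANNER80$bowtie
  expect_equal(sum(bt$pdf), 1, tolerance = 1e-12)
  # mirrored profile must give a symmetric pdf
  expect_equal(bt$pdf, rev(bt$pdf), tolerance = 1e-12)
  # brute-force oracle: photon totals per bin normalized
  w <- diff(bt$bin_edges)
  totals <- apply(bt$per_bin_spectrum, 2, sum) * w
  expect_equal(bt$pdf, totals / sum(totals), tolerance = 1e-12)
  # uniform thickness -> uniform pdf; opaque bin -> ~zero probability
  mono <- mono_spectrum(60)
  bt_u <- fit_bowtie_thickness(
    data.frame(distance_cm = 0:3,
               normalized_exposure = rep(1, 4)), mono, XS, mirror = FALSE)
  expect_equal(bt_u$pdf, rep(0.25, 4), tolerance = 1e-12)
  bt_o <- fit_bowtie_thickness(
    data.frame(distance_cm = 0:1, normalized_exposure = c(1, 1e-9)),
    mono, XS, mirror = FALSE)
  expect_lt(bt_o$pdf[2], 1e-8)
})

test_that("bowtie sampling matches its PDF and geometry", {
  set.seed(42)
  bt <- SCANNER80$bowtie
  s <- sample_bowtie_exit(bt, 1e5, 625.6)
  # every exit coordinate inside its bin
  expect_true(all(s$x_cm >= bt$bin_edges[s$bin] &
                    s$x_cm <= bt$bin_edges[s$bin + 1]))
  obs <- tabulate(s$bin, nbins = length(bt$pdf))
  keep <- bt$pdf * 1e5 >= 5
  chi <- sum((obs[keep] - 1e5 * bt$pdf[keep])^2 / (1e5 * bt$pdf[keep]))
  p <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
  # exit at the isocenter projection -> fan angle 0
  expect_equal(atan(0 / 625.6), 0)
  expect_equal(s$fan_angle, atan(s$x_cm * 10 / 625.6))
})

test_that("heel sampling: symmetry, confinement, distribution", {
  set.seed(43)
  # symmetric rectangular profile -> mean z near 0
  z <- seq(-60, 60, by = 1)
  sym <- beam_profile(z, ifelse(abs(z) <= 40, 1, 1e-4))
  s <- sample_heel_z(sym, 1e5, 625.6)
  sigma_mean <- stats::sd(s$z_mm) / sqrt(1e5)
  expect_lt(abs(mean(s$z_mm)), 3 * sigma_mean + 0.5)
  expect_equal(s$cone_angle, atan(s$z_mm / 625.6))
  # delta profile confines z to one bin
  one <- structure(list(z_edges = c(0, 1), intensity = 1, pdf = 1,
                        fwhm_mm = 10), class = "beam_profile")
  s1 <- sample_heel_z(one, 1000, 625.6)
  expect_true(all(s1$z_mm >= 0 & s1$z_mm <= 10))
  # empirical frequencies match the H_j pdf
  bp <- SCANNER80$beam
  sh <- sample_heel_z(bp, 1e5, 625.6)
  obs <- tabulate(sh$bin, nbins = length(bp$pdf))
  keep <- bp$pdf * 1e5 >= 5
  chi <- sum((obs[keep] - 1e5 * bp$pdf[keep])^2 / (1e5 * bp$pdf[keep]))
  expect_gt(stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE),
            0.001)
})

test_that("fwhm: rectangle, Gaussian, asymmetric triangle oracle", {
  z <- seq(-100, 100, by = 0.1)
  rect <- as.numeric(abs(z) <= 40)
  expect_equal(fwhm(z, rect), 80, tolerance = 0.2)
  gauss <- exp(-z^2 / (2 * 10^2))
  expect_equal(fwhm(z, gauss), 2 * sqrt(2 * log(2)) * 10,
               tolerance = 0.05)
  tri <- pmax(0, pmin((z + 30) / 50, (10 - z) / 20))
  w <- fwhm(z, tri)
  # dense brute-force crossing search
  zz <- seq(-100, 100, by = 1e-4)
  yy <- approx(z, tri, zz)$y
  above <- zz[yy >= max(tri) / 2]
  expect_equal(w, max(above) - min(above), tolerance = 1e-3)
  expect_error(fwhm(z, z * 0 + 1), "half maximum")
})

test_that("source strength: one-term closed form, linearity, triple loop", {
  mono <- mono_spectrum(60, fluence = 1234)
  bt1 <- structure(list(bin_edges = c(-0.5, 0.5), thickness_mm = 0,
                        per_bin_spectrum = matrix(1234, 1, 1), pdf = 1,
                        base_spectrum = mono, material = "aluminum"),
                   class = "bowtie_profile")
  bp1 <- structure(list(z_edges = c(-0.5, 0.5), intensity = 0.8, pdf = 1,
                        fwhm_mm = 10), class = "beam_profile")
  geom <- source_geometry(600)
  # single bins centred at isocenter: A=100 mm2, D=SDD
  q <- source_strength(bt1, bp1, geom, mAs = 2)
  expect_equal(q, 0.8 * (100 * 600 / 600^2) * 1234 * 2, tolerance = 1e-12)
  # linearity in mAs and in H_j
  expect_equal(source_strength(bt1, bp1, geom, 4), 2 * q)
  bp2 <- bp1; bp2$intensity <- 1.6
  expect_equal(source_strength(bt1, bp2, geom, 2), 2 * q)
  # multi-bin fixture equals a brute-force triple loop
  bt <- SCANNER80$bowtie; bp <- SCANNER80$beam
  sdd <- 625.6
  xi <- (bt$bin_edges[-1] + head(bt$bin_edges, -1)) * 5
  zj <- (bp$z_edges[-1] + head(bp$z_edges, -1)) * 5
  brute <- 0
  for (i in seq_along(xi)) for (j in seq_along(zj)) {
    d_ij <- sqrt(sdd^2 + xi[i]^2 + zj[j]^2)
    for (k in seq_len(nrow(bt$per_bin_spectrum)))
      brute <- brute + bp$intensity[j] * (100 * d_ij / sdd^2) *
        bt$per_bin_spectrum[k, i] * 300
  }
  expect_equal(source_strength(bt, bp, source_geometry(sdd), 300), brute,
               tolerance = 1e-9)
})

test_that("scanner model serializes through JSON losslessly", {
  path <- tempfile(fileext = ".json")
  write_scanner_model(SCANNER80, path)
  back <- read_scanner_model(path)
  expect_equal(back$bowtie$thickness_mm, SCANNER80$bowtie$thickness_mm)
  expect_equal(back$bowtie$pdf, SCANNER80$bowtie$pdf)
  expect_equal(back$beam$pdf, SCANNER80$beam$pdf)
  expect_equal(back$beam$fwhm_mm, SCANNER80$beam$fwhm_mm)
  expect_equal(back$geometry$tube_to_iso_mm,
               SCANNER80$geometry$tube_to_iso_mm)
  q1 <- source_strength(SCANNER80$bowtie, SCANNER80$beam,
                        SCANNER80$geometry, 300)
  q2 <- source_strength(back$bowtie, back$beam, back$geometry, 300)
  expect_equal(q1, q2)
})
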