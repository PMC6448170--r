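# Transport kernel physics: free paths, analytic transmission, Compton
# sampling, estimator equivalence, energy conservation and error scaling.

pencil <- function(n, energy, x0 = -199, dir = c(1, 0, 0)) {
  list(position = matrix(rep(c(x0, 0, 0), each = n), n, 3),
       direction = matrix(rep(dir, each = n), n, 3),
       energy = rep(energy, n))
}

test_that("free-path lengths in a homogeneous medium are exponential", {
  set.seed(31)
  ph <- uniform_phantom(0)                # water everywhere
  n <- 1e5
  src <- pencil(n, 60, x0 = 0)
  res <- track_photons(src$position, src$direction, src$energy, ph,
                       xs = XS, record_first_collision = TRUE)
  mu <- mixture_mu(hu_to_composition(0), hu_to_density(0), 60, XS) / 10
  d <- res$first_collision_mm[!is.na(res$first_collision_mm)]
  t_max <- 200                            # box half-width along +x
  cdf <- function(q) (1 - exp(-mu * q)) / (1 - exp(-mu * t_max))
  ks <- stats::ks.test(d, cdf)
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(d), 1 / mu - t_max * exp(-mu * t_max) /
                 (1 - exp(-mu * t_max)), tolerance = 0.05)
})

test_that("zero-density phantom lets every photon escape with no deposit", {
  ph <- uniform_phantom(-1000, extent_mm = c(200, 200, 200))
  ph$density[] <- 0                       # true vacuum
  src <- pencil(1000, 60, x0 = -99)
  res <- track_photons(src$position, src$direction, src$energy, ph, xs = XS)
  expect_equal(res$n_escaped, 1000)
  expect_equal(res$total_edep, 0)
  expect_equal(res$escape_energy, 1000 * 60)
})

test_that("two-slab primary transmission matches Beer-Lambert within 3 sigma", {
  set.seed(32)
  # slab 1: water (HU 0) for x in [-100, 0); slab 2: bone (HU 1000)
  dims <- c(50L, 26L, 26L)
  hu <- array(0L, dims)
  hu[26:50, , ] <- 1000L
  ph <- voxel_phantom(hu, c(4, 4, 4), -(dims - 1) / 2 * c(4, 4, 4))
  n <- 2e5
  src <- pencil(n, 60, x0 = -99.9)
  res <- track_photons(src$position, src$direction, src$energy, ph, xs = XS,
                       record_first_collision = TRUE)
  p_primary <- mean(is.na(res$first_collision_mm))
  mu1 <- mixture_mu(hu_to_composition(0), hu_to_density(0), 60, XS) / 10
  mu2 <- mixture_mu(hu_to_composition(1000), hu_to_density(1000), 60,
                    XS) / 10
  t1 <- 99.9; t2 <- 100                    # slab boundary at x = 0
  expected <- exp(-mu1 * t1 - mu2 * t2)
  sigma <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(p_primary - expected), 3 * sigma + 1e-4)
})

test_that("Klein-Nishina sampler: kinematics and quadrature moments", {
  set.seed(33)
  E <- 100
  alpha <- E / 510.999
  s <- sample_compton(1e6, E)
  # kinematic identity and backscatter bound on every draw
  expect_equal(s$energy_keV,
               E / (1 + alpha * (1 - cos(s$theta_rad))), tolerance = 1e-9)
  expect_true(all(s$energy_keV >= E / (1 + 2 * alpha) - 1e-9))
  expect_true(all(s$energy_keV <= E + 1e-9))
  # mean scattered-energy fraction vs numerical quadrature, 3 sigma
  q <- kn_quadrature(E)
  frac <- s$energy_keV / E
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - q$mean_fraction), 3 * se)
})

test_that("energy is conserved to 1e-9 and absorbed beam stays inside", {
  set.seed(34)
  ph <- uniform_phantom(0, extent_mm = c(400, 400, 400),
                        spacing_mm = c(8, 8, 8))
  src <- pencil(2e4, 10, x0 = 0)           # 10 keV: mfp ~ 2 mm in water
  res <- track_photons(src$position, src$direction, src$energy, ph, xs = XS)
  emitted <- 2e4 * 10
  expect_lt(abs(res$total_edep + res$escape_energy - emitted) / emitted,
            1e-9)
  expect_gt(res$total_edep / emitted, 0.995)  # fully absorbing medium
})

test_that("fluence and deposition estimators agree on transfer kerma", {
  set.seed(35)
  ph <- make_fixture("air_chamber", spacing_mm = c(8, 8, 8))
  n <- 4e5
  E <- 60
  # broad parallel beam along the chamber axis covering its cross-section
  r_ch <- sqrt(3000 / (pi * 100))
  rr <- r_ch * sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
  pos <- cbind(rr * cos(phi), rr * sin(phi), -119)
  dir <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  tl <- list(chamber_tally(nbins = 30),
             tally_cylinder(c(0, 0, 0), "z", r_ch, 100, score = "edep",
                            name = "edep"))
  res <- track_photons(pos, dir, rep(E, n), ph, tallies = tl, xs = XS)
  flu <- res$scores[[1]]                  # mm track length per energy bin
  edep <- res$scores[[2]]                 # keV deposited in the cylinder
  # kernel-consistent transfer coefficient per energy bin: photoelectric
  # deposits all, Compton deposits the KN-average recoil fraction
  edges <- seq(1, 61, length.out = 31)
  ec <- (edges[-1] + edges[-31]) / 2
  rho_air <- XS$air$density
  mu_pe <- mu_rho(XS, "air", ec, "pe") * rho_air / 10       # 1/mm
  mu_inc <- mu_rho(XS, "air", ec, "incoh") * rho_air / 10
  ftr <- vapply(ec, function(e) kn_quadrature(e)$transfer_fraction,
                numeric(1))
  expected_edep <- sum(flu * ec * (mu_pe + ftr * mu_inc))
  # Poisson-dominated uncertainty on the deposit tally
  n_events <- edep / (0.5 * E)            # conservative event count proxy
  sigma <- expected_edep / sqrt(max(n_events, 1))
  expect_lt(abs(edep - expected_edep), 3 * sigma)
  expect_gt(edep, 0)
})

test_that("track-length fluence reproduces the inverse-square law", {
  set.seed(36)
  ph <- make_fixture("air_chamber", spacing_mm = c(8, 8, 8),
                     extent_mm = c(300, 300, 300))
  n <- 1e6
  # isotropic point source at the origin
  u <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  st <- sqrt(1 - u^2)
  dir <- cbind(st * cos(phi), st * sin(phi), u)
  pos <- matrix(0, n, 3)
  r0 <- 100
  tl <- list(tally_cylinder(c(r0, 0, 0), "z", 5, 10, score = "efluence",
                            nbins = 1, name = "probe"))
  res <- track_photons(pos, dir, rep(60, n), ph, tallies = tl, xs = XS)
  vol <- pi * 25 * 10
  flu <- res$scores[[1]] / n / vol        # 1/mm2 per history
  expected <- 1 / (4 * pi * r0^2)
  # ~600 photons traverse the probe; allow 3/sqrt(N) relative
  n_hit <- n * pi * 25 / (4 * pi * r0^2)
  expect_lt(abs(flu - expected) / expected, 3 / sqrt(n_hit) + 0.02)
})

test_that("batch statistics closed forms", {
  expect_equal(batch_statistics(c(3, 3, 3))$sigma, 0)
  bs <- batch_statistics(c(2, 6))
  expect_equal(bs$mean, 4)
  expect_equal(bs$sigma, abs(2 - 6) / 2)
  set.seed(37)
  x <- rnorm(64)
  bs2 <- batch_statistics(x)
  expect_equal(bs2$mean, mean(x))
  expect_equal(bs2$sigma, stats::sd(x) / 8)
  expect_equal(bs2$rel_sigma, bs2$sigma / abs(mean(x)))
  expect_error(batch_statistics(1), "2 batches")
})

test_that("simulation runs are reproducible and tally-order invariant", {
  ph <- make_fixture("air_chamber")
  cfg <- run_config(2e4, n_batches = 2, seed = 99)
  tl <- list(chamber_tally(),
             tally_cylinder(c(0, 0, 0), "z", 20, 100, score = "edep",
                            name = "edep"))
  r1 <- run_simulation(cfg, PROT_STATIC, SCANNER80, ph, tl, XS)
  r2 <- run_simulation(cfg, PROT_STATIC, SCANNER80, ph, tl, XS)
  expect_identical(r1$tallies$chamber$batch_means,
                   r2$tallies$chamber$batch_means)
  expect_identical(r1$accounting, r2$accounting)
  r3 <- run_simulation(cfg, PROT_STATIC, SCANNER80, ph, rev(tl), XS)
  expect_identical(r3$tallies$chamber$batch_means,
                   r1$tallies$chamber$batch_means)
})

test_that("statistical error scales like 1/sqrt(N)", {
  # the sigma estimate from k batches is itself noisy (~1/sqrt(2k)), so the
  # quadrupling ratio is averaged over three independent master seeds
  ph <- make_fixture("air_chamber")
  ratio <- vapply(c(5, 6, 7), function(seed) {
    rel <- vapply(c(250000, 1000000), function(n) {
      rs <- run_simulation(run_config(n, n_batches = 20, seed = seed),
                           PROT_STATIC, SCANNER80, ph,
                           list(chamber_tally()), XS)
      fluence_to_kerma(rs$tallies$chamber, XS)$rel_sigma
    }, numeric(1))
    rel[1] / rel[2]
  }, numeric(1))
  # quadrupling the histories should halve sigma, within 30%
  expect_lt(abs(mean(ratio) - 2), 0.6)
})

test_that("fluence-to-kerma conversion: zero and single-bin closed form", {
  spec <- chamber_tally(nbins = 2)
  spec$emin <- 1; spec$emax <- 121
  bm <- matrix(0, 2, 2)
  tr <- ctdosim:::.tally_result(spec, bm, 100, 2, 1)
  expect_equal(fluence_to_kerma(tr, XS)$kerma_Gy, 0)
  # one bin with known track length: K = (L/V) E muen conversion
  bm2 <- matrix(c(10, 10, 0, 0), 2, 2)    # 10 mm in bin 1, both batches
  tr2 <- ctdosim:::.tally_result(spec, bm2, 100, 2, 1)
  vol <- pi * spec$radius^2 * 2 * spec$half_length
  ec1 <- (1 + 61) / 2
  expected <- 10 / vol * ec1 * mu_rho(XS, "air", ec1, "en") *
    1.60218e-5 * 1e-6
  k <- fluence_to_kerma(tr2, XS)
  expect_equal(k$kerma_Gy, expected, tolerance = 1e-12)
  expect_equal(k$sigma_Gy, 0)
})
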