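# Mie amplitudes, efficiencies and the polarization-dependent phase function.

test_that("size parameter follows pi*d*n/lambda with input validation", {
  expect_equal(size_parameter(0, 1.33, 0.5), 0)
  expect_equal(size_parameter(0.5 / (pi * 1.33), 1.33, 0.5), 1)
  expect_equal(size_parameter(0.5, 1.33, 0.488), pi * 0.5 * 1.33 / 0.488)
  expect_equal(size_parameter(0.5, 1.33, 0.488), 4.281, tolerance = 1e-3)
  expect_error(size_parameter(0.5, 1.33, 0), "wavelength")
  expect_error(size_parameter(0.5, 0.9, 0.5), "index")
  expect_error(scatterer_spec(-1, 1.33, 1.59, 0.5), "diameter")
})

test_that("forward-scattering amplitudes are equal for all sizes", {
  for (alpha in c(0.01, 0.1, 1, 4.2807, 8.5, 20)) {
    amp <- mie_amplitudes(spec_for_alpha(alpha), c(0, pi / 3, pi))
    expect_equal(amp$S1[1], amp$S2[1], tolerance = 1e-14)
    expect_true(all(amp$S3 == 0) && all(amp$S4 == 0))
  }
})

test_that("Rayleigh limit: S1 constant and S2/S1 -> cos(theta)", {
  theta <- seq(0, pi, length.out = 101)
  amp <- mie_amplitudes(spec_for_alpha(0.01), theta)
  expect_lt(max(Mod(amp$S2 / amp$S1 - cos(theta))), 1e-3)
  expect_lt(max(Mod(amp$S1) / min(Mod(amp$S1))) - 1, 1e-3)
})

test_that("amplitudes agree with the doubled-truncation Bessel oracle", {
  theta <- seq(0, pi, length.out = 181)
  for (alpha in c(1, 4.2807, 8.5)) {
    spec <- spec_for_alpha(alpha)
    amp <- mie_amplitudes(spec, theta)
    ora <- oracle_mie_amplitudes(spec, theta)
    scale <- max(Mod(ora$S1))
    expect_lt(max(Mod(amp$S1 - ora$S1)) / scale, 1e-10)
    expect_lt(max(Mod(amp$S2 - ora$S2)) / scale, 1e-10)
  }
})

test_that("efficiencies: lossless identity, benchmark value, absorption", {
  eff <- mie_efficiencies(spec_for_alpha(4.2807))
  expect_equal(eff$Q_abs, 0, tolerance = 1e-12)
  expect_equal(eff$Q_ext, eff$Q_sca, tolerance = 1e-12)
  expect_lte(abs(eff$g), 1)
  # classic benchmark: x = 10, m = 1.5 gives Q_ext = 2.8820
  bench <- scatterer_spec(10 * 0.5 / pi, 1.0, 1.5, 0.5)
  expect_equal(mie_efficiencies(bench)$Q_ext, 2.8820, tolerance = 5e-5)
  # absorbing particle: Q_ext = Q_sca + Q_abs with Q_abs > 0
  ab <- scatterer_spec(0.5, 1.33, complex(real = 1.59, imaginary = 0.05),
                       0.488)
  effa <- mie_efficiencies(ab)
  expect_gt(effa$Q_abs, 0)
  expect_equal(effa$Q_ext, effa$Q_sca + effa$Q_abs, tolerance = 1e-12)
})

test_that("Q_sca equals the quadrature of the differential cross-section", {
  for (alpha in c(1, 4.2807, 8.5)) {
    spec <- spec_for_alpha(alpha)
    eff <- mie_efficiencies(spec)
    mu <- seq(-1, 1, length.out = 4001)
    amp <- mie_amplitudes(spec, acos(mu))
    q <- simpson(Mod(amp$S1)^2 + Mod(amp$S2)^2, mu[2] - mu[1]) /
      spec$size_parameter^2
    expect_equal(q, eff$Q_sca, tolerance = 1e-6)
  }
})

test_that("Rayleigh regime scattering efficiency scales as alpha^4", {
  q1 <- mie_efficiencies(spec_for_alpha(0.01))$Q_sca
  q2 <- mie_efficiencies(spec_for_alpha(0.02))$Q_sca
  slope <- log(q2 / q1) / log(2)
  expect_equal(slope, 4, tolerance = 0.02)
})

test_that("phase function is normalized over the sphere", {
  mu <- seq(-1, 1, length.out = 2001)
  phi <- 2 * pi * (0:63) / 64
  for (alpha in c(0.1, 1, 4)) {
    spec <- spec_for_alpha(alpha)
    for (L in c(0, 0.5, 1)) {
      F <- matrix(phase_function(spec, L, rep(acos(mu), length(phi)),
                                 rep(phi, each = length(mu))),
                  length(mu), length(phi))
      tot <- simpson(rowSums(F), mu[2] - mu[1]) * (2 * pi / length(phi))
      expect_lt(abs(tot - 1), 1e-6)
    }
  }
})

test_that("phase function: azimuthal symmetry at L = 0, cos(2 phi) at L = 1", {
  spec <- spec_for_alpha(1)
  phi <- seq(0, 2 * pi, length.out = 73)
  f0 <- phase_function(spec, 0, rep(pi / 3, length(phi)), phi)
  expect_lt(max(f0) - min(f0), 1e-12)
  expect_error(phase_function(spec, 1.5, pi / 3, 0), "L must")
  expect_error(phase_function(spec, -0.1, pi / 3, 0), "L must")
  # Rayleigh limit shape: normalized (cos^2 + 1 - L sin^2 cos 2 phi)
  specr <- spec_for_alpha(0.01)
  th <- seq(0.05, pi - 0.05, length.out = 41)
  gr <- expand.grid(th = th, ph = phi)
  for (L in c(0, 1)) {
    Fnum <- phase_function(specr, L, gr$th, gr$ph)
    Fan <- (cos(gr$th)^2 + 1 - L * sin(gr$th)^2 * cos(2 * gr$ph)) *
      3 / (16 * pi)
    expect_lt(max(abs(Fnum - Fan)) / max(Fan), 0.01)
  }
})

test_that("amplitude tables export as plain text", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_amplitude_table(spec_for_alpha(1), seq(0, pi, length.out = 19), f)
  tab <- read.table(f, header = TRUE)
  expect_named(tab, c("theta", "re_S1", "im_S1", "re_S2", "im_S2"))
  expect_equal(nrow(tab), 19)
  amp <- mie_amplitudes(spec_for_alpha(1), tab$theta)
  expect_equal(tab$re_S2, Re(amp$S2), tolerance = 1e-12)
})
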