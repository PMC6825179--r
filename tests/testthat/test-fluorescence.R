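# Probabilistic fluorescence: spectra, conversion statistics, emission
# properties and interoperability with elastic transport.

test_that("fluorophore specification validates its parameters", {
  expect_error(fluorophore_spec(0, 0.1, 0.51), "l_f")
  expect_error(fluorophore_spec(5, 1.5, 0.51), "p_f")
  expect_error(fluorophore_spec(5, 0.1, numeric(0)), "nonempty|spectrum")
  expect_warning(fluorophore_spec(5, 0.1, c(0.51, 0.53), c(2, 1)),
                 "normalizing")
  # p_s = l_f * mu_s > 1 is a configuration error
  med <- medium_optics(0, 0.5, spec_for_alpha(1),
                       tables = tables_for_alpha(1))
  fl <- fluorophore_spec(5, 0.1, 0.51)
  rays <- launch_collimated(10, c(1, 0), 0.488)
  expect_error(
    propagate_fluorescent_medium(rays, med, fl, slab_geometry(10), seed = 1),
    "exceeds 1")
})

test_that("emission wavelengths are drawn from the configured spectrum", {
  fl1 <- fluorophore_spec(5, 0.1, 0.510)
  expect_true(all(sample_emission_wavelength(fl1, 100) == 0.510))
  set.seed(6)
  fl4 <- fluorophore_spec(5, 0.1, c(0.50, 0.51, 0.53, 0.55))
  w <- sample_emission_wavelength(fl4, 1e5)
  freq <- as.numeric(table(w)) / 1e5
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
  fl2 <- fluorophore_spec(5, 0.1, c(0.51, 0.55), c(0.7, 0.3))
  w2 <- sample_emission_wavelength(fl2, 1e5)
  expect_lt(abs(mean(w2 == 0.51) - 0.7), 3 * sqrt(0.21 / 1e5))
})

test_that("first-fluorescence depth matches the compound-exponential mean", {
  # without scattering, depth = sum of N ~ Geometric(p_f) segments of mean
  # l_f: mean l_f / p_f, variance l_f^2 (2 - p_f) / p_f^2
  l_f <- 5; p_f <- 0.05; n <- 3e4
  fl <- fluorophore_spec(l_f, p_f, 0.51, excitation_band = c(0.4, 0.5))
  rays <- local({
    set.seed(2)
    launch_collimated(n, c(1, 0), 0.488)
  })
  res <- propagate_fluorescent_medium(rays, medium_optics(0, 0), fl,
                                      slab_geometry(Inf), seed = 2,
                                      follow_emission = FALSE)
  expect_equal(nrow(res$fluor_events), n)
  mean_th <- l_f / p_f
  se <- sqrt(l_f^2 * (2 - p_f) / p_f^2 / n)
  expect_lt(abs(mean(res$fluor_events$z) - mean_th), 3 * se)
})

test_that("doubling the fluorescence mean free path doubles the mean depth", {
  n <- 2e4; p_f <- 0.05
  depth <- sapply(c(5, 10), function(l_f) {
    fl <- fluorophore_spec(l_f, p_f, 0.51, excitation_band = c(0.4, 0.5))
    rays <- local({
      set.seed(3)
      launch_collimated(n, c(1, 0), 0.488)
    })
    res <- propagate_fluorescent_medium(rays, medium_optics(0, 0), fl,
                                        slab_geometry(Inf), seed = 3,
                                        follow_emission = FALSE)
    mean(res$fluor_events$z)
  })
  se_ratio <- 2 * sqrt((2 - p_f) / p_f^2 / n) * 5 / (5 / p_f)
  expect_lt(abs(depth[2] / depth[1] - 2), 3 * sqrt(2) * se_ratio)
})

test_that("emitted rays are isotropic, fully linear, randomly oriented", {
  fl <- fluorophore_spec(5, 0.05, 0.51, excitation_band = c(0.4, 0.5))
  rays <- local({
    set.seed(4)
    launch_collimated(2e4, c(1, 0), 0.488)
  })
  res <- propagate_fluorescent_medium(rays, medium_optics(0, 0), fl,
                                      slab_geometry(Inf), seed = 4,
                                      follow_emission = FALSE)
  em <- res$exits[res$exits$status == "emitted", ]
  expect_equal(nrow(em), 2e4)
  expect_true(all(em$wavelength == 0.51))
  # directions uniform on the sphere: cos(polar) uniform, azimuth uniform
  expect_gt(suppressWarnings(ks.test(em$uz, "punif", -1, 1))$p.value, 0.01)
  expect_gt(suppressWarnings(
    ks.test(atan2(em$uy, em$ux), "punif", -pi, pi))$p.value, 0.01)
  expect_equal(em$L, rep(1, nrow(em)), tolerance = 1e-12)
  # orientation uniformity via the source-sampling path (same emitter)
  tab <- structure(list(voxels = data.frame(x = 0, y = 0, z = 0, weight = 1),
                        pitch = c(1, 1, 1), threshold = 0),
                   class = "excitation_table")
  src <- sample_fluorescence_sources(tab, 2e4, fl, seed = 5)
  ref <- matrix(c(1, 0, 0), src$n, 3, byrow = TRUE)
  b1 <- polmc:::unitize(ref - src$e_p * polmc:::vdot(ref, src$e_p))
  b2 <- polmc:::vcross(src$e_p, b1)
  ang <- atan2(polmc:::vdot(src$e_l, b2), polmc:::vdot(src$e_l, b1)) %% pi
  expect_gt(suppressWarnings(ks.test(ang, "punif", 0, pi))$p.value, 0.01)
})

test_that("with p_f = 0 the fluorescent kernel reduces to elastic transport", {
  tb <- tables_for_alpha(1)
  mu_s <- 0.1
  med <- medium_optics(0.01, mu_s, spec_for_alpha(1), tables = tb)
  # l_f segments thin the scattering process exactly: p_s / l_f = mu_s
  fl <- fluorophore_spec(2, 0, 0.51, excitation_band = c(0.4, 0.5))
  n <- 1e4
  rays1 <- local({
    set.seed(8)
    launch_collimated(n, c(1, 0), 0.488)
  })
  resf <- propagate_fluorescent_medium(rays1, med, fl, slab_geometry(30),
                                       seed = 8)
  rays2 <- local({
    set.seed(9)
    launch_collimated(n, c(1, 0), 0.488)
  })
  rese <- propagate_through_medium(rays2, med, slab_geometry(30), seed = 9)
  t1 <- resf$exits[resf$exits$status == "transmitted", ]
  t2 <- rese$exits[rese$exits$status == "transmitted", ]
  expect_gt(suppressWarnings(ks.test(t1$uz, t2$uz))$p.value, 0.01)
  # continuous part only: the ballistic atom (path exactly = thickness)
  # breaks the KS null, so compare scattered rays and the atom separately
  s1 <- t1$path_length[t1$events > 0]; s2 <- t2$path_length[t2$events > 0]
  expect_gt(suppressWarnings(ks.test(s1, s2))$p.value, 0.01)
  b1 <- mean(t1$events == 0); b2 <- mean(t2$events == 0)
  expect_lt(abs(b1 - b2), 3 * sqrt(2 * b2 * (1 - b2) / nrow(t2)))
  expect_lt(abs(nrow(t1) - nrow(t2)) / n, 3 * sqrt(2 * 0.25 / n))
})

test_that("fluorescence conversion conserves weight at unit quantum yield", {
  tb <- tables_for_alpha(1)
  med <- medium_optics(0.005, 0.05, spec_for_alpha(1), tables = tb)
  fl <- fluorophore_spec(4, 0.1, c(0.51, 0.53), c(0.6, 0.4),
                         excitation_band = c(0.4, 0.5))
  rays <- local({
    set.seed(12)
    launch_collimated(3000, c(1, 0), 0.488)
  })
  res <- propagate_fluorescent_medium(rays, med, fl, slab_geometry(25),
                                      seed = 12)
  l <- res$ledger
  expect_equal(unname(l["yield_loss"]), 0)
  closure <- l["launched"] - sum(l[c("transmitted", "reflected", "absorbed",
                                     "capped", "roulette_net", "yield_loss")])
  expect_lt(abs(unname(closure)), 1e-9)
  expect_gt(nrow(res$fluor_events), 0)
  # emitted generations appear among the exit records
  expect_gt(sum(res$exits$generation == 1), 0)
})

test_that("the shipped EGFP-like line spectrum loads as a fluorophore", {
  f <- system.file("extdata", "egfp_like_spectrum_synthetic.tsv",
                   package = "polmc")
  tab <- read.delim(f)
  fl <- fluorophore_spec(5, 0.05, tab$wavelength_um, tab$weight,
                         excitation_band = c(0.47, 0.50))
  expect_equal(sum(fl$emission_weights), 1)
  set.seed(1)
  w <- sample_emission_wavelength(fl, 2e4)
  expect_lt(abs(mean(w == 0.510) - 0.35), 3 * sqrt(0.35 * 0.65 / 2e4))
  # Stokes-shift guard: emission lines sit above the excitation band
  expect_true(all(fl$emission_wavelengths >= fl$excitation_band[1]))
})
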