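# Angular-spectrum field construction, diffraction propagation, fractal
# index volumes and excitation tables.

test_that("a single on-axis ray gives a constant field with its phase", {
  rays <- data.frame(x = 0, y = 0, ux = 0, uy = 0, uz = 1, weight = 4,
                     phase = 1.3)
  fg <- record_angular_spectrum(rays, 0.5, 32, 32, 0.2)
  expect_lt(max(Mod(fg$amplitude - 2 * exp(1.3i))), 1e-12)
  expect_equal(attr(fg, "n_rejected"), 0)
})

test_that("a path-length offset shifts the plane-wave phase by 2 pi d/lambda", {
  lam <- 0.5; delta <- 0.1234
  r1 <- data.frame(x = 0, y = 0, ux = 0, uy = 0, uz = 1, weight = 1,
                   phase = 0)
  r2 <- r1; r2$phase <- 2 * pi * delta / lam
  f1 <- record_angular_spectrum(r1, lam, 8, 8, 0.2)
  f2 <- record_angular_spectrum(r2, lam, 8, 8, 0.2)
  expect_lt(max(Mod(f2$amplitude - f1$amplitude * exp(2i * pi * delta / lam))),
            1e-12)
})

test_that("two symmetric beams interfere at the two-beam fringe period", {
  lam <- 0.5; th <- 0.05; n <- 256; pitch <- 0.2
  rays <- data.frame(x = 0, y = 0, ux = c(sin(th), -sin(th)), uy = 0,
                     uz = cos(th), weight = 1, phase = 0)
  fg <- record_angular_spectrum(rays, lam, n, 8, pitch)
  I <- Mod(fg$amplitude[, 1])^2
  sp <- Mod(stats::fft(I - mean(I)))[1:(n / 2)]
  cycles_meas <- which.max(sp) - 1
  cycles_exp <- round(n * pitch / (lam / (2 * sin(th))))
  expect_equal(cycles_meas, cycles_exp)
})

test_that("rays beyond the Nyquist bound are rejected with a count", {
  lam <- 0.5; pitch <- 0.4   # Nyquist angle: lambda/(2 pitch) = 0.625
  rays <- data.frame(x = 0, y = 0, ux = c(0, 0.9), uy = 0,
                     uz = c(1, sqrt(1 - 0.81)), weight = 1, phase = 0)
  fg <- record_angular_spectrum(rays, lam, 16, 16, pitch)
  expect_equal(attr(fg, "n_rejected"), 1)
})

test_that("free-space propagation is unitary and invertible", {
  n <- 128; pitch <- 0.25; lam <- 0.5
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * pitch
  U <- exp(-outer(ax^2, ax^2, "+") / 4) * exp(1i * outer(ax, ax * 0, "+"))
  f <- field_grid(U, pitch, lam)
  fwd <- propagate_field(f, 25)$fields[[1]]
  expect_lt(abs(field_power(fwd) / field_power(f) - 1), 1e-10)
  back <- propagate_field(fwd, -25)$fields[[1]]
  expect_lt(max(Mod(back$amplitude - U)) / max(Mod(U)), 1e-10)
})

test_that("Gaussian beam width follows w0 sqrt(1 + (z/zR)^2) within 1%", {
  lam <- 0.5; w0 <- 2; n <- 256; pitch <- 0.15
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * pitch
  U <- exp(-outer(ax^2, ax^2, "+") / w0^2)
  f <- field_grid(matrix(as.complex(U), n, n), pitch, lam)
  zR <- pi * w0^2 / lam
  zs <- seq(-2 * zR, 2 * zR, length.out = 9)
  st <- propagate_field(f, zs)
  w_meas <- vapply(st$fields, function(g) {
    I <- Mod(g$amplitude)^2
    Ix <- rowSums(I)
    m <- sum(Ix * ax) / sum(Ix)
    2 * sqrt(sum(Ix * (ax - m)^2) / sum(Ix))
  }, numeric(1))
  w_true <- w0 * sqrt(1 + (zs / zR)^2)
  expect_lt(max(abs(w_meas - w_true) / w_true), 0.01)
})

test_that("a converging ray fan focuses to the scalar Airy width", {
  lam <- 0.5; na <- 0.25; zf <- 60
  g <- expand.grid(ux = seq(-na, na, length.out = 21),
                   uy = seq(-na, na, length.out = 21))
  g <- g[g$ux^2 + g$uy^2 <= na^2, ]
  uz <- sqrt(1 - g$ux^2 - g$uy^2)
  k <- 2 * pi / lam
  rays <- data.frame(x = -g$ux / uz * zf, y = -g$uy / uz * zf,
                     ux = g$ux, uy = g$uy, uz = uz, weight = 1,
                     phase = -k * zf / uz)
  n <- 512; pitch <- 0.25
  fg <- record_angular_spectrum(rays, lam, n, n, pitch)
  I <- Mod(propagate_field(fg, zf)$fields[[1]]$amplitude)^2
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * pitch
  core <- abs(ax) < 8   # exclude aliasing replicas of the discrete ray set
  Icore <- I[core, core]
  pk <- which(Icore == max(Icore), arr.ind = TRUE)[1, ]
  prof <- Icore[, pk[2]]
  axc <- ax[core]
  half <- max(prof) / 2
  f <- approxfun(axc, prof - half)
  i0 <- pk[1]
  lo <- uniroot(f, c(axc[i0] - 2, axc[i0]))$root
  hi <- uniroot(f, c(axc[i0], axc[i0] + 2))$root
  expect_lt(abs((hi - lo) / (0.514 * lam / na) - 1), 0.05)
})

test_that("fractal index volumes honour rms, exponent and reproducibility", {
  v0 <- fractal_index_volume(16, 16, 16, 0.5, rms = 0, seed = 1)
  expect_true(all(v0$dn == 0))
  v <- fractal_index_volume(64, 64, 64, 0.5, rms = 5e-3, beta = 3.7,
                            outer_scale = 20, seed = 5)
  expect_lt(abs(mean(v$dn)), 1e-4)
  expect_lt(abs(sd(as.numeric(v$dn)) / 5e-3 - 1), 0.05)
  v2 <- fractal_index_volume(64, 64, 64, 0.5, rms = 5e-3, beta = 3.7,
                             outer_scale = 20, seed = 5)
  expect_identical(v$dn, v2$dn)
  expect_error(fractal_index_volume(8, 8, 8, 0.5, rms = 1e-3, beta = -1),
               "beta")
})

test_that("ensemble periodogram slope matches the requested exponent", {
  beta <- 3.7
  pw <- 0
  ks <- NULL
  for (i in 1:8) {
    v <- fractal_index_volume(48, 48, 48, 0.5, rms = 5e-3, beta = beta,
                              outer_scale = 20, seed = 100 + i)
    rs <- radial_spectrum(v)
    rs <- rs[stats::complete.cases(rs), ]
    if (is.null(ks)) { ks <- rs$k; pw <- rs$power } else pw <- pw + rs$power
  }
  df <- data.frame(k = ks, power = pw / 8)
  sel <- df$k > 1.5 & df$k < 6
  fit <- stats::lm(log10(power) ~ log10(k), data = df[sel, ])
  ci <- stats::confint(fit)["log10(k)", ]
  expect_gt(-beta, ci[1])
  expect_lt(-beta, ci[2])
})

test_that("split-step propagation through fluctuations perturbs the beam", {
  n <- 64; pitch <- 0.5; lam <- 0.5
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * pitch
  U <- exp(-outer(ax^2, ax^2, "+") / 16)
  f <- field_grid(matrix(as.complex(U), n, n), pitch, lam)
  vol <- fractal_index_volume(n, n, 20, pitch, rms = 2e-3, beta = 3.7,
                              outer_scale = 10, pitch_z = 2, seed = 3)
  zs <- seq(2, 40, by = 2)
  hom <- propagate_field(f, zs)
  het <- propagate_field(f, zs, medium = vol)
  d <- Mod(het$fields[[20]]$amplitude - hom$fields[[20]]$amplitude)
  expect_gt(max(d), 1e-4)       # fluctuations actually act on the field
  expect_lt(abs(field_power(het$fields[[20]]) / field_power(f) - 1), 1e-9)
})

test_that("excitation tables select illuminated voxels inside the mesh", {
  mesh <- polmc:::make_icosphere(6, 1)
  nx <- 16
  org <- c(-7.5, -7.5, -7.5)
  uniform <- array(1, c(nx, nx, nx))
  tab <- build_excitation_table(uniform, mesh, 0, origin = org, pitch = 1)
  ctr <- as.matrix(expand.grid(x = org[1] + 0:(nx - 1),
                               y = org[2] + 0:(nx - 1),
                               z = org[3] + 0:(nx - 1)))
  expect_equal(nrow(tab$voxels), sum(points_in_mesh(mesh, ctr)))
  expect_true(all(tab$voxels$weight == 1))
  # weights are intensities relative to the volume maximum
  set.seed(1)
  I <- array(runif(nx^3), c(nx, nx, nx))
  tab2 <- build_excitation_table(I, mesh, 0.2, origin = org, pitch = 1)
  expect_true(all(tab2$voxels$weight > 0.2 & tab2$voxels$weight <= 1))
  idx <- which(I / max(I) > 0.2, arr.ind = TRUE)
  expect_lte(nrow(tab2$voxels), nrow(idx))
  # threshold monotonicity
  tab3 <- build_excitation_table(I, mesh, 0.5, origin = org, pitch = 1)
  expect_lte(nrow(tab3$voxels), nrow(tab2$voxels))
  # mesh disjoint from the illuminated volume: empty table
  far <- polmc:::make_icosphere(2, 1, center = c(100, 100, 100))
  tab4 <- build_excitation_table(uniform, far, 0, origin = org, pitch = 1)
  expect_equal(nrow(tab4$voxels), 0)
  # open mesh rejected
  open_mesh <- tri_mesh(mesh$vertices, mesh$faces[-1, ])
  expect_error(build_excitation_table(uniform, open_mesh, 0), "watertight")
})

test_that("fluorescence sources follow the excitation-table weights", {
  fl <- fluorophore_spec(5, 0.05, c(0.51, 0.53), c(0.5, 0.5))
  tab <- structure(list(voxels = data.frame(x = c(0, 10), y = 0, z = 0,
                                            weight = c(0.75, 0.25)),
                        pitch = c(1, 1, 1), threshold = 0),
                   class = "excitation_table")
  src <- sample_fluorescence_sources(tab, 4e4, fl, seed = 4)
  frac <- mean(src$position[, 1] < 5)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 4e4))
  # jitter stays within the voxel
  expect_true(all(abs(src$position[, 2]) <= 0.5))
  # isotropy: equal-measure bins in cos(polar) x azimuth
  nb <- 8
  iu <- pmin(floor((src$e_p[, 3] + 1) / 2 * nb) + 1L, nb)
  ia <- pmin(floor((atan2(src$e_p[, 2], src$e_p[, 1]) + pi) /
                     (2 * pi) * nb) + 1L, nb)
  cnt <- tabulate(iu + nb * (ia - 1L), nb * nb)
  expect_gt(stats::chisq.test(cnt)$p.value, 0.01)
  # reproducible under the seed; degenerate single-voxel table
  src2 <- sample_fluorescence_sources(tab, 4e4, fl, seed = 4)
  expect_identical(src$position, src2$position)
  tab1 <- tab; tab1$voxels <- tab1$voxels[1, ]
  s1 <- sample_fluorescence_sources(tab1, 100, fl, seed = 1)
  expect_true(all(abs(s1$position[, 1]) <= 0.5))
  tab0 <- tab; tab0$voxels$weight <- 0
  expect_error(sample_fluorescence_sources(tab0, 10, fl), "zero total weight")
})
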