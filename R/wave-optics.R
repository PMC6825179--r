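# Scalar wave optics: angular-spectrum field construction from rays,
# band-limited diffraction propagation (split-step through refractive-index
# fluctuations), fractal index volumes and voxel excitation tables.

#' Complex scalar field on a uniform plane grid
#'
#' @param amplitude nx x ny complex matrix (rows index x, columns y).
#' @param pitch Pixel pitch (um).
#' @param wavelength Vacuum wavelength (um).
#' @param z Axial position of the plane (um).
#' @param n_background Refractive index of the propagation background.
#' @return An object of class `field_grid`.
#' @export
field_grid <- function(amplitude, pitch, wavelength, z = 0, n_background = 1) {
  stopifnot(is.matrix(amplitude), pitch > 0, wavelength > 0)
  structure(list(amplitude = amplitude, pitch = pitch,
                 wavelength = wavelength, z = z,
                 n_background = n_background),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d x %d px, pitch %g um, lambda %g um, power %.4g\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pitch, x$wavelength,
              field_power(x)))
  invisible(x)
}

#' Total power of a field grid
#'
#' @param field A [field_grid()].
#' @return `sum |U|^2 * pitch^2`.
#' @export
field_power <- function(field) sum(Mod(field$amplitude)^2) * field$pitch^2

grid_axes <- function(nx, ny, pitch) {
  list(x = (seq_len(nx) - 1 - (nx - 1) / 2) * pitch,
       y = (seq_len(ny) - 1 - (ny - 1) / 2) * pitch)
}

#' Record the angular spectrum of a traced ray set
#'
#' Assigns one plane wave to each ray crossing the plane `z = z0`: amplitude
#' `sqrt(weight)`, transverse wavevector from the ray direction, and absolute
#' phase equal to the optical phase accrued along the ray path, anchored at
#' the ray's crossing point. The coherent sum over rays gives the complex
#' field on the grid. Rays whose transverse spatial frequency exceeds the
#' grid's Nyquist bound are rejected and counted.
#'
#' @param rays Exit-record data frame (from [propagate_through_medium()]) or a
#'   data frame with columns `x`, `y`, `ux`, `uy`, `uz`, `weight`, `phase`;
#'   all rays must share one wavelength.
#' @param wavelength Vacuum wavelength (um).
#' @param nx,ny Grid size in pixels.
#' @param pitch Pixel pitch (um).
#' @param z Plane position (informational).
#' @param n_background Background refractive index.
#' @return A [field_grid()] with attribute `n_rejected`.
#' @export
record_angular_spectrum <- function(rays, wavelength, nx, ny, pitch, z = 0,
                                    n_background = 1) {
  k <- 2 * pi * n_background / wavelength
  kx <- k * rays$ux; ky <- k * rays$uy
  nyq <- pi / pitch
  ok <- abs(kx) <= nyq & abs(ky) <= nyq & rays$uz > 0
  n_rej <- sum(!ok)
  ax <- grid_axes(nx, ny, pitch)
  U <- matrix(0 + 0i, nx, ny)
  amp <- sqrt(rays$weight[ok])
  ph0 <- rays$phase[ok] - kx[ok] * rays$x[ok] - ky[ok] * rays$y[ok]
  for (r in seq_along(amp)) {
    px <- exp(1i * kx[ok][r] * ax$x)
    py <- exp(1i * ky[ok][r] * ax$y)
    U <- U + amp[r] * exp(1i * ph0[r]) * outer(px, py)
  }
  out <- field_grid(U, pitch, wavelength, z, n_background)
  attr(out, "n_rejected") <- n_rej
  out
}

# Band-limited angular-spectrum transfer step over distance dz. Evanescent
# components are zeroed; their power fraction is returned in an attribute.
fft_freqs <- function(n, pitch) {
  if (n == 1) return(0)
  f <- c(0:(floor(n / 2)), seq_len(ceiling(n / 2) - 1) - ceiling(n / 2)) /
    (n * pitch)
  2 * pi * f[seq_len(n)]
}

asm_step <- function(U, pitch, k, dz) {
  nx <- nrow(U); ny <- ncol(U)
  kx <- fft_freqs(nx, pitch); ky <- fft_freqs(ny, pitch)
  k2 <- outer(kx^2, ky^2, "+")
  kz2 <- k^2 - k2
  prop <- k2 <= k^2
  kz <- sqrt(pmax(kz2, 0))
  A <- stats::fft(U)
  lost <- sum(Mod(A[!prop])^2) / max(sum(Mod(A)^2), .Machine$double.xmin)
  A[!prop] <- 0
  A <- A * exp(1i * kz * dz)
  out <- stats::fft(A, inverse = TRUE) / (nx * ny)
  attr(out, "evanescent_fraction") <- lost
  out
}

#' Propagate a field through a volume by the angular-spectrum method
#'
#' Band-limited angular-spectrum stepping to each requested plane. In an
#' inhomogeneous medium ([fractal_index_volume()]), split-step propagation is
#' used: a homogeneous half/full-step in the background index followed by a
#' thin phase screen `exp(i k0 dn dz)` accumulated from the voxel slab between
#' consecutive planes. Evanescent spectral components are dropped and their
#' power fraction reported.
#'
#' @param field A [field_grid()].
#' @param z_planes Increasing (or decreasing) axial distances from the input
#'   plane at which the field is evaluated (um). Negative distances propagate
#'   backwards.
#' @param medium `NULL` for a uniform background, or an `index_volume` whose
#'   transverse grid matches the field grid.
#' @return A list of class `field_stack`: `fields` (list of [field_grid()]),
#'   `z` (the distances), `evanescent_fraction` (max over steps).
#' @export
propagate_field <- function(field, z_planes, medium = NULL) {
  k <- 2 * pi * field$n_background / field$wavelength
  k0 <- 2 * pi / field$wavelength
  U <- field$amplitude
  zs <- c(0, z_planes)
  fields <- vector("list", length(z_planes))
  ev <- 0
  for (i in seq_along(z_planes)) {
    dz <- zs[i + 1] - zs[i]
    if (!is.null(medium)) {
      # accumulate the phase screen of the voxel slab spanned by this step
      screen <- index_slab_screen(medium, zs[i], zs[i + 1])
      U <- asm_step(U, field$pitch, k, dz)
      ev <- max(ev, attr(U, "evanescent_fraction"))
      U <- U * exp(1i * k0 * screen)
    } else {
      U <- asm_step(U, field$pitch, k, dz)
      ev <- max(ev, attr(U, "evanescent_fraction"))
    }
    attr(U, "evanescent_fraction") <- NULL
    fields[[i]] <- field_grid(U, field$pitch, field$wavelength,
                              field$z + z_planes[i], field$n_background)
  }
  structure(list(fields = fields, z = z_planes, evanescent_fraction = ev),
            class = "field_stack")
}

#' Intensity volume from a field stack
#'
#' @param stack A [propagate_field()] result.
#' @return nx x ny x nz numeric array of `|U|^2`.
#' @export
intensity_volume <- function(stack) {
  nx <- nrow(stack$fields[[1]]$amplitude)
  ny <- ncol(stack$fields[[1]]$amplitude)
  arr <- array(0, c(nx, ny, length(stack$fields)))
  for (i in seq_along(stack$fields))
    arr[, , i] <- Mod(stack$fields[[i]]$amplitude)^2
  arr
}

# Integrated index fluctuation (dn * length, um) between axial positions
# z0 < z1, per transverse pixel, from the voxelized index volume.
index_slab_screen <- function(volume, z0, z1) {
  if (z1 < z0) { tmp <- z0; z0 <- z1; z1 <- tmp }
  nz <- dim(volume$dn)[3]
  edges <- volume$z0 + (0:nz) * volume$pitch_z
  scr <- matrix(0, dim(volume$dn)[1], dim(volume$dn)[2])
  for (iz in seq_len(nz)) {
    ov <- max(0, min(z1, edges[iz + 1]) - max(z0, edges[iz]))
    if (ov > 0) scr <- scr + volume$dn[, , iz] * ov
  }
  scr
}

#' Synthesize a fractal refractive-index volume
#'
#' Zero-mean Gaussian random field with isotropic power-law spectrum
#' \eqn{\Phi(k) \propto (k^2 + 1/L_{out}^2)^{-\beta/2}}, generated spectrally
#' (white complex Gaussian coefficients shaped by \eqn{\sqrt\Phi}, inverse
#' FFT). The spectral normalization is chosen analytically so the expected
#' variance equals `rms^2`; individual realizations fluctuate around it.
#' Such power-law index fluctuations are a standard weak-scattering model of
#' turbid biological media.
#'
#' @param nx,ny,nz Voxel counts.
#' @param pitch Transverse voxel pitch (um).
#' @param pitch_z Axial voxel pitch (um); defaults to `pitch`.
#' @param rms Root-mean-square index fluctuation (dimensionless, >= 0).
#' @param beta Spectral exponent (> 0); the 3D power spectrum decays as
#'   `k^-beta` beyond the outer scale.
#' @param outer_scale Outer scale L_out (um) flattening the spectrum at low k.
#' @param z0 Axial position of the first voxel slab's entry face (um).
#' @param seed Optional seed.
#' @return An object of class `index_volume` with the fluctuation array `dn`,
#'   grid metadata and the generation parameters.
#' @export
fractal_index_volume <- function(nx, ny, nz, pitch, rms, beta = 3.7,
                                 outer_scale = 10, pitch_z = pitch,
                                 z0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  if (rms < 0) stop("rms must be >= 0")
  if (beta <= 0 || outer_scale <= 0)
    stop("beta and outer_scale must be > 0")
  if (rms == 0) {
    dn <- array(0, c(nx, ny, nz))
  } else {
    kx <- fft_freqs(nx, pitch); ky <- fft_freqs(ny, pitch)
    kz <- fft_freqs(nz, pitch_z)
    k2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
    Phi <- (k2 + 1 / outer_scale^2)^(-beta / 2)
    Phi[1, 1, 1] <- 0                      # zero-mean constraint
    if (!all(is.finite(Phi))) stop("divergent spectrum on this grid")
    ntot <- nx * ny * nz
    W <- array(complex(real = stats::rnorm(ntot), imaginary = stats::rnorm(ntot)),
               c(nx, ny, nz))
    A <- W * sqrt(Phi)
    f <- Re(stats::fft(A, inverse = TRUE)) / ntot
    # E[var(f)] = sum(Phi) / ntot^2 * E|W|^2 = 2*sum(Phi)/ntot^2 per Re part:
    # Re keeps half the complex variance -> E[var] = sum(Phi)/ntot^2
    dn <- f * rms / sqrt(sum(Phi) / ntot^2)
  }
  structure(list(dn = dn, pitch = pitch, pitch_z = pitch_z, z0 = z0,
                 rms = rms, beta = beta, outer_scale = outer_scale),
            class = "index_volume")
}

#' @export
print.index_volume <- function(x, ...) {
  cat(sprintf("<index_volume> %s voxels, rms %g, beta %g, L_out %g um\n",
              paste(dim(x$dn), collapse = " x "), x$rms, x$beta,
              x$outer_scale))
  invisible(x)
}

#' Radially averaged 3D power spectrum of an index volume
#'
#' Diagnostic for the spectral exponent: returns the mean periodogram power in
#' logarithmic radial wavenumber bins.
#'
#' @param volume An `index_volume`, or an array of the same shape to average
#'   several realizations externally.
#' @param nbins Number of radial bins.
#' @return Data frame with `k` (bin centre, rad/um) and `power`.
#' @export
radial_spectrum <- function(volume, nbins = 24) {
  dn <- if (inherits(volume, "index_volume")) volume$dn else volume
  d <- dim(dn)
  p <- if (inherits(volume, "index_volume")) c(volume$pitch, volume$pitch, volume$pitch_z)
       else c(1, 1, 1)
  P <- Mod(stats::fft(dn))^2
  kx <- fft_freqs(d[1], p[1]); ky <- fft_freqs(d[2], p[2]); kz <- fft_freqs(d[3], p[3])
  kr <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  sel <- kr > 0
  lk <- log10(kr[sel]); pw <- P[sel]
  br <- seq(min(lk), max(lk), length.out = nbins + 1)
  bin <- cut(lk, br, include.lowest = TRUE)
  data.frame(k = 10^(tapply(lk, bin, mean)),
             power = as.numeric(tapply(pw, bin, mean)))
}

# ---------------------------------------------------------------------------
# Excitation tables (fluorescence from diffracted beams)

#' Build a voxel excitation table
#'
#' Tabulates the voxels of an illumination intensity volume that lie inside a
#' watertight sample mesh and whose relative intensity exceeds a threshold.
#' Weights are the voxel intensities relative to the volume maximum.
#'
#' @param intensity nx x ny x nz intensity array.
#' @param mesh A watertight `tri_mesh` in the same frame as the volume.
#' @param threshold Relative intensity threshold in \eqn{[0, 1)}; voxels with
#'   `intensity / max > threshold` are kept.
#' @param origin Coordinates of the centre of voxel (1,1,1).
#' @param pitch Voxel pitch (um), scalar or length 3.
#' @return An object of class `excitation_table`: data frame `voxels`
#'   (`x`, `y`, `z`, `weight`), plus `threshold`, `pitch` and `origin`.
#' @export
build_excitation_table <- function(intensity, mesh, threshold = 0,
                                   origin = c(0, 0, 0), pitch = 1) {
  if (!mesh_is_watertight(mesh))
    stop("excitation table requires a watertight sample mesh")
  pitch <- rep_len(pitch, 3)
  d <- dim(intensity)
  mx <- max(intensity)
  if (mx <= 0) stop("intensity volume is empty")
  rel <- intensity / mx
  keep <- which(rel > threshold, arr.ind = TRUE)
  if (nrow(keep)) {
    pts <- cbind(origin[1] + (keep[, 1] - 1) * pitch[1],
                 origin[2] + (keep[, 2] - 1) * pitch[2],
                 origin[3] + (keep[, 3] - 1) * pitch[3])
    inside <- points_in_mesh(mesh, pts)
    keep <- keep[inside, , drop = FALSE]
    pts <- pts[inside, , drop = FALSE]
  } else {
    pts <- matrix(0, 0, 3)
  }
  vox <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    weight = rel[keep])
  structure(list(voxels = vox, threshold = threshold, pitch = pitch,
                 origin = origin),
            class = "excitation_table")
}

#' @export
print.excitation_table <- function(x, ...) {
  cat(sprintf("<excitation_table> %d voxels above threshold %g\n",
              nrow(x$voxels), x$threshold))
  invisible(x)
}

#' Export an excitation table as plain text
#'
#' @param table An `excitation_table`.
#' @param file Output path (whitespace-separated `x y z weight`).
#' @return The path, invisibly.
#' @export
write_excitation_table <- function(table, file) {
  utils::write.table(table$voxels, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Generate fluorescence source rays from an excitation table
#'
#' Ray origins are drawn categorically proportional to the voxel weights with
#' uniform jitter inside each voxel; directions are isotropic; wavelengths are
#' drawn from the fluorophore emission spectrum; polarization is fully linear
#' with uniformly random orientation and random phase.
#'
#' @param table An [build_excitation_table()] result with nonzero total
#'   weight.
#' @param n Number of rays.
#' @param fluor A [fluorophore_spec()] supplying the emission spectrum.
#' @param seed Optional seed.
#' @return A [ray_bundle()] with unit weights and generation tag 1.
#' @export
sample_fluorescence_sources <- function(table, n, fluor, seed = NULL) {
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  w <- table$voxels$weight
  if (!length(w) || sum(w) <= 0) stop("excitation table has zero total weight")
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  jitter <- cbind(stats::runif(n, -0.5, 0.5) * table$pitch[1],
                  stats::runif(n, -0.5, 0.5) * table$pitch[2],
                  stats::runif(n, -0.5, 0.5) * table$pitch[3])
  pos <- cbind(table$voxels$x[idx], table$voxels$y[idx],
               table$voxels$z[idx]) + jitter
  e_p <- isotropic_directions(n)
  e_l <- random_perpendicular(e_p)
  rb <- ray_bundle(pos, e_p, e_l,
                   exp(1i * stats::runif(n, 0, 2 * pi)), complex(n),
                   sample_emission_wavelength(fluor, n))
  rb$generation <- rep(1L, n)
  rb
}
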