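# Mie theory for homogeneous spheres: amplitude functions S1/S2, efficiencies,
# anisotropy, and the polarization-dependent single-scattering phase function.

#' Scatterer specification
#'
#' Bundles the parameters of a single monodisperse spherical scatterer species
#' and derives the dimensionless size parameter \eqn{\alpha = \pi d n / \lambda}.
#'
#' @param particle_diameter Particle diameter \eqn{d} in micrometres (>= 0).
#' @param medium_index Real refractive index \eqn{n} of the embedding medium
#'   (>= 1).
#' @param particle_index Refractive index of the particle, complex allowed.
#'   Convention: a positive imaginary part means an absorbing particle.
#' @param wavelength Vacuum wavelength \eqn{\lambda} in micrometres (> 0).
#'
#' @return An object of class `scatterer_spec` with fields
#'   `particle_diameter`, `medium_index`, `particle_index`, `wavelength`,
#'   `size_parameter` (\eqn{\alpha}) and `relative_index`
#'   (particle index / medium index).
#' @export
#' @examples
#' sp <- scatterer_spec(0.5, 1.33, 1.59, 0.488)
#' sp$size_parameter
scatterer_spec <- function(particle_diameter, medium_index, particle_index,
                           wavelength) {
  if (!is.numeric(particle_diameter) || particle_diameter < 0)
    stop("particle_diameter must be >= 0")
  if (!is.numeric(medium_index) || medium_index < 1)
    stop("medium_index must be real and >= 1")
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be > 0")
  structure(
    list(
      particle_diameter = particle_diameter,
      medium_index = medium_index,
      particle_index = as.complex(particle_index),
      wavelength = wavelength,
      size_parameter = size_parameter(particle_diameter, medium_index, wavelength),
      relative_index = as.complex(particle_index) / medium_index
    ),
    class = "scatterer_spec"
  )
}

#' @export
print.scatterer_spec <- function(x, ...) {
  cat(sprintf(
    "<scatterer_spec> d = %g um, n_med = %g, n_p = %s, lambda = %g um, alpha = %.4f\n",
    x$particle_diameter, x$medium_index, format(x$particle_index),
    x$wavelength, x$size_parameter))
  invisible(x)
}

#' Mie size parameter
#'
#' \eqn{\alpha = \pi d n / \lambda} with the particle diameter \eqn{d} and the
#' vacuum wavelength \eqn{\lambda}; the factor \eqn{n} converts to the
#' wavelength inside the medium.
#'
#' @param d Particle diameter (micrometres, >= 0).
#' @param n Real refractive index of the medium (>= 1).
#' @param wavelength Vacuum wavelength (micrometres, > 0).
#' @return The dimensionless size parameter.
#' @export
size_parameter <- function(d, n, wavelength) {
  if (any(d < 0)) stop("particle diameter must be >= 0")
  if (any(n < 1)) stop("medium index must be >= 1")
  if (any(wavelength <= 0)) stop("wavelength must be > 0")
  pi * d * n / wavelength
}

# Wiscombe series truncation with the package's safety margin.
mie_nmax <- function(x) {
  if (x > 2e4) stop("size parameter ", x, " beyond the supported Mie range")
  ceiling(x + 4 * x^(1/3) + 2) + 15L
}

# Logarithmic derivative D_n(mx) by downward recurrence (stable direction).
mie_log_derivative <- function(mx, nmax) {
  nstart <- max(nmax + 16L, ceiling(Mod(mx)) + 16L)
  D <- complex(nstart + 1L)  # D[n + 1] = D_n
  for (n in nstart:1) {
    rn <- (n + 1) / mx
    D[n] <- rn - 1 / (D[n + 1L] + rn)
  }
  D[seq_len(nmax)]
}

# Mie expansion coefficients a_n, b_n for size parameter x and relative index m.
mie_coefficients <- function(x, m, nmax = mie_nmax(x)) {
  if (!is.finite(x) || x <= 0) stop("size parameter must be finite and > 0")
  D <- mie_log_derivative(m * x, nmax)
  # Riccati-Bessel psi_n(x), chi_n(x) by upward recurrence (real argument).
  psi0 <- sin(x); psi1 <- sin(x) / x - cos(x)
  chi0 <- cos(x); chi1 <- cos(x) / x + sin(x)
  a <- complex(nmax); b <- complex(nmax)
  psi_nm1 <- psi0; psi_n <- psi1
  chi_nm1 <- chi0; chi_n <- chi1
  for (n in seq_len(nmax)) {
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    a[n] <- (da * psi_n - psi_nm1) / (da * xi_n - xi_nm1)
    b[n] <- (db * psi_n - psi_nm1) / (db * xi_n - xi_nm1)
    if (n < nmax) {
      psi_np1 <- (2 * n + 1) / x * psi_n - psi_nm1
      chi_np1 <- (2 * n + 1) / x * chi_n - chi_nm1
      psi_nm1 <- psi_n; psi_n <- psi_np1
      chi_nm1 <- chi_n; chi_n <- chi_np1
    }
  }
  if (!all(is.finite(Re(a)) & is.finite(Im(a)) & is.finite(Re(b)) & is.finite(Im(b))))
    stop("Mie series did not converge for size parameter ", x)
  list(a = a, b = b, nmax = nmax)
}

#' Mie amplitude functions S1 and S2
#'
#' Complex scattering amplitudes of a homogeneous sphere on a grid of
#' scattering angles, from the Mie series with Wiscombe-criterion truncation
#' (plus a fixed safety margin). For spheres the off-diagonal amplitudes S3 and
#' S4 vanish identically and are reported as zero.
#'
#' @param spec A [scatterer_spec()].
#' @param theta Scattering angles in radians, in \eqn{[0, \pi]}.
#' @return A data frame with columns `theta`, `S1`, `S2` (complex), `S3`, `S4`
#'   (complex zero).
#' @export
mie_amplitudes <- function(spec, theta) {
  stopifnot(inherits(spec, "scatterer_spec"))
  if (any(theta < -1e-12 | theta > pi + 1e-12))
    stop("scattering angles must lie in [0, pi]")
  theta <- pmin(pmax(theta, 0), pi)
  x <- spec$size_parameter
  if (x <= 0) stop("size parameter must be > 0 for Mie amplitudes")
  co <- mie_coefficients(x, spec$relative_index)
  ang <- mie_angular_sums(co$a, co$b, cos(theta))
  data.frame(theta = theta, S1 = ang$S1, S2 = ang$S2,
             S3 = complex(length(theta)), S4 = complex(length(theta)))
}

# S1, S2 sums over the angular functions pi_n, tau_n; vectorized over mu.
mie_angular_sums <- function(a, b, mu) {
  nmax <- length(a)
  S1 <- complex(length(mu)); S2 <- complex(length(mu))
  pi_nm1 <- numeric(length(mu))      # pi_0 = 0
  pi_n <- rep(1, length(mu))         # pi_1 = 1
  for (n in seq_len(nmax)) {
    tau_n <- n * mu * pi_n - (n + 1) * pi_nm1
    fn <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fn * (a[n] * pi_n + b[n] * tau_n)
    S2 <- S2 + fn * (a[n] * tau_n + b[n] * pi_n)
    if (n < nmax) {
      pi_np1 <- ((2 * n + 1) * mu * pi_n - (n + 1) * pi_nm1) / n
      pi_nm1 <- pi_n
      pi_n <- pi_np1
    }
  }
  list(S1 = S1, S2 = S2)
}

#' Mie efficiencies and anisotropy
#'
#' Extinction, scattering and absorption efficiencies and the scattering
#' anisotropy \eqn{g = \langle\cos\theta\rangle} of a homogeneous sphere.
#' Medium-level extinction coefficients follow from the efficiencies via the
#' particle concentration and geometric cross-section
#' (\eqn{\mu_s = \rho\, Q_{sca}\, \pi d^2/4}).
#'
#' @param spec A [scatterer_spec()].
#' @return A list of class `mie_efficiencies` with `Q_ext`, `Q_sca`, `Q_abs`
#'   and `g`. `Q_abs` is zero (to rounding) for a real particle index.
#' @export
mie_efficiencies <- function(spec) {
  stopifnot(inherits(spec, "scatterer_spec"))
  x <- spec$size_parameter
  if (x <= 0) stop("size parameter must be > 0")
  co <- mie_coefficients(x, spec$relative_index)
  a <- co$a; b <- co$b
  n <- seq_along(a)
  Q_sca <- 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  Q_ext <- 2 / x^2 * sum((2 * n + 1) * Re(a + b))
  np <- n[-length(n)]
  gq <- 4 / x^2 * (
    sum(np * (np + 2) / (np + 1) *
          Re(a[np] * Conj(a[np + 1]) + b[np] * Conj(b[np + 1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b))))
  structure(list(Q_ext = Q_ext, Q_sca = Q_sca,
                 Q_abs = Q_ext - Q_sca, g = gq / Q_sca),
            class = "mie_efficiencies")
}

#' @export
print.mie_efficiencies <- function(x, ...) {
  cat(sprintf("<mie_efficiencies> Q_ext = %.6g  Q_sca = %.6g  Q_abs = %.3g  g = %.4f\n",
              x$Q_ext, x$Q_sca, x$Q_abs, x$g))
  invisible(x)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), used for all
# cos(theta) quadratures; absorbs the sin(theta) Jacobian.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

# Quadrature of (|S1|^2 + |S2|^2) over cos(theta): the azimuth-independent part
# of the unnormalized phase function. Returns the normalization constant
# A = 1 / (2*pi*integral).
phase_norm_constant <- function(spec, n_nodes = 512) {
  gl <- gauss_legendre(n_nodes)
  amp <- mie_amplitudes(spec, acos(gl$nodes))
  f1 <- Mod(amp$S1)^2 + Mod(amp$S2)^2
  1 / (2 * pi * sum(gl$weights * f1))
}

#' Polarization-dependent single-scattering phase function
#'
#' Probability density (per steradian) of the scattering direction for
#' incident light with degree of linear polarization \eqn{L}:
#' \deqn{F(\theta,\phi) = A\,[\,|S_2|^2 + |S_1|^2 +
#'   L\,(|S_2|^2 - |S_1|^2)\cos 2\phi\,]}
#' where the azimuth \eqn{\phi} is measured from the major axis of the incident
#' polarization ellipse and \eqn{A} is fixed numerically so the density
#' integrates to one over the full sphere (Gauss-Legendre quadrature in
#' \eqn{\cos\theta}).
#'
#' @param spec A [scatterer_spec()].
#' @param L Degree of linear polarization of the incident ray, in \eqn{[0, 1]}.
#' @param theta,phi Scattering and azimuthal angles (radians); recycled to a
#'   common length.
#' @param n_nodes Quadrature order for the normalization constant.
#' @return Numeric vector of densities (per steradian), nonnegative.
#' @export
phase_function <- function(spec, L, theta, phi, n_nodes = 512) {
  if (length(L) != 1 || L < 0 || L > 1)
    stop("L must be a single value in [0, 1]")
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  A <- phase_norm_constant(spec, n_nodes)
  amp <- mie_amplitudes(spec, theta)
  s1 <- Mod(amp$S1)^2; s2 <- Mod(amp$S2)^2
  A * (s2 + s1 + L * (s2 - s1) * cos(2 * phi))
}

#' Export tabulated amplitudes as plain text
#'
#' Writes a whitespace-separated table of `theta`, `Re(S1)`, `Im(S1)`,
#' `Re(S2)`, `Im(S2)` for external cross-checking.
#'
#' @param spec A [scatterer_spec()].
#' @param theta Angle grid (radians).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_amplitude_table <- function(spec, theta, file) {
  amp <- mie_amplitudes(spec, theta)
  tab <- data.frame(theta = amp$theta,
                    re_S1 = Re(amp$S1), im_S1 = Im(amp$S1),
                    re_S2 = Re(amp$S2), im_S2 = Im(amp$S2))
  utils::write.table(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
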