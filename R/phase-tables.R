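# Dynamic look-up-table sampling of (theta, phi) scattering doublets from the
# polarization-dependent bivariate Mie phase function.
#
# The density F(theta, phi) is split into a polarization-independent part
# F1 = |S2|^2 + |S1|^2 and a polarization coupling F2 = (|S2|^2 - |S1|^2)
# cos(2 phi), so that F ~ F1 + L * F2. Both parts are tabulated once per
# medium/wavelength on a product grid uniform in cos(theta) and phi, together
# with their cumulative trapezoidal integrals G1, G2 over the lexicographic
# doublet index. At a scattering event the cumulative table for the current
# degree of linear polarization L is G1 + L*G2, searched in O(log mn).

#' Build phase-function sampling tables
#'
#' Precomputes the tabulated phase-function components and their cumulative
#' integrals for the dynamic look-up-table sampler. The scattering-angle grid
#' is uniform in \eqn{\cos\theta} (descending from \eqn{\pi} to 0),
#' \eqn{\theta_i = \arccos(2(i-1)/(m-1) - 1)}, and the azimuth grid is uniform,
#' \eqn{\phi_j = 2\pi (j-1)/n}. Doublets are ordered lexicographically,
#' \eqn{k = i + m(j-1)}. Because the \eqn{\theta} grid is uniform in
#' \eqn{\cos\theta}, the \eqn{\sin\theta} solid-angle Jacobian is absorbed by
#' the grid spacing and no explicit Jacobian enters the cumulative sums.
#' Cumulative trapezoids are taken within each azimuth column (the index step
#' that would span the seam between columns, where \eqn{\theta} jumps from 0
#' back to \eqn{\pi}, carries no probability mass).
#'
#' @param spec A [scatterer_spec()].
#' @param m Number of \eqn{\theta} samples (>= 3). Default 1000.
#' @param n Number of \eqn{\phi} samples (>= 4). Default 360.
#' @return An object of class `phase_tables` with the grids, `F1`, `F2`,
#'   cumulative `G1`, `G2`, cached complex `S1`, `S2` on the \eqn{\theta} grid,
#'   and the numeric normalization constant `A` of the phase function.
#' @export
build_phase_tables <- function(spec, m = 1000L, n = 360L) {
  stopifnot(inherits(spec, "scatterer_spec"))
  m <- as.integer(m); n <- as.integer(n)
  if (m < 3L) stop("theta grid needs m >= 3 samples")
  if (n < 4L) stop("phi grid needs n >= 4 samples")
  theta <- acos(2 * (seq_len(m) - 1) / (m - 1) - 1)   # pi .. 0
  phi <- 2 * pi * (seq_len(n) - 1) / n
  amp <- mie_amplitudes(spec, theta)
  f1_theta <- Mod(amp$S2)^2 + Mod(amp$S1)^2
  f2_theta <- Mod(amp$S2)^2 - Mod(amp$S1)^2
  cos2phi <- cos(2 * phi)
  # Lexicographic tables: index k = i + m*(j-1); columns are phi blocks.
  F1 <- rep(f1_theta, times = n)
  F2 <- rep(f2_theta, times = n) * rep(cos2phi, each = m)
  G1 <- cumtrap_columns(F1, m, n)
  G2 <- cumtrap_columns(F2, m, n)
  structure(
    list(m = m, n = n, theta = theta, phi = phi,
         F1 = F1, F2 = F2, G1 = G1, G2 = G2,
         S1 = amp$S1, S2 = amp$S2,
         A = phase_norm_constant(spec),
         spec = spec),
    class = "phase_tables")
}

# Cumulative trapezoid along the lexicographic index, restarted at each
# azimuth-column seam (where theta wraps from 0 to pi).
cumtrap_columns <- function(f, m, n) {
  inc <- (f[-1] + f[-length(f)]) / 2
  seam <- seq_len(n - 1) * m      # steps k -> k+1 crossing column boundaries
  inc[seam] <- 0
  c(0, cumsum(inc))
}

#' @export
print.phase_tables <- function(x, ...) {
  cat(sprintf("<phase_tables> m = %d theta x n = %d phi, alpha = %.4f\n",
              x$m, x$n, x$spec$size_parameter))
  invisible(x)
}

#' Draw scattering doublets from the tabulated phase function
#'
#' Dynamic look-up-table sampling: for each draw the boundary number
#' \eqn{r_{max} = G_1[mn] + L\,G_2[mn]} is formed, \eqn{r \sim U[0, r_{max}]}
#' drawn, the cell \eqn{k} with
#' \eqn{G_1[k] + L G_2[k] \le r < G_1[k+1] + L G_2[k+1]} located by binary
#' search, and \eqn{(\theta, \phi)} interpolated uniformly within the cell:
#' \eqn{\theta = \theta_i + r_\theta(\theta_{i+1} - \theta_i)},
#' \eqn{\phi = \phi_j + r_\phi(\phi_{j+1} - \phi_j)}.
#'
#' `L` may be a scalar (all draws share one table) or a vector of per-draw
#' degrees of linear polarization (each draw searches its own dynamic table;
#' implemented as a vectorized bisection).
#'
#' @param tables A [build_phase_tables()] object.
#' @param L Degree(s) of linear polarization in \eqn{[0, 1]}; length 1 or
#'   `n_draws`.
#' @param n_draws Number of doublets to draw.
#' @return A list with numeric vectors `theta`, `phi` and the integer cell
#'   index `k`.
#' @export
sample_scattering_angles <- function(tables, L, n_draws = 1L) {
  stopifnot(inherits(tables, "phase_tables"))
  if (any(L < 0 | L > 1)) stop("L must lie in [0, 1]")
  n_draws <- as.integer(n_draws)
  L <- rep_len(L, n_draws)
  m <- tables$m; n <- tables$n
  mn <- m * n
  if (length(unique(L)) == 1L) {
    G <- tables$G1 + L[1] * tables$G2
    r <- stats::runif(n_draws, 0, G[mn])
    k <- findInterval(r, G, rightmost.closed = TRUE, all.inside = TRUE)
  } else {
    rmax <- tables$G1[mn] + L * tables$G2[mn]
    r <- stats::runif(n_draws) * rmax
    k <- lut_bisect(tables$G1, tables$G2, L, r, mn)
  }
  # Zero-mass cells (seams) cannot be hit: findInterval/bisection land on the
  # lower edge of the first cell whose upper cumulative exceeds r, and seam
  # cells have equal lower and upper cumulative except for ties at the exact
  # boundary. Remap any seam index to the first cell of the next column.
  i <- ((k - 1L) %% m) + 1L
  j <- ((k - 1L) %/% m) + 1L
  at_seam <- i == m & j < n
  if (any(at_seam)) {
    i[at_seam] <- 1L
    j[at_seam] <- j[at_seam] + 1L
    k[at_seam] <- i[at_seam] + m * (j[at_seam] - 1L)
  }
  r_theta <- stats::runif(n_draws)
  r_phi <- stats::runif(n_draws)
  i_next <- pmin(i + 1L, m)
  theta <- tables$theta[i] + r_theta * (tables$theta[i_next] - tables$theta[i])
  phi <- tables$phi[j] + r_phi * (2 * pi / n)
  list(theta = theta, phi = phi, k = k)
}

# Vectorized binary search over the per-draw cumulative G1 + L*G2.
lut_bisect <- function(G1, G2, L, r, mn) {
  lo <- rep(1L, length(r))       # invariant: G[lo] <= r
  hi <- rep(mn, length(r))       # invariant: G[hi] >= r (upper cell edge)
  while (any(hi - lo > 1L)) {
    mid <- (lo + hi) %/% 2L
    gm <- G1[mid] + L * G2[mid]
    below <- gm <= r
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  lo
}

#' Interpolate cached amplitudes at sampled angles
#'
#' Linear interpolation of the precomputed complex S1, S2 tables at arbitrary
#' scattering angles, avoiding a fresh Mie evaluation per event. Exact
#' per-event Mie evaluation is available via `exact = TRUE`.
#'
#' @param tables A [build_phase_tables()] object.
#' @param theta Scattering angles (radians).
#' @param exact If `TRUE`, evaluate the Mie series at `theta` instead of
#'   interpolating the table.
#' @return A list with complex vectors `S1`, `S2`.
#' @export
amplitudes_at <- function(tables, theta, exact = FALSE) {
  if (exact) {
    amp <- mie_amplitudes(tables$spec, theta)
    return(list(S1 = amp$S1, S2 = amp$S2))
  }
  # theta grid descends from pi to 0, so cos(theta) ascends with the index;
  # interpolate linearly on the cos(theta) axis.
  mu_grid <- 2 * (seq_len(tables$m) - 1) / (tables$m - 1) - 1
  mu <- cos(theta)
  interp <- function(z) {
    re <- stats::approx(mu_grid, Re(z), xout = mu, rule = 2)$y
    im <- stats::approx(mu_grid, Im(z), xout = mu, rule = 2)$y
    complex(real = re, imaginary = im)
  }
  list(S1 = interp(tables$S1), S2 = interp(tables$S2))
}

#' Save / load phase tables
#'
#' Tables are stored in an RDS container whose filename is keyed by the
#' scatterer (size parameter, relative index) and grid so they can be reused
#' across runs.
#'
#' @param tables A `phase_tables` object.
#' @param dir Directory for the container.
#' @return `save_phase_tables` returns the file path;
#'   `load_phase_tables` returns the `phase_tables` object or `NULL` when no
#'   matching container exists.
#' @export
save_phase_tables <- function(tables, dir = ".") {
  key <- sprintf("phasetab_a%.6g_m%s_%dx%d.rds",
                 tables$spec$size_parameter,
                 gsub("[^0-9a-zA-Z.+-]", "", format(tables$spec$relative_index)),
                 tables$m, tables$n)
  path <- file.path(dir, key)
  saveRDS(tables, path)
  path
}

#' @rdname save_phase_tables
#' @param spec A [scatterer_spec()].
#' @param m,n Grid sizes of the sought table.
#' @export
load_phase_tables <- function(spec, m = 1000L, n = 360L, dir = ".") {
  key <- sprintf("phasetab_a%.6g_m%s_%dx%d.rds",
                 spec$size_parameter,
                 gsub("[^0-9a-zA-Z.+-]", "", format(as.complex(spec$particle_index) / spec$medium_index)),
                 as.integer(m), as.integer(n))
  path <- file.path(dir, key)
  if (!file.exists(path)) return(NULL)
  readRDS(path)
}

#' Henyey-Greenstein angle sampling (test baseline)
#'
#' Draws scattering angles from the Henyey-Greenstein phase function with
#' anisotropy `g` and uniform azimuth. Provided only as a scalar baseline for
#' comparison: it carries no polarization dependence and is not used by the
#' polarized transport kernel.
#'
#' @param g Anisotropy in (-1, 1).
#' @param n Number of draws.
#' @return A list with `theta` and `phi`.
#' @export
sample_hg <- function(g, n = 1L) {
  u <- stats::runif(n)
  mu <- if (abs(g) < 1e-8) 2 * u - 1 else
    (1 + g^2 - ((1 - g^2) / (1 - g + 2 * g * u))^2) / (2 * g)
  list(theta = acos(pmin(1, pmax(-1, mu))), phi = stats::runif(n, 0, 2 * pi))
}
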