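# Polarized photon-packet bundles: positions, orthonormal propagation frames,
# complex field pairs, and Stokes-vector accounting.
#
# Frame convention: each ray carries an orthonormal right-handed triple
# (e_p, e_r, e_l) with e_p x e_r = e_l (propagation, perpendicular, parallel).
# The complex field is E = E_l e_l + E_r e_r with |E_l|^2 + |E_r|^2 equal to
# the ray weight, so intensity bookkeeping lives in the fields themselves.

vnorm <- function(v) sqrt(rowSums(v * v))

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vdot <- function(a, b) rowSums(a * b)

unitize <- function(v) v / vnorm(v)

#' Construct a bundle of polarized rays
#'
#' Low-level constructor. Positions and direction frames are n x 3 matrices;
#' fields are complex vectors whose squared moduli sum to the ray weight.
#'
#' @param position n x 3 matrix of positions (micrometres).
#' @param e_p n x 3 matrix of unit propagation vectors.
#' @param e_l n x 3 matrix of parallel (in-polarization-plane) unit vectors,
#'   orthogonal to `e_p`. The perpendicular vector is derived as
#'   `e_r = e_l x e_p`.
#' @param E_l,E_r Complex field components in the (e_l, e_r) basis.
#' @param wavelength Vacuum wavelength(s), micrometres.
#' @return An object of class `ray_bundle`.
#' @export
ray_bundle <- function(position, e_p, e_l, E_l, E_r, wavelength) {
  n <- nrow(position)
  e_p <- unitize(e_p)
  e_l <- unitize(e_l - e_p * vdot(e_l, e_p))
  e_r <- vcross(e_l, e_p)
  structure(list(
    position = position,
    e_p = e_p, e_r = e_r, e_l = e_l,
    E_l = as.complex(E_l), E_r = as.complex(E_r),
    wavelength = rep_len(wavelength, n),
    path_length = numeric(n),
    phase = numeric(n),
    events = integer(n),
    generation = integer(n),
    n = n), class = "ray_bundle")
}

#' @export
print.ray_bundle <- function(x, ...) {
  cat(sprintf("<ray_bundle> %d rays, total weight %.4g, %s events (median)\n",
              x$n, sum(ray_weight(x)), stats::median(x$events)))
  invisible(x)
}

#' Ray weights (intensities)
#'
#' @param rays A [ray_bundle()].
#' @return Numeric vector `|E_l|^2 + |E_r|^2` per ray.
#' @export
ray_weight <- function(rays) Mod(rays$E_l)^2 + Mod(rays$E_r)^2

#' Launch a collimated polarized beam
#'
#' Rays start on the plane `z = origin[3]` travelling along +z (or a supplied
#' direction), with a shared Jones polarization state expressed in the lab
#' (x, y) basis and optional uniform-disc beam cross-section.
#'
#' @param n Number of rays.
#' @param jones Length-2 complex Jones vector (Ex, Ey); normalized internally.
#'   Examples: `c(1, 0)` horizontal, `c(1, 1i)/sqrt(2)` right circular.
#' @param wavelength Vacuum wavelength (micrometres).
#' @param origin Length-3 beam centre.
#' @param radius Beam radius; rays are spread uniformly over a disc of this
#'   radius in the launch plane (0 = pencil beam).
#' @param direction Length-3 propagation direction (default +z).
#' @return A [ray_bundle()] with unit weights.
#' @export
launch_collimated <- function(n, jones = c(1, 0), wavelength = 0.5,
                              origin = c(0, 0, 0), radius = 0,
                              direction = c(0, 0, 1)) {
  jones <- as.complex(jones)
  jones <- jones / sqrt(sum(Mod(jones)^2))
  if (radius > 0) {
    r <- radius * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    pos <- cbind(origin[1] + r * cos(a), origin[2] + r * sin(a), origin[3])
  } else {
    pos <- matrix(rep(origin, each = n), n, 3)
  }
  d <- direction / sqrt(sum(direction^2))
  e_p <- matrix(rep(d, each = n), n, 3)
  # lab-frame basis: e_l along x (projected), fallback y for near-x directions
  hint <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  h <- matrix(rep(hint, each = n), n, 3)
  e_l <- h - e_p * vdot(h, e_p)
  # Jones (Ex, Ey) decomposed onto the constructed (e_l, e_r)
  rb <- ray_bundle(pos, e_p, e_l, complex(n), complex(n), wavelength)
  ex <- cbind(rep(1, n), 0, 0); ey <- cbind(rep(0, n), 1, 0)
  rb$E_l <- jones[1] * complex(real = vdot(rb$e_l, ex)) +
            jones[2] * complex(real = vdot(rb$e_l, ey))
  rb$E_r <- jones[1] * complex(real = vdot(rb$e_r, ex)) +
            jones[2] * complex(real = vdot(rb$e_r, ey))
  w <- Mod(rb$E_l)^2 + Mod(rb$E_r)^2
  rb$E_l <- rb$E_l / sqrt(w); rb$E_r <- rb$E_r / sqrt(w)
  rb
}

#' Stokes parameters from a complex field pair
#'
#' \eqn{I = E_\ell E_\ell^* + E_r E_r^*}, \eqn{Q = E_\ell E_\ell^* - E_r E_r^*},
#' \eqn{U = E_\ell E_r^* + E_r E_\ell^*}, \eqn{V = -2\,\mathrm{Im}(E_\ell E_r^*)},
#' and the degree of linear polarization \eqn{L = \sqrt{Q^2 + U^2}/I}.
#'
#' @param E_l,E_r Complex field components (vectors of equal length).
#' @return A data frame with columns `I`, `Q`, `U`, `V`, `L`.
#' @export
stokes_from_field <- function(E_l, E_r) {
  I <- Mod(E_l)^2 + Mod(E_r)^2
  if (any(I == 0)) stop("zero field: polarization undefined")
  cr <- E_l * Conj(E_r)
  data.frame(I = I,
             Q = Mod(E_l)^2 - Mod(E_r)^2,
             U = 2 * Re(cr),
             V = -2 * Im(cr),
             L = sqrt((Mod(E_l)^2 - Mod(E_r)^2)^2 + (2 * Re(cr))^2) / I)
}

#' Stokes parameters of a ray bundle
#'
#' @param rays A [ray_bundle()].
#' @return Data frame as in [stokes_from_field()], rows aligned with rays.
#' @export
ray_stokes <- function(rays) stokes_from_field(rays$E_l, rays$E_r)

# Maximum deviation of the (e_p, e_r, e_l) triples from right-handed
# orthonormality.
frame_error <- function(rays) {
  with(rays, max(abs(vnorm(e_p) - 1), abs(vnorm(e_r) - 1), abs(vnorm(e_l) - 1),
                 abs(vdot(e_p, e_r)), abs(vdot(e_p, e_l)), abs(vdot(e_r, e_l)),
                 abs(vcross(e_p, e_r) - e_l)))
}

# Gram-Schmidt re-orthonormalization of the frames (e_p kept, e_l projected,
# e_r rebuilt). Called after every scattering event.
reorthonormalize <- function(rays) {
  rays$e_p <- unitize(rays$e_p)
  rays$e_l <- unitize(rays$e_l - rays$e_p * vdot(rays$e_l, rays$e_p))
  rays$e_r <- vcross(rays$e_l, rays$e_p)
  rays
}

# Rotate the polarization frame of each ray about its own e_p by beta
# (from e_l towards e_r), updating fields so the physical field is unchanged.
rotate_frame <- function(rays, beta) {
  cb <- cos(beta); sb <- sin(beta)
  e_l_new <- rays$e_l * cb + rays$e_r * sb
  e_r_new <- rays$e_r * cb - rays$e_l * sb
  E_l_new <- rays$E_l * cb + rays$E_r * sb
  E_r_new <- rays$E_r * cb - rays$E_l * sb
  rays$e_l <- e_l_new; rays$e_r <- e_r_new
  rays$E_l <- E_l_new; rays$E_r <- E_r_new
  rays
}

# Angle of the polarization-ellipse major axis from e_l, psi = atan2(U, Q)/2.
# For L below the degeneracy floor the reference is immaterial (circular or
# unpolarized) and 0 is returned.
ellipse_axis_angle <- function(rays, floor = 1e-9) {
  st <- ray_stokes(rays)
  psi <- 0.5 * atan2(st$U, st$Q)
  psi[st$L < floor] <- 0
  psi
}

# Subset a ray bundle.
bundle_subset <- function(rays, idx) {
  structure(list(
    position = rays$position[idx, , drop = FALSE],
    e_p = rays$e_p[idx, , drop = FALSE],
    e_r = rays$e_r[idx, , drop = FALSE],
    e_l = rays$e_l[idx, , drop = FALSE],
    E_l = rays$E_l[idx], E_r = rays$E_r[idx],
    wavelength = rays$wavelength[idx],
    path_length = rays$path_length[idx],
    phase = rays$phase[idx],
    events = rays$events[idx],
    generation = rays$generation[idx],
    n = if (is.logical(idx)) sum(idx) else length(idx)),
    class = "ray_bundle")
}

# Write fields of a sub-bundle back into the parent at idx.
bundle_assign <- function(rays, idx, sub) {
  rays$position[idx, ] <- sub$position
  rays$e_p[idx, ] <- sub$e_p
  rays$e_r[idx, ] <- sub$e_r
  rays$e_l[idx, ] <- sub$e_l
  rays$E_l[idx] <- sub$E_l
  rays$E_r[idx] <- sub$E_r
  rays$wavelength[idx] <- sub$wavelength
  rays$path_length[idx] <- sub$path_length
  rays$phase[idx] <- sub$phase
  rays$events[idx] <- sub$events
  rays$generation[idx] <- sub$generation
  rays
}
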