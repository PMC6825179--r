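# Monte-Carlo propagation of polarized photon packets through scattering and
# absorbing media with slab / mesh / embedded-absorber geometries.

#' Optical properties of a turbid medium
#'
#' @param mu_a Absorption coefficient (1/um, >= 0). Applied as continuous
#'   weight decay `exp(-mu_a * s)` along each path segment.
#' @param mu_s Scattering coefficient (1/um, >= 0); the scattering mean free
#'   path is `1/mu_s`.
#' @param spec A [scatterer_spec()] describing the scatterers (required when
#'   `mu_s > 0`).
#' @param tables Optional precomputed [build_phase_tables()]; built on demand
#'   (with default grid) if missing and needed.
#' @param exact_amplitudes If `TRUE`, evaluate the Mie series at each sampled
#'   scattering angle instead of interpolating the cached table.
#' @return An object of class `medium_optics`.
#' @export
medium_optics <- function(mu_a, mu_s, spec = NULL, tables = NULL,
                          exact_amplitudes = FALSE) {
  if (mu_a < 0 || mu_s < 0) stop("mu_a and mu_s must be >= 0")
  if (mu_s > 0 && is.null(spec) && is.null(tables))
    stop("a scattering medium needs a scatterer_spec or phase tables")
  if (is.null(spec) && !is.null(tables)) spec <- tables$spec
  structure(list(mu_a = mu_a, mu_s = mu_s, spec = spec, tables = tables,
                 exact_amplitudes = exact_amplitudes),
            class = "medium_optics")
}

ensure_tables <- function(medium, m = 1000L, n = 360L) {
  if (medium$mu_s > 0 && is.null(medium$tables))
    medium$tables <- build_phase_tables(medium$spec, m, n)
  medium
}

#' Sample an exponential free path
#'
#' Path lengths to the next interaction are exponential with mean `1/mu`;
#' `mu = 0` returns `Inf` (ballistic propagation, no event).
#'
#' @param mu Interaction rate (1/um, >= 0).
#' @param n Number of draws.
#' @return Numeric vector of path lengths.
#' @export
sample_free_path <- function(mu, n = 1L) {
  if (mu < 0) stop("rate mu must be >= 0")
  if (mu == 0) return(rep(Inf, n))
  stats::rexp(n, rate = mu)
}

# ---------------------------------------------------------------------------
# Geometry primitives

#' Axis-aligned slab geometry
#'
#' The medium occupies `0 <= z <= thickness` and is infinite in x and y.
#' Optional embedded absorbers (non-scattering, purely absorbing inclusions
#' such as blood-vessel rods) attenuate rays along their chords.
#'
#' @param thickness Slab thickness in micrometres (may be `Inf` for a
#'   semi-infinite medium).
#' @param absorbers Optional list of absorbers from [cylinder_absorber()].
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness, absorbers = list()) {
  if (thickness <= 0) stop("slab thickness must be > 0")
  structure(list(thickness = thickness, absorbers = absorbers),
            class = c("slab_geometry", "geometry"))
}

#' Cylindrical absorbing inclusion
#'
#' An infinite circular cylinder (e.g. a vessel rod) with its own absorption
#' coefficient, embedded in a slab.
#'
#' @param point A point on the cylinder axis (length 3).
#' @param axis Axis direction (length 3; normalized internally).
#' @param radius Cylinder radius (um).
#' @param mu_a Additional absorption coefficient inside the cylinder (1/um).
#' @return A list describing the absorber.
#' @export
cylinder_absorber <- function(point, axis, radius, mu_a) {
  if (radius <= 0 || mu_a < 0) stop("radius must be > 0 and mu_a >= 0")
  list(point = as.numeric(point), axis = axis / sqrt(sum(axis^2)),
       radius = radius, mu_a = mu_a)
}

#' Closed-mesh geometry
#'
#' The medium occupies the interior of a watertight triangle mesh (see
#' [read_stl()] / [generate_fixture()]).
#'
#' @param mesh A `tri_mesh` object; must pass [mesh_is_watertight()].
#' @return An object of class `mesh_geometry`.
#' @export
mesh_geometry <- function(mesh) {
  if (!mesh_is_watertight(mesh))
    stop("mesh geometry requires a watertight mesh")
  structure(list(mesh = mesh), class = c("mesh_geometry", "geometry"))
}

# Distance along e_p to the boundary of the region, Inf if never reached.
boundary_distance <- function(geometry, pos, dir) {
  UseMethod("boundary_distance")
}

#' @export
boundary_distance.slab_geometry <- function(geometry, pos, dir) {
  dz <- dir[, 3]
  t_b <- rep(Inf, nrow(pos))
  up <- dz > 0
  dn <- dz < 0
  t_b[up] <- (geometry$thickness - pos[up, 3]) / dz[up]
  t_b[dn] <- -pos[dn, 3] / dz[dn]
  pmax(t_b, 0)
}

#' @export
boundary_distance.mesh_geometry <- function(geometry, pos, dir) {
  mesh_exit_distance(geometry$mesh, pos, dir)
}

# Chord length of segments [pos, pos + step*dir] inside a cylinder.
cylinder_chord <- function(absorber, pos, dir, step) {
  a <- absorber$axis
  w0 <- sweep(pos, 2, absorber$point)
  perp <- function(v) v - outer(as.numeric(v %*% a), a)
  dp <- perp(dir); wp <- perp(w0)
  A <- rowSums(dp * dp)
  B <- 2 * rowSums(wp * dp)
  C <- rowSums(wp * wp) - absorber$radius^2
  disc <- B^2 - 4 * A * C
  chord <- numeric(nrow(pos))
  ok <- disc > 0 & A > 1e-30
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-B[ok] - sq) / (2 * A[ok])
    t2 <- (-B[ok] + sq) / (2 * A[ok])
    chord[ok] <- pmax(0, pmin(t2, step[ok]) - pmax(t1, 0))
  }
  # rays parallel to the axis inside the cylinder
  par <- A <= 1e-30 & C < 0
  chord[par] <- step[par]
  chord
}

# ---------------------------------------------------------------------------
# Scattering event

#' Scatter all rays of a bundle once
#'
#' Performs one polarized Mie scattering event per ray: draws a
#' \eqn{(\theta, \phi)} doublet from the dynamic look-up table using each
#' ray's own degree of linear polarization, rotates the polarization frame
#' about \eqn{\hat e_p} so the new parallel direction lies in the scattering
#' plane (azimuth measured from the polarization-ellipse major axis), rotates
#' the propagation direction by \eqn{\theta} in that plane, and updates the
#' fields by \eqn{E_\ell^s = N S_2 E_\ell}, \eqn{E_r^s = N S_1 E_r} with
#' \eqn{N} preserving the ray intensity.
#'
#' @param rays A [ray_bundle()].
#' @param medium A [medium_optics()] with `mu_s > 0`.
#' @return The scattered bundle (event counters incremented, frames
#'   re-orthonormalized).
#' @export
scatter_bundle <- function(rays, medium) {
  medium <- ensure_tables(medium)
  st <- ray_stokes(rays)
  draw <- sample_scattering_angles(medium$tables, pmin(st$L, 1), rays$n)
  psi <- ellipse_axis_angle(rays)
  rays <- rotate_frame(rays, psi + draw$phi)
  ct <- cos(draw$theta); stn <- sin(draw$theta)
  e_p_new <- rays$e_p * ct + rays$e_l * stn
  e_l_new <- rays$e_l * ct - rays$e_p * stn
  rays$e_p <- e_p_new; rays$e_l <- e_l_new
  amp <- amplitudes_at(medium$tables, draw$theta,
                       exact = isTRUE(medium$exact_amplitudes))
  w <- Mod(rays$E_l)^2 + Mod(rays$E_r)^2
  El <- amp$S2 * rays$E_l
  Er <- amp$S1 * rays$E_r
  N <- sqrt(w / (Mod(El)^2 + Mod(Er)^2))
  rays$E_l <- N * El
  rays$E_r <- N * Er
  rays$events <- rays$events + 1L
  reorthonormalize(rays)
}

# ---------------------------------------------------------------------------
# Transport driver

empty_exit_frame <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             ux = numeric(0), uy = numeric(0), uz = numeric(0),
             I = numeric(0), Q = numeric(0), U = numeric(0), V = numeric(0),
             L = numeric(0), weight = numeric(0),
             events = integer(0), path_length = numeric(0),
             phase = numeric(0), wavelength = numeric(0),
             generation = integer(0),
             Ex = complex(0), Ey = complex(0),
             status = character(0))
}

exit_rows <- function(rays, status) {
  st <- ray_stokes(rays)
  # lab-projected transverse field (paraxial detection basis)
  Ex <- rays$E_l * rays$e_l[, 1] + rays$E_r * rays$e_r[, 1]
  Ey <- rays$E_l * rays$e_l[, 2] + rays$E_r * rays$e_r[, 2]
  data.frame(x = rays$position[, 1], y = rays$position[, 2],
             z = rays$position[, 3],
             ux = rays$e_p[, 1], uy = rays$e_p[, 2], uz = rays$e_p[, 3],
             I = st$I, Q = st$Q, U = st$U, V = st$V, L = st$L,
             weight = st$I, events = rays$events,
             path_length = rays$path_length, phase = rays$phase,
             wavelength = rays$wavelength, generation = rays$generation,
             Ex = Ex, Ey = Ey,
             status = rep(status, rays$n))
}

#' Propagate a polarized ray bundle through a turbid medium
#'
#' Alternates exponential free-path draws and polarized scattering events
#' until each ray exits the geometry, is terminated by Russian roulette, or
#' reaches the event cap. Absorption is continuous weight decay
#' `exp(-mu_a * s)` per segment; an unbiased Russian-roulette stage (survival
#' probability `roulette_survival`) triggers when a ray's weight falls below
#' `weight_floor`. An energy ledger accounts for every unit of launched
#' weight.
#'
#' @param rays A [ray_bundle()] starting inside (or on the entry face of) the
#'   geometry.
#' @param medium A [medium_optics()].
#' @param geometry A [slab_geometry()] or [mesh_geometry()].
#' @param seed Optional integer seed (Mersenne-Twister) for reproducibility.
#' @param max_events Event cap per ray; capped weight is reported separately.
#' @param weight_floor Weight below which Russian roulette is played.
#' @param roulette_survival Survival probability of the roulette stage.
#' @return A list of class `transport_result`: `exits` (one row per
#'   terminated ray: position, direction, Stokes, fields, status one of
#'   `"transmitted"`, `"reflected"`, `"exited"`, `"roulette"`, `"capped"`) and
#'   `ledger` (launched, transmitted, reflected, absorbed, capped,
#'   roulette_net; sums to launched).
#' @export
propagate_through_medium <- function(rays, medium, geometry, seed = NULL,
                                     max_events = 10000L,
                                     weight_floor = 1e-4,
                                     roulette_survival = 0.1) {
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  medium <- ensure_tables(medium)
  n_med <- if (!is.null(medium$spec)) medium$spec$medium_index else 1
  ledger <- c(launched = sum(ray_weight(rays)), transmitted = 0, reflected = 0,
              absorbed = 0, capped = 0, roulette_net = 0)
  out <- list()
  while (rays$n > 0L) {
    w_before <- ray_weight(rays)
    s <- sample_free_path(medium$mu_s, rays$n)
    t_b <- boundary_distance(geometry, rays$position, rays$e_p)
    step <- pmin(s, t_b)
    # continuous absorption (medium + embedded absorbers)
    tau <- medium$mu_a * step
    if (inherits(geometry, "slab_geometry") && length(geometry$absorbers)) {
      for (ab in geometry$absorbers)
        tau <- tau + ab$mu_a * cylinder_chord(ab, rays$position, rays$e_p, step)
    }
    fac <- exp(-tau)
    rays$E_l <- rays$E_l * sqrt(fac)
    rays$E_r <- rays$E_r * sqrt(fac)
    ledger["absorbed"] <- ledger["absorbed"] + sum(w_before * (1 - fac))
    finite_step <- ifelse(is.finite(step), step, 0)
    rays$position <- rays$position + rays$e_p * finite_step
    rays$path_length <- rays$path_length + finite_step
    rays$phase <- rays$phase + 2 * pi * n_med * finite_step / rays$wavelength
    exiting <- t_b <= s & is.finite(t_b)
    # rays that can neither scatter nor reach a boundary (vacuum, direction
    # parallel to an infinite face) are terminated via the cap ledger
    stuck <- is.infinite(s) & is.infinite(t_b)
    if (any(stuck)) {
      sub <- bundle_subset(rays, stuck)
      out[[length(out) + 1L]] <- exit_rows(sub, "capped")
      ledger["capped"] <- ledger["capped"] + sum(ray_weight(sub))
      exiting <- exiting[!stuck]
      rays <- bundle_subset(rays, !stuck)
      if (rays$n == 0L) break
    }
    if (any(exiting)) {
      ex <- bundle_subset(rays, exiting)
      if (inherits(geometry, "slab_geometry")) {
        up <- ex$e_p[, 3] > 0
        if (any(up)) {
          sub <- bundle_subset(ex, up)
          out[[length(out) + 1L]] <- exit_rows(sub, "transmitted")
          ledger["transmitted"] <- ledger["transmitted"] + sum(ray_weight(sub))
        }
        if (any(!up)) {
          sub <- bundle_subset(ex, !up)
          out[[length(out) + 1L]] <- exit_rows(sub, "reflected")
          ledger["reflected"] <- ledger["reflected"] + sum(ray_weight(sub))
        }
      } else {
        out[[length(out) + 1L]] <- exit_rows(ex, "exited")
        ledger["transmitted"] <- ledger["transmitted"] + sum(ray_weight(ex))
      }
    }
    rays <- bundle_subset(rays, !exiting)
    if (rays$n == 0L) break
    rays <- scatter_bundle(rays, medium)
    # event cap
    capped <- rays$events >= max_events
    if (any(capped)) {
      sub <- bundle_subset(rays, capped)
      out[[length(out) + 1L]] <- exit_rows(sub, "capped")
      ledger["capped"] <- ledger["capped"] + sum(ray_weight(sub))
      rays <- bundle_subset(rays, !capped)
    }
    if (rays$n == 0L) break
    # Russian roulette below the weight floor
    w <- ray_weight(rays)
    low <- w < weight_floor
    if (any(low)) {
      u <- stats::runif(rays$n)
      kill <- low & u >= roulette_survival
      boost <- low & !kill
      if (any(kill)) {
        sub <- bundle_subset(rays, kill)
        out[[length(out) + 1L]] <- exit_rows(sub, "roulette")
        ledger["roulette_net"] <- ledger["roulette_net"] + sum(ray_weight(sub))
        rays <- bundle_subset(rays, !kill)
        boost <- boost[!kill]
      }
      if (any(boost)) {
        gain <- ray_weight(bundle_subset(rays, boost)) *
          (1 / roulette_survival - 1)
        rays$E_l[boost] <- rays$E_l[boost] / sqrt(roulette_survival)
        rays$E_r[boost] <- rays$E_r[boost] / sqrt(roulette_survival)
        ledger["roulette_net"] <- ledger["roulette_net"] - sum(gain)
      }
    }
  }
  exits <- if (length(out)) do.call(rbind, out) else empty_exit_frame()
  structure(list(exits = exits, ledger = ledger),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  l <- x$ledger
  cat(sprintf(paste0(
    "<transport_result> %d exit records\n",
    "  launched %.4g = transmitted %.4g + reflected %.4g + absorbed %.4g",
    " + capped %.4g + roulette %.4g\n"),
    nrow(x$exits), l["launched"], l["transmitted"], l["reflected"],
    l["absorbed"], l["capped"], l["roulette_net"]))
  invisible(x)
}

#' Energy-ledger closure error
#'
#' @param result A [propagate_through_medium()] result.
#' @return `launched - (transmitted + reflected + absorbed + capped +
#'   roulette_net)`; zero up to accumulation rounding.
#' @export
ledger_closure <- function(result) {
  l <- result$ledger
  unname(l["launched"] - sum(l[c("transmitted", "reflected", "absorbed",
                                 "capped", "roulette_net")]))
}

#' Median depolarization versus scattering order
#'
#' Launches a linearly polarized ensemble in an unbounded non-absorbing
#' medium and records the median degree of linear polarization after each
#' successive scattering event. Multiple Mie scattering converts linear to
#' elliptical polarization through the S2/S1 phase lag, so the median L decays
#' with scattering order.
#'
#' @param medium A [medium_optics()] with `mu_s > 0`.
#' @param n_rays Ensemble size.
#' @param n_orders Number of scattering orders to follow.
#' @param jones Launch polarization (lab Jones vector).
#' @param seed Optional seed.
#' @return Data frame with columns `order` (0..n_orders), `median_L` (median
#'   over rays of the per-ray degree of linear polarization, which stays near
#'   1 for nearly-real amplitude ratios and decays through the S2/S1 phase
#'   lag) and `ensemble_L` (degree of linear polarization of the summed
#'   lab-projected Stokes vector, the quantity a fixed analyzer measures;
#'   this is the classic rapid multiple-scattering depolarization).
#' @export
depolarization_by_order <- function(medium, n_rays = 10000L, n_orders = 10L,
                                    jones = c(1, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  medium <- ensure_tables(medium)
  rays <- launch_collimated(n_rays, jones = jones,
                            wavelength = medium$spec$wavelength)
  ens_L <- function(rays) {
    Ex <- rays$E_l * rays$e_l[, 1] + rays$E_r * rays$e_r[, 1]
    Ey <- rays$E_l * rays$e_l[, 2] + rays$E_r * rays$e_r[, 2]
    I <- sum(Mod(Ex)^2 + Mod(Ey)^2)
    Q <- sum(Mod(Ex)^2 - Mod(Ey)^2)
    U <- sum(2 * Re(Ex * Conj(Ey)))
    sqrt(Q^2 + U^2) / I
  }
  med <- numeric(n_orders + 1L)
  ens <- numeric(n_orders + 1L)
  med[1] <- stats::median(ray_stokes(rays)$L)
  ens[1] <- ens_L(rays)
  for (k in seq_len(n_orders)) {
    rays <- scatter_bundle(rays, medium)
    med[k + 1L] <- stats::median(ray_stokes(rays)$L)
    ens[k + 1L] <- ens_L(rays)
  }
  data.frame(order = 0:n_orders, median_L = med, ensemble_L = ens)
}
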