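# Probabilistic fluorescence in scattering media: per-segment wavelength
# shift, isotropic re-emission, polarization and phase randomization.

#' Fluorophore specification
#'
#' The probabilistic fluorescence model draws propagation segments from an
#' exponential distribution with mean `l_f` (the fluorescence mean free path);
#' at the end of each segment the ray fluoresces with probability `p_f`,
#' elastically scatters with probability `p_s = l_f / l_s` (the ratio of the
#' fluorescence to the scattering mean free path), or continues unchanged.
#' Together `l_f` and `p_f` set the excitation penetration depth
#' (`l_f / p_f` in the absence of scattering).
#'
#' @param l_f Fluorescence mean free path (um, > 0).
#' @param p_f Fluorescence probability per segment, in \eqn{[0, 1]}.
#' @param emission_wavelengths Emission wavelengths (um) sampling the spectrum.
#' @param emission_weights Relative line weights; normalized to sum to 1 (with
#'   a warning if they do not already).
#' @param excitation_band Length-2 wavelength interval (um) within which a ray
#'   can excite fluorescence.
#' @param quantum_yield Emitted weight per unit excitation weight converted
#'   (default 1).
#' @return An object of class `fluorophore_spec`.
#' @export
fluorophore_spec <- function(l_f, p_f, emission_wavelengths,
                             emission_weights = NULL,
                             excitation_band = c(0, Inf),
                             quantum_yield = 1) {
  if (l_f <= 0) stop("fluorescence mean free path l_f must be > 0")
  if (p_f < 0 || p_f > 1) stop("p_f must lie in [0, 1]")
  if (!length(emission_wavelengths)) stop("emission spectrum must be nonempty")
  if (is.null(emission_weights))
    emission_weights <- rep(1 / length(emission_wavelengths),
                            length(emission_wavelengths))
  if (abs(sum(emission_weights) - 1) > 1e-12) {
    warning("emission weights do not sum to 1; normalizing")
    emission_weights <- emission_weights / sum(emission_weights)
  }
  if (quantum_yield < 0 || quantum_yield > 1)
    stop("quantum_yield must lie in [0, 1]")
  structure(list(l_f = l_f, p_f = p_f,
                 emission_wavelengths = emission_wavelengths,
                 emission_weights = emission_weights,
                 excitation_band = excitation_band,
                 quantum_yield = quantum_yield),
            class = "fluorophore_spec")
}

#' Draw emission wavelengths from a fluorophore spectrum
#'
#' Categorical draw proportional to the configured line weights.
#'
#' @param fluor A [fluorophore_spec()].
#' @param n Number of draws.
#' @return Numeric vector of wavelengths (um).
#' @export
sample_emission_wavelength <- function(fluor, n = 1L) {
  stopifnot(inherits(fluor, "fluorophore_spec"))
  fluor$emission_wavelengths[
    sample.int(length(fluor$emission_wavelengths), n, replace = TRUE,
               prob = fluor$emission_weights)]
}

# n isotropic unit vectors.
isotropic_directions <- function(n) {
  u <- stats::runif(n, -1, 1)
  a <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(s * cos(a), s * sin(a), u)
}

# A unit vector perpendicular to each row of ep, rotated by a uniform random
# angle about ep (uniform linear-polarization orientation).
random_perpendicular <- function(e_p) {
  n <- nrow(e_p)
  h <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  swap <- abs(e_p[, 1]) > 0.9
  h[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), sum(swap), 3)
  b1 <- unitize(h - e_p * vdot(h, e_p))
  b2 <- vcross(e_p, b1)
  a <- stats::runif(n, 0, pi)
  b1 * cos(a) + b2 * sin(a)
}

# Convert rays in place to fluorescence-emission rays: wavelength shift,
# isotropic direction, fully linear polarization with random orientation,
# randomized phase, reset event counter, generation tag 1.
emit_fluorescence <- function(rays, fluor) {
  n <- rays$n
  w <- ray_weight(rays) * fluor$quantum_yield
  rays$wavelength <- sample_emission_wavelength(fluor, n)
  rays$e_p <- isotropic_directions(n)
  rays$e_l <- random_perpendicular(rays$e_p)
  rays$e_r <- vcross(rays$e_l, rays$e_p)
  rays$E_l <- sqrt(w) * exp(1i * stats::runif(n, 0, 2 * pi))
  rays$E_r <- complex(n)
  rays$phase <- stats::runif(n, 0, 2 * pi)
  rays$events <- integer(n)
  rays$generation <- rays$generation + 1L
  rays
}

#' Propagate rays through a fluorescent scattering medium
#'
#' Implements the probabilistic fluorescence model: excitation-band rays
#' advance in exponential segments of mean `l_f`; at each segment end they
#' fluoresce with probability `p_f`, elastically scatter with probability
#' `p_s = l_f * mu_s`, or continue straight. On fluorescence the ray's
#' wavelength shifts (categorical draw from the emission spectrum), its
#' direction is redrawn isotropically, its polarization is set fully linear
#' with uniformly random orientation and its phase is randomized; emitted rays
#' then propagate with ordinary elastic transport. The configuration is
#' rejected when `p_f + p_s > 1` (the fluorescence segments are then too long
#' to resolve the scattering rate; choose a smaller `l_f`).
#'
#' @param rays A [ray_bundle()] entering the medium.
#' @param medium A [medium_optics()].
#' @param fluor A [fluorophore_spec()].
#' @param geometry A [slab_geometry()] or [mesh_geometry()].
#' @param seed Optional seed.
#' @param follow_emission If `FALSE`, emitted rays are returned immediately as
#'   exit records with status `"emitted"` instead of being propagated further.
#' @param max_events,weight_floor,roulette_survival As in
#'   [propagate_through_medium()].
#' @return A list of class `fluor_result`: `exits` (as in transport, plus
#'   status `"emitted"` when `follow_emission = FALSE`), `fluor_events` (one
#'   row per fluorescence conversion: position and path length at the event),
#'   and `ledger`.
#' @export
propagate_fluorescent_medium <- function(rays, medium, fluor, geometry,
                                         seed = NULL, follow_emission = TRUE,
                                         max_events = 10000L,
                                         weight_floor = 1e-4,
                                         roulette_survival = 0.1) {
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  stopifnot(inherits(fluor, "fluorophore_spec"))
  medium <- ensure_tables(medium)
  p_s <- fluor$l_f * medium$mu_s
  if (p_s > 1)
    stop("p_s = l_f * mu_s = ", signif(p_s, 4),
         " exceeds 1: fluorescence segments cannot resolve the scattering ",
         "rate; reduce l_f")
  if (fluor$p_f + p_s > 1)
    stop("p_f + p_s exceeds 1; reduce l_f or p_f")
  n_med <- if (!is.null(medium$spec)) medium$spec$medium_index else 1
  ledger <- c(launched = sum(ray_weight(rays)), transmitted = 0, reflected = 0,
              absorbed = 0, capped = 0, roulette_net = 0, yield_loss = 0)
  out <- list()
  fl_events <- list()
  while (rays$n > 0L) {
    w_before <- ray_weight(rays)
    excitable <- rays$generation == 0L &
      rays$wavelength >= fluor$excitation_band[1] &
      rays$wavelength <= fluor$excitation_band[2]
    # excitation rays step on the fluorescence mean free path; others on the
    # elastic scattering mean free path
    s <- ifelse(excitable, stats::rexp(rays$n, rate = 1 / fluor$l_f),
                sample_free_path(medium$mu_s, rays$n))
    t_b <- boundary_distance(geometry, rays$position, rays$e_p)
    step <- pmin(s, t_b)
    fac <- exp(-medium$mu_a * step)
    rays$E_l <- rays$E_l * sqrt(fac)
    rays$E_r <- rays$E_r * sqrt(fac)
    ledger["absorbed"] <- ledger["absorbed"] + sum(w_before * (1 - fac))
    finite_step <- ifelse(is.finite(step), step, 0)
    rays$position <- rays$position + rays$e_p * finite_step
    rays$path_length <- rays$path_length + finite_step
    rays$phase <- rays$phase + 2 * pi * n_med * finite_step / rays$wavelength
    exiting <- t_b <= s & is.finite(t_b)
    stuck <- is.infinite(s) & is.infinite(t_b)
    done <- exiting | stuck
    if (any(done)) {
      ex <- bundle_subset(rays, exiting)
      if (ex$n && inherits(geometry, "slab_geometry")) {
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
      } else if (ex$n) {
        out[[length(out) + 1L]] <- exit_rows(ex, "exited")
        ledger["transmitted"] <- ledger["transmitted"] + sum(ray_weight(ex))
      }
      if (any(stuck)) {
        sub <- bundle_subset(rays, stuck)
        out[[length(out) + 1L]] <- exit_rows(sub, "capped")
        ledger["capped"] <- ledger["capped"] + sum(ray_weight(sub))
      }
      excitable <- excitable[!done]
      rays <- bundle_subset(rays, !done)
    }
    if (rays$n == 0L) break
    # segment-end events
    u <- stats::runif(rays$n)
    fluoresce <- excitable & u < fluor$p_f
    scatter <- (excitable & u >= fluor$p_f & u < fluor$p_f + p_s) |
      (!excitable & medium$mu_s > 0)
    if (any(fluoresce)) {
      sub <- bundle_subset(rays, fluoresce)
      fl_events[[length(fl_events) + 1L]] <-
        data.frame(x = sub$position[, 1], y = sub$position[, 2],
                   z = sub$position[, 3], path_length = sub$path_length)
      w_in <- ray_weight(sub)
      sub <- emit_fluorescence(sub, fluor)
      ledger["yield_loss"] <- ledger["yield_loss"] +
        sum(w_in) - sum(ray_weight(sub))
      if (follow_emission) {
        rays <- bundle_assign(rays, fluoresce, sub)
      } else {
        out[[length(out) + 1L]] <- exit_rows(sub, "emitted")
        ledger["transmitted"] <- ledger["transmitted"] + sum(ray_weight(sub))
        rays <- bundle_subset(rays, !fluoresce)
        scatter <- scatter[!fluoresce]
      }
    }
    if (rays$n == 0L) break
    if (any(scatter)) {
      sub <- scatter_bundle(bundle_subset(rays, scatter), medium)
      rays <- bundle_assign(rays, scatter, sub)
    }
    capped <- rays$events >= max_events
    if (any(capped)) {
      sub <- bundle_subset(rays, capped)
      out[[length(out) + 1L]] <- exit_rows(sub, "capped")
      ledger["capped"] <- ledger["capped"] + sum(ray_weight(sub))
      rays <- bundle_subset(rays, !capped)
    }
    if (rays$n == 0L) break
    w <- ray_weight(rays)
    low <- w < weight_floor
    if (any(low)) {
      ur <- stats::runif(rays$n)
      kill <- low & ur >= roulette_survival
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
  fl <- if (length(fl_events)) do.call(rbind, fl_events) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               path_length = numeric(0))
  structure(list(exits = exits, fluor_events = fl, ledger = ledger),
            class = c("fluor_result", "transport_result"))
}
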