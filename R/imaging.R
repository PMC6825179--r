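# Detector-plane image formation (pinhole/bucket detection), Mueller-matrix
# backscatter imaging, and the Beer-Lambert vessel-contrast / oximetry
# analysis.

#' Detector specification
#'
#' A pixelated detector on a plane normal to z. In `"direct"` mode exit
#' positions are binned as-is; in `"lens"` mode an ideal thin-lens mapping
#' scales object-plane positions by `-magnification` before binning.
#'
#' @param nx,ny Pixel counts.
#' @param pitch Pixel pitch (um).
#' @param center Length-2 lateral centre of the detector (um).
#' @param mode `"direct"` or `"lens"`.
#' @param magnification Lateral magnification of the ideal lens mapping.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(nx, ny, pitch, center = c(0, 0),
                          mode = c("direct", "lens"), magnification = 1) {
  if (pitch <= 0) stop("pixel pitch must be > 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), pitch = pitch,
                 center = center, mode = match.arg(mode),
                 magnification = magnification),
            class = "detector_spec")
}

#' Accumulate exit rays onto a detector
#'
#' Each accepted ray adds its weight (or an externally supplied per-ray
#' intensity) to the pixel containing its mapped position. Rays falling
#' outside the pixel grid are counted and their weight reported, never
#' silently dropped.
#'
#' @param rays Exit-record data frame with columns `x`, `y`, `weight`.
#' @param det A [detector_spec()].
#' @param intensity Optional per-ray intensities overriding `rays$weight`
#'   (e.g. analyzer-projected intensities).
#' @return An object of class `detector_image`: `pixels` (nx x ny weight
#'   matrix), `n_rays`, `missed_weight`, `missed_rays`, `det`.
#' @export
accumulate_detector <- function(rays, det, intensity = NULL) {
  stopifnot(inherits(det, "detector_spec"))
  w <- if (is.null(intensity)) rays$weight else intensity
  pos <- cbind(rays$x, rays$y)
  if (det$mode == "lens") pos <- -det$magnification * pos
  ix <- floor((pos[, 1] - det$center[1]) / det$pitch + det$nx / 2) + 1L
  iy <- floor((pos[, 2] - det$center[2]) / det$pitch + det$ny / 2) + 1L
  ok <- ix >= 1L & ix <= det$nx & iy >= 1L & iy <= det$ny
  img <- matrix(0, det$nx, det$ny)
  if (any(ok)) {
    flat <- ix[ok] + det$nx * (iy[ok] - 1L)
    acc <- tapply(w[ok], flat, sum)
    img[as.integer(names(acc))] <- as.numeric(acc)
  }
  structure(list(pixels = img, n_rays = length(w),
                 missed_weight = sum(w[!ok]), missed_rays = sum(!ok),
                 det = det),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> %d x %d px, total %.4g, missed %.4g (%d rays)\n",
              x$det$nx, x$det$ny, sum(x$pixels), x$missed_weight,
              x$missed_rays))
  invisible(x)
}

#' Pinhole-summed signal
#'
#' Sums the detector pixels whose centres lie within a disc (the pinhole);
#' `radius = Inf` gives bucket (full-aperture) detection.
#'
#' @param image A [accumulate_detector()] result.
#' @param radius Pinhole radius (um).
#' @param center Length-2 pinhole centre (um, detector coordinates).
#' @return Scalar signal.
#' @export
pinhole_signal <- function(image, radius, center = c(0, 0)) {
  det <- image$det
  xc <- (seq_len(det$nx) - 0.5 - det$nx / 2) * det$pitch + det$center[1]
  yc <- (seq_len(det$ny) - 0.5 - det$ny / 2) * det$pitch + det$center[2]
  r2 <- outer((xc - center[1])^2, (yc - center[2])^2, "+")
  sum(image$pixels[r2 <= radius^2])
}

#' Write a detector image as 32-bit float TIFF with a JSON sidecar
#'
#' @param image A `detector_image`.
#' @param file Output TIFF path; the sidecar is `<file>.json`.
#' @param meta Named list merged into the sidecar (seed, scene hash, ...).
#' @return The path, invisibly.
#' @export
write_detector_image <- function(image, file, meta = list()) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to write TIFF images")
  px <- image$pixels
  mx <- max(px)
  tiff::writeTIFF(if (mx > 0) px / mx else px, file, bits.per.sample = 32L)
  side <- c(list(n_rays = image$n_rays, missed_weight = image$missed_weight,
                 missed_rays = image$missed_rays, max_weight = mx,
                 nx = image$det$nx, ny = image$det$ny,
                 pitch = image$det$pitch), meta)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Mueller-matrix imaging (6 input x 6 analyzer protocol)

# Jones vectors (lab x, y) of the six protocol states, consistent with the
# package Stokes convention (V = -2 Im(Ex Ey*)).
protocol_jones <- function() {
  list(H = c(1, 0), V = c(0, 1),
       P = c(1, 1) / sqrt(2), M = c(1, -1) / sqrt(2),
       R = c(1, 1i) / sqrt(2), L = c(1, -1i) / sqrt(2))
}

protocol_stokes <- function() {
  rbind(H = c(1, 1, 0, 0), V = c(1, -1, 0, 0),
        P = c(1, 0, 1, 0), M = c(1, 0, -1, 0),
        R = c(1, 0, 0, 1), L = c(1, 0, 0, -1))
}

# Least-squares reconstruction operator: 16 x 36 matrix mapping the 36
# measured intensities I[analyzer, input] (column-major over analyzers fast)
# to vec(M) (column-major 4 x 4).
mueller_design_pinv <- function() {
  S <- protocol_stokes()
  D <- matrix(0, 36, 16)
  r <- 0L
  for (j in 1:6) for (i in 1:6) {
    r <- r + 1L
    D[r, ] <- 0.5 * kronecker(S[j, ], S[i, ])
  }
  solve(crossprod(D), t(D))
}

#' Mueller matrix of a Jones element
#'
#' Converts a 2 x 2 complex Jones matrix (lab x, y basis) to its 4 x 4
#' Mueller matrix under the package Stokes convention, via exact simulation of
#' the 6 x 6 polarization-state protocol.
#'
#' @param J 2 x 2 complex matrix.
#' @return 4 x 4 real Mueller matrix.
#' @export
mueller_from_jones <- function(J) {
  jon <- protocol_jones()
  I36 <- numeric(36)
  r <- 0L
  for (j in 1:6) for (i in 1:6) {
    r <- r + 1L
    eo <- J %*% jon[[j]]
    I36[r] <- Mod(Conj(jon[[i]][1]) * eo[1] + Conj(jon[[i]][2]) * eo[2])^2
  }
  matrix(mueller_design_pinv() %*% I36, 4, 4)
}

#' Reconstruct a Mueller matrix image stack from analyzer images
#'
#' @param images A 6 x 6 list-matrix (or nested list) of equal-size intensity
#'   matrices, `images[[analyzer]][[input]]`.
#' @return nx x ny x 4 x 4 array of per-pixel Mueller elements.
#' @export
mueller_from_images <- function(images) {
  P <- mueller_design_pinv()
  nx <- nrow(images[[1]][[1]]); ny <- ncol(images[[1]][[1]])
  stack <- matrix(0, 36, nx * ny)
  r <- 0L
  for (j in 1:6) for (i in 1:6) {
    r <- r + 1L
    stack[r, ] <- as.numeric(images[[i]][[j]])
  }
  vecM <- P %*% stack
  out <- array(0, c(nx, ny, 4, 4))
  for (q in 1:4) for (p in 1:4)
    out[, , p, q] <- matrix(vecM[p + 4 * (q - 1), ], nx, ny)
  out
}

#' Mueller-matrix backscatter imaging of a turbid slab
#'
#' Runs the full 6-input-state / 6-analyzer measurement protocol on a
#' backscattering slab: one polarized Monte-Carlo transport run per input
#' state, with the backscattered (reflected) exit rays analyzed by all six
#' analyzer states and accumulated into detector images at the entry face.
#' The per-pixel Mueller stack is recovered by least squares from the 36
#' intensity images. A per-element variance proxy (total reflected weight per
#' pixel) is returned to judge the stability of the estimates.
#'
#' @param medium A [medium_optics()].
#' @param thickness Slab thickness (um).
#' @param n_rays Rays per input state.
#' @param det A [detector_spec()] for the backscatter image.
#' @param seed Integer seed; run `j` uses `seed + j`.
#' @param max_events Event cap per ray.
#' @return A list of class `mueller_map`: `M` (nx x ny x 4 x 4 array),
#'   `weight` (per-pixel total reflected weight), `n_rays`.
#' @export
mueller_backscatter_map <- function(medium, thickness, n_rays, det,
                                    seed = 1L, max_events = 500L) {
  jon <- protocol_jones()
  images <- lapply(1:6, function(i) vector("list", 6))
  wtot <- matrix(0, det$nx, det$ny)
  for (j in 1:6) {
    rays <- local({
      set.seed(seed + j, kind = "Mersenne-Twister")
      launch_collimated(n_rays, jones = jon[[j]],
                        wavelength = medium$spec$wavelength)
    })
    res <- propagate_through_medium(rays, medium,
                                    slab_geometry(thickness),
                                    max_events = max_events)
    bk <- res$exits[res$exits$status == "reflected", ]
    for (i in 1:6) {
      a <- jon[[i]]
      Ia <- Mod(Conj(a[1]) * bk$Ex + Conj(a[2]) * bk$Ey)^2
      images[[i]][[j]] <- accumulate_detector(bk, det, intensity = Ia)$pixels
    }
    wtot <- wtot + accumulate_detector(bk, det)$pixels
  }
  structure(list(M = mueller_from_images(images), weight = wtot,
                 n_rays = n_rays),
            class = "mueller_map")
}

#' Azimuthal harmonic power of an image annulus
#'
#' Averages image values in azimuthal bins over a radial annulus around the
#' centre and returns the squared-magnitude Fourier coefficients over
#' azimuth, used to quantify the fourfold (quadrifolium) symmetry of
#' polarized backscatter patterns.
#'
#' @param img Numeric matrix (pixels).
#' @param pitch Pixel pitch (um).
#' @param r_inner,r_outer Annulus radii (um).
#' @param n_bins Number of azimuthal bins.
#' @return Data frame with `harmonic` (0..n_bins/2) and `power`.
#' @export
azimuthal_harmonics <- function(img, pitch, r_inner, r_outer, n_bins = 36) {
  nx <- nrow(img); ny <- ncol(img)
  xc <- (seq_len(nx) - 0.5 - nx / 2) * pitch
  yc <- (seq_len(ny) - 0.5 - ny / 2) * pitch
  X <- matrix(xc, nx, ny); Y <- matrix(yc, nx, ny, byrow = TRUE)
  R <- sqrt(X^2 + Y^2); A <- atan2(Y, X) %% (2 * pi)
  sel <- R >= r_inner & R <= r_outer
  bin <- pmin(floor(A[sel] / (2 * pi) * n_bins) + 1L, n_bins)
  prof <- as.numeric(tapply(img[sel], factor(bin, levels = seq_len(n_bins)),
                            mean))
  prof[is.na(prof)] <- 0
  co <- stats::fft(prof) / n_bins
  m <- 0:(n_bins %/% 2)
  data.frame(harmonic = m, power = Mod(co[m + 1])^2)
}

# ---------------------------------------------------------------------------
# Vessel contrast and Beer-Lambert oximetry

#' Michelson vessel contrast
#'
#' \eqn{C = (I_b - I_v) / (I_b + I_v)} for a vessel intensity \eqn{I_v} on
#' background \eqn{I_b}.
#'
#' @param I_vessel Vessel (absorbing-structure) intensity, `0 <= I_vessel <=
#'   I_background`.
#' @param I_background Background intensity (> 0).
#' @return Contrast in \eqn{[0, 1]}.
#' @export
vessel_contrast <- function(I_vessel, I_background) {
  if (any(I_background <= 0)) stop("background intensity must be > 0")
  if (any(I_vessel < 0)) stop("intensities must be nonnegative")
  if (any(I_vessel > I_background))
    stop("vessel intensity must not exceed background")
  (I_background - I_vessel) / (I_background + I_vessel)
}

#' Vessel contrast minimizing the relative optical-density uncertainty
#'
#' For vessel transmission \eqn{t = I_v / I_b} the optical density is
#' \eqn{OD = \log_{10}(I_b / I_v)}. Under additive intensity noise of fixed
#' standard deviation on the vessel signal, the propagated OD uncertainty is
#' \eqn{\sigma_{OD} \propto 1/(t \ln 10)}, so the relative OD uncertainty is
#' \eqn{\sigma_{OD}/OD \propto 1/(t \ln(1/t))}. This function minimizes it by
#' a 1-D numerical search; the optimum is \eqn{t^* = 1/e}, i.e.
#' \eqn{OD = \log_{10} e \approx 0.434} and a Michelson contrast of about 46
#' percent.
#'
#' @return A list with `transmission` (t*), `od` (optical density at t*) and
#'   `contrast` (Michelson contrast at t*).
#' @export
optimal_contrast_for_od_precision <- function() {
  rel_od_uncertainty <- function(t) (1 / (t * log(10))) / log10(1 / t)
  opt <- stats::optimize(rel_od_uncertainty, interval = c(1e-9, 1 - 1e-9),
                         tol = 1e-12)
  t_star <- opt$minimum
  list(transmission = t_star,
       od = log10(1 / t_star),
       contrast = vessel_contrast(t_star, 1))
}

#' Two-wavelength Beer-Lambert oxygen saturation
#'
#' Solves the standard two-wavelength Beer-Lambert model
#' \eqn{OD_\lambda = f\, c\, d\,[\varepsilon_{HbO_2}(\lambda) S +
#' \varepsilon_{Hb}(\lambda)(1 - S)]} for the oxygen saturation fraction
#' \eqn{S}; the path factor \eqn{f} (1 single-pass, 2 double-pass) and the
#' concentration-path product cancel in the OD ratio.
#'
#' @param od1,od2 Measured optical densities at the two wavelengths (>= 0).
#' @param extinction 2 x 2 matrix of molar extinction coefficients, rows =
#'   wavelengths (1, 2), columns = species `(HbO2, Hb)`.
#' @param path_factor Single- vs double-pass factor (kept for interface
#'   completeness; it does not affect S).
#' @return Saturation fraction `S`.
#' @export
two_wavelength_saturation <- function(od1, od2, extinction, path_factor = 1) {
  if (od1 < 0 || od2 < 0) stop("optical densities must be >= 0")
  extinction <- as.matrix(extinction)
  stopifnot(all(dim(extinction) == c(2, 2)))
  eo <- extinction[, 1]; ed <- extinction[, 2]
  a <- eo - ed
  if (od2 == 0) stop("od2 must be > 0 to form the OD ratio")
  R <- (od1 / path_factor) / (od2 / path_factor)
  den <- a[1] - R * a[2]
  if (abs(den) < 1e-12 * max(abs(extinction)))
    stop("degenerate extinction pair (isosbestic at both wavelengths)")
  (R * ed[2] - ed[1]) / den
}
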