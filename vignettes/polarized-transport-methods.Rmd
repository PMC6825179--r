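---
title: "Methods: polarized Monte-Carlo light transport in turbid media"
author: "polmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarized Monte-Carlo light transport in turbid media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polmc)
```

# The model

`polmc` simulates how polarized light propagates through turbid (scattering
and absorbing) biological media and how images form at a detector. The
simulation is a hybrid of stochastic ray optics (Monte-Carlo photon packets)
and scalar wave optics (angular-spectrum diffraction), with the following
physical ingredients.

## Single scattering: Mie theory

Scatterers are homogeneous spheres characterized by the size parameter
$\alpha = \pi d n / \lambda$ ($d$ particle diameter, $n$ medium index,
$\lambda$ vacuum wavelength). The amplitude scattering matrix of a sphere is
diagonal: the scattered field components parallel and perpendicular to the
scattering plane are $E_\ell^s = N S_2(\theta) E_\ell^i$ and
$E_r^s = N S_1(\theta) E_r^i$, with $S_1, S_2$ from the Mie series and $N$ a
normalization that preserves the packet intensity (the extinction of the
beam is carried separately by the $\mu_a$, $\mu_s$ coefficients, so a
scattering event only redirects energy). The off-diagonal amplitudes $S_3,
S_4$ vanish for spheres and are fixed at zero; non-spherical particles are
out of scope.

The series is truncated at the Wiscombe order $x + 4x^{1/3} + 2$ plus a
safety margin of 15 terms; the logarithmic derivative $D_n(mx)$ is computed
by downward recurrence and the Riccati–Bessel functions by upward recurrence.
Convergence failures (non-finite coefficients, $\alpha$ beyond the supported
range) raise errors rather than truncating silently. The test suite checks
the amplitudes against a structurally different implementation (half-integer
Bessel functions, doubled truncation order) to $10^{-10}$ relative, and
efficiencies against the classic benchmark $Q_{ext}(x{=}10, m{=}1.5) =
2.8820$.

## The polarization-dependent phase function

For incident light with degree of linear polarization
$L = \sqrt{Q^2 + U^2}/I$, the probability density of the scattering
direction is bivariate:

$$F(\theta, \phi) = A\left[|S_2|^2 + |S_1|^2 +
  L\,(|S_2|^2 - |S_1|^2)\cos 2\phi\right],$$

with the azimuth $\phi$ measured from the major axis of the incident
polarization ellipse. $A$ is always computed numerically so that
$\int F \sin\theta\, d\theta\, d\phi = 1$, by Gauss–Legendre quadrature in
$\cos\theta$ with 512 nodes. Because $|S_{1,2}|^2$ are polynomials in
$\cos\theta$ of degree at most twice the truncation order, this quadrature
is exact at double precision for every size parameter the package tests. In
the Rayleigh limit the normalized density approaches
$\tfrac{3}{16\pi}(\cos^2\theta + 1 - L \sin^2\theta \cos 2\phi)$; the
package enforces the normalization and verifies the angular *shape* of this
limit (an often-quoted closed-form prefactor of $3/(4\pi)$ is inconsistent
with unit normalization over the sphere, which is why the constant is never
taken from a printed formula).

## Dynamic look-up-table angle sampling

$F(\theta,\phi)$ cannot be inverted analytically and depends on the
a-priori-unknown $L$ of each packet, so the sampler splits it as
$F \propto F_1 + L F_2$ with $F_1 = |S_2|^2 + |S_1|^2$ and
$F_2 = (|S_2|^2 - |S_1|^2)\cos 2\phi$. Both parts are tabulated once per
medium on a product grid: $\theta_i = \arccos(2(i-1)/(m-1) - 1)$ (uniform in
$\cos\theta$, so the $\sin\theta$ Jacobian is absorbed by the grid) and
$\phi_j = 2\pi(j-1)/n$, ordered lexicographically $k = i + m(j-1)$.
Cumulative trapezoidal integrals $G_1[k], G_2[k]$ are precomputed; at each
event the sampler forms $r_{\max} = G_1[mn] + L\,G_2[mn]$, draws
$r \sim U[0, r_{\max}]$, locates the cell by binary search on
$G_1 + L G_2$ (left-closed/right-open cells; $r = r_{\max}$ maps to the last
cell), and interpolates $(\theta, \phi)$ uniformly within the cell with two
further uniform draws.

Two numerical choices deserve mention:

* **Column seams.** The lexicographic index steps from $\theta = 0$ (end of
  one azimuth column) back to $\theta = \pi$ (start of the next). A
  trapezoid increment across this seam would attribute spurious probability
  to a degenerate cell, biasing the exact-forward direction; the cumulative
  sums are therefore taken within each azimuth column and the seam steps
  carry zero mass. All real cells keep their ordinary trapezoid weights.
* **Amplitudes at sampled angles.** $S_1, S_2$ for the interpolated
  $\theta$ are linearly interpolated from the cached table by default
  (indistinguishable at $m = 1000$); exact per-event Mie evaluation is a
  switch (`exact_amplitudes`).

The default grid is $m = 1000 \times n = 360$ (sub-degree azimuthal
resolution, a few tens of MB at double precision). Fidelity is verified
against a plain rejection sampler drawing from $F$ directly: two-sample
chi-square on a $24\times12$ equal-measure binning, $10^6$ look-up-table
draws against $5\times10^4$ rejection draws, for every
$(\alpha, L) \in \{0.1, 1, 4, 8.5\} \times \{0, 0.5, 1\}$.

## Polarized transport

Each photon packet carries a position, a right-handed orthonormal triple
$(\hat e_p, \hat e_r, \hat e_\ell)$, a complex field pair $(E_\ell, E_r)$
whose squared moduli sum to the packet weight, a wavelength, accumulated
geometric path and optical phase, and an event counter. Propagation
alternates exponential free paths (mean $1/\mu_s$) with scattering events;
absorption is continuous weight decay $e^{-\mu_a s}$ per segment (applied to
the fields as $\sqrt{\cdot}$), never probabilistic termination. At an event
the frame is rotated about $\hat e_p$ by $\psi + \phi$, where
$\psi = \tfrac12\operatorname{atan2}(U, Q)$ is the ellipse-axis angle in the
$(\hat e_\ell, \hat e_r)$ basis (for $L < 10^{-9}$ the reference is
immaterial by symmetry and $\hat e_\ell$ is used), then $\hat e_p$ is
rotated by $\theta$ in the new scattering plane and the fields are updated
by the amplitude matrix. Frames are re-orthonormalized after every event;
the orthonormality error stays below $10^{-10}$ over $10^3$ chained events.

Termination policy (a free choice — the physics literature rarely states
one): an event cap of $10^4$ per packet whose weight is reported separately,
and an unbiased Russian-roulette stage with survival probability 0.1
triggered below weight $10^{-4}$. The energy ledger

$$\text{launched} = \text{transmitted} + \text{reflected} + \text{absorbed}
  + \text{capped} + \text{roulette}_{net}$$

closes to accumulation rounding on every run; the roulette term is the net
of killed weight minus survivor boosts and is zero whenever the floor is
never reached. Media boundaries are index-matched (no Fresnel step) —
polarization-resolved interface physics is deliberately not modelled inside
the Monte-Carlo medium. Geometry primitives are the infinite axis-aligned
slab $0 \le z \le D$ (with optional embedded absorbing cylinders,
attenuating each segment by its chord length) and watertight triangle
meshes with parity inside-tests.

### Depolarization bookkeeping

Each packet is a pure polarization state, so its *own* degree of linear
polarization decays only through the relative phase of $S_2/S_1$ — at
$\alpha = 1$ those amplitudes are nearly real and the per-packet median
$L$ is flat near 1 to within Monte-Carlo noise. The operative
depolarization of multiple scattering is that of the *ensemble*: the summed
lab-projected Stokes vector loses $\sqrt{Q^2+U^2}/I$ rapidly as directions
and frames randomize. `depolarization_by_order()` reports both columns;
the decay of the ensemble value from 1 to below 0.1 over 12 scattering
orders at $\alpha = 1$ is the tested property.

## Fluorescence

Two mechanisms are provided.

**Probabilistic (transport) fluorescence.** Inside a fluorescent medium,
excitation-band packets advance in exponential segments of mean $\ell_f$
(the fluorescence mean free path). At each segment end the packet
fluoresces with probability $p_f$, elastically scatters with probability
$p_s = \ell_f/\ell_s = \ell_f \mu_s$, or continues straight. The pair
$(\ell_f, p_f)$ sets the excitation penetration depth, $\ell_f/p_f$ without
scattering (a compound geometric–exponential mean, used as the test
oracle). Read literally, $p_s$ exceeds one when $\ell_f > \ell_s$; the
package treats that as a configuration error ($p_f + p_s \le 1$ required)
rather than silently re-interpreting the scheme — segments must resolve the
scattering rate. On conversion the wavelength is redrawn from a line
spectrum (categorical weights), the direction is redrawn isotropically, the
polarization is set fully linear with uniformly random orientation, and the
phase is randomized — incoherent emission with no memory of the excitation
state. Quantum yield defaults to 1 and multiplies the emitted weight;
conversion bookkeeping appears in the ledger. Auto-fluorescence of an
embedding medium is the same mechanism with its own parameters.

**Fluorescence from diffracted beams.** For diffraction-limited excitation
(light sheets, focused beams) a two-pass scheme is used: (1) rays crossing
a recording plane are converted to plane waves — amplitude
$\sqrt{\text{weight}}$, transverse wavevector from the direction, absolute
phase anchored at the crossing point from the accrued optical path — and
summed coherently on a grid (`record_angular_spectrum()`, with rays beyond
the grid's Nyquist angle rejected and counted); (2) the field is advanced
through the sample volume by band-limited angular-spectrum stepping
(evanescent power dropped and reported), with weak inhomogeneity handled by
split-step phase screens accumulated from a voxelized refractive-index
volume. Voxels that are inside a watertight sample mesh and above a
relative-intensity threshold become an excitation table; fluorescence
source packets are then drawn with origins proportional to the voxel
weights (uniform jitter within the voxel), isotropic directions and random
linear polarization. The scalar-field approximation is used for this
diffraction stage; polarization re-enters when the fluorescence packets are
generated.

The refractive-index fluctuations use an isotropic power-law spectrum
$\Phi(k) \propto (k^2 + 1/L_{out}^2)^{-\beta/2}$ — a standard fractal model
family for turbid tissue. The literature this family comes from does not
pin down amplitudes, so the defaults ($\beta = 3.7$, rms $5\times10^{-3}$,
outer scale tens of µm) are explicit configuration, not claims. The
spectral normalization is analytic (expected variance equals the requested
rms²), so a single large realization lands within a few percent of the
target and rescaling never distorts the spectral shape.

## Image formation

Detectors are pixel grids on planes normal to $z$, in direct-binning or
ideal thin-lens (magnification $-M$) mode. Every accepted packet deposits
its weight in exactly one pixel; rays missing the grid are counted and
their weight reported. Pinhole (confocal) and bucket detection are masks
over the same image, so pinhole-radius sweeps are paired by construction.
Detection is paraxial: exit fields are projected on the lab transverse
basis, dropping the longitudinal component.

Mueller-matrix imaging uses the overdetermined 6-input × 6-analyzer
protocol (H, V, ±45°, R, L on both sides, 36 intensity images) and
per-pixel least squares through the precomputed pseudoinverse of the
$36\times16$ design. The same operator converts a Jones matrix to its
Mueller matrix exactly, which doubles as the closed-form reference in the
tests (ideal polarizer recovery; identity control). Backscatter maps from
a turbid slab at $\alpha \approx 1$ show the characteristic four-lobed
(quadrifolium) azimuthal symmetry; the tested statistic is the fraction of
non-DC azimuthal Fourier power in the $m = 2, 4$ harmonics of the
off-diagonal element images over an annulus.

## Vessel contrast and oximetry

Contrast is Michelson, $C = (I_b - I_v)/(I_b + I_v)$ — the only standard
definition consistent with pairing a 46% contrast with a transmission of
$1/e$. For vessel transmission $t$, $OD = \log_{10}(1/t)$; additive
intensity noise on the vessel signal propagates to
$\sigma_{OD} \propto 1/(t \ln 10)$, so the relative OD uncertainty is
$\propto 1/(t\ln(1/t))$, minimized at $t^* = 1/e$ where
$OD = \log_{10} e \approx 0.434$ and $C = (e-1)/(e+1) \approx 46\%$. The
package evaluates this by a 1-D numerical search rather than hard-coding
the closed form. The noise model behind this derivation (additive intensity
noise, relative OD error) is an inference documented here; it reproduces
the printed pairing exactly. Two-wavelength oximetry solves the standard
Beer–Lambert ratio for the oxygen saturation $S$; the path factor
(single/double pass) and the concentration–path product cancel in the
ratio, and an isosbestic wavelength pair is rejected as degenerate.

# Synthetic scenes and what the tests do (and do not) show

All inputs are synthetic. The fixture generators produce homogeneous slab
phantoms, a slab with an embedded absorbing rod (an idealized vessel), a
backscattering slab for the Mueller protocol, and a watertight neuron-like
mesh (icosphere soma plus cylindrical dendrites as separate closed
components, interior = union; impossible dendrite packings are rejected).
These emulate the geometry and optical-property ranges of tissue phantoms —
single monodisperse scatterer species, index-matched boundaries, piecewise
homogeneous media. They do not emulate polydisperse size distributions,
birefringence, rough interfaces, or the aberrations of real instrument
optics, so passing tests validate the transport and imaging kernels, not
instrument-level predictions for any specific microscope.

Problem sizes used by the default checks (chosen to give 3-sigma
statistical resolution at interactive run times): $10^5$ packets for
extinction-law and fluorescence statistics, $10^6$ sampler draws per
$(\alpha, L)$ case, $10^4$ packets for depolarization, $6\times6\times10^4$
packets for Mueller maps, 256²–512² grids for diffraction, and 48³–64³
voxels for fractal volumes.

# Known limitations

* Scalar diffraction only; no vectorial high-NA focal theory.
* Paraxial detection basis; steep exit rays lose their longitudinal field
  component at the detector.
* No Fresnel refraction/reflection at medium boundaries (index-matched
  assumption).
* Single scatterer species per medium; no size distributions or coated
  spheres.
* The Henyey–Greenstein sampler is shipped only as a scalar baseline for
  comparison studies; it carries no polarization and is never used by the
  polarized kernel.
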