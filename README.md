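# polmc — polarized Monte-Carlo light transport in turbid media

`polmc` simulates how polarized light travels through scattering, absorbing
biological media and how images form at a detector. It is aimed at people
who model optical microscopy and ophthalmic imaging of turbid samples —
confocal and scanning-laser systems, light-sheet fluorescence, polarimetric
backscatter imaging, vascular oximetry — and who need a transport kernel
that tracks the full complex field (and therefore polarization and phase) of
every photon packet, not just a scalar weight.

## What it computes

**Single scattering.** Mie amplitude functions S1(θ), S2(θ), efficiencies
Q_ext, Q_sca, Q_abs and anisotropy g for homogeneous spheres, with
Wiscombe-criterion series truncation. A scattering event maps the field as
E<sub>ℓ</sub><sup>s</sup> = N S2 E<sub>ℓ</sub><sup>i</sup>,
E<sub>r</sub><sup>s</sup> = N S1 E<sub>r</sub><sup>i</sup> in the
scattering-plane basis, with N preserving intensity.

**Angle sampling.** The polarization-dependent bivariate phase function

> F(θ, φ) = A [ |S2|² + |S1|² + L (|S2|² − |S1|²) cos 2φ ],

with L the degree of linear polarization of the incident packet and φ
measured from its polarization-ellipse major axis, is sampled by a dynamic
look-up table: the two components are tabulated once on a grid uniform in
cos θ and φ with cumulative integrals G1, G2, and each event draws from
G1 + L·G2 by binary search — no rejection loop, exact polarization
dependence.

**Transport.** Photon packets with orthonormal frames and complex field
pairs alternate exponential free paths and scattering events in slab or
triangle-mesh geometries; absorption is continuous weight decay; embedded
absorbing cylinders model vessels; an exact energy ledger accounts for
every unit of launched weight (transmitted + reflected + absorbed + capped
+ roulette).

**Fluorescence.** Probabilistic wavelength shift per propagation segment
(mean free path ℓ_f, probability p_f, isotropic depolarized re-emission),
plus a two-pass scheme for diffracted excitation: angular-spectrum field
construction from rays, split-step propagation through fractal
refractive-index fluctuations, voxel excitation tables inside watertight
sample meshes, and weighted fluorescence source generation.

**Imaging.** Pixelated detectors with pinhole (confocal) or bucket masks;
Mueller-matrix backscatter imaging via the 6×6 polarization-state protocol;
Michelson vessel contrast and two-wavelength Beer–Lambert oximetry,
including the noise-propagation analysis showing vascular optical density
is most precise at ≈46% contrast.

## Worked example

```r
library(polmc)

# polystyrene-like spheres in water at 488 nm
spec <- scatterer_spec(particle_diameter = 0.5, medium_index = 1.33,
                       particle_index = 1.59, wavelength = 0.488)
print(spec)
#> <scatterer_spec> d = 0.5 um, n_med = 1.33, n_p = 1.59+0i, lambda = 0.488 um, alpha = 4.2811
mie_efficiencies(spec)
#> <mie_efficiencies> Q_ext = 1.29041  Q_sca = 1.29041  Q_abs = 0  g = 0.8680

# a 10 um slab with mu_a = 0.02/um, mu_s = 0.08/um (optical depth 1)
tab <- build_phase_tables(spec)
med <- medium_optics(mu_a = 0.02, mu_s = 0.08, spec, tables = tab)
rays <- local({set.seed(1); launch_collimated(50000, jones = c(1, 0),
                                              wavelength = 0.488)})
res <- propagate_through_medium(rays, med, slab_geometry(10), seed = 1)
print(res)
#> <transport_result> 50000 exit records
#>   launched 5e+04 = transmitted 3.957e+04 + reflected 642.9 + absorbed 9788 + capped 0 + roulette 0

ball <- with(res$exits, status == "transmitted" & events == 0)
sum(res$exits$weight[ball]) / 50000
#> 0.3672   # Beer-Lambert exp(-(mu_a + mu_s) D) = 0.3679

optimal_contrast_for_od_precision()$contrast
#> 0.4621   # ~46%: the vessel contrast at which OD is most noise-robust
```

The first block gives the size parameter α = πdn/λ and the single-particle
optical constants; the anisotropy g = 0.868 says scattering is strongly
forward-peaked. The transport run shows the exact energy ledger, and the
unscattered (ballistic, undeviated) transmission reproduces the extinction
law exp(−(μ<sub>a</sub>+μ<sub>s</sub>)D) to Monte-Carlo precision. The last
line is the analytic optimum of the vascular-oximetry noise analysis.

A command-line driver with subcommands (`mie`, `sample-check`, `transport`,
`fluor`, `sheet`, `mueller`, `oximetry`, `fixtures`) is installed at
`inst/cli/polmc`; every run writes a JSON manifest (seed, config hash,
versions) beside its outputs. Scenes are YAML files with strict validation;
`generate_fixture()` produces slab phantoms, rod-in-slab phantoms,
Mueller slabs and watertight neuron-like meshes deterministically from a
seed.

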