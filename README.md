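# cpetnull

Null-function analysis for charged-particle emission tomography (CPET).

## The problem

CPET reconstructs the 3D distribution of an alpha- or beta-emitting
radioisotope in a tissue slab from a *single projection*: a planar
particle-processing detector (PPD) pressed against one face of the slab.
For every detected particle the PPD estimates up to five attributes — the
interaction position (x_d, y_d), the track direction cosines (s_x, s_y) and
the residual energy E — and stores them as a list. How much of the object is
fundamentally invisible to such a system? That question is answered by its
**null functions**: nonzero objects f with L f = 0, where L is the system
operator with kernel prf(Â | R), the point response function.

Any object splits orthogonally into a measurement component (recoverable
from noise-free data) and a null component (invisible):

    f = f_meas + f_null,
    f_meas = sum over retained modes of  w_n w_n^† f,
    ||f_null||_s = ||f_null||_2 / ||f||_2  (scaled null norm).

The retained modes are eigenfunctions of the projection/backprojection
operator L^† L. Lateral shift invariance and rotational symmetry reduce its
kernel to a depth kernel K(ρ, z, z′) indexed by radial spatial frequency ρ,
so the analysis is a small symmetric eigenproblem at each frequency
(20 depth samples on the default grids), with normalized spectra
λ_n(ρ) = μ_n(ρ)/μ_max and a retention cutoff λ_min = 1e-6.

The package provides, for detectors measuring q = 2, 3, 4, 5 attributes:

* an **analytic alpha forward model** (straight-line tracks, Bragg–Kleeman
  range–energy relation calibrated to 39.4 um at 5.15 MeV, exact binned
  PRFs with mass = sensitivity to machine accuracy, plus an exact list-mode
  sampler);
* a **condensed-history electron Monte Carlo** in water (Berger–Seltzer
  stopping power, Highland multiple scattering, allowed-shape beta
  spectrum) as a documented stand-in for a full transport toolkit;
* **list-mode I/O and histogramming** on the standard analysis bins
  (4 um / 2° / 20 keV, half-open);
* **depth-kernel construction and per-frequency eigenanalysis**;
* **null decomposition** of voxelized test objects (default: a 7-cylinder
  phantom scaled to the slab) with forward/adjoint operators for
  verification.

See `vignettes/cpet-null-functions.Rmd` for the models, numerical choices
and their rationale.

## Worked example

Sweep the four alpha-ET detector types and decompose the default phantom
(40-um slab, depths {1, 3, ..., 39} um, 2-um voxels; about half a minute):

```r
library(cpetnull)
cfg <- experiment_config("alpha", q = 2:5, seed = 1)
bundle <- run_experiment(cfg)
bundle
#> CPET experiment (alpha), seed 1:
#>  q scaled_null_norm
#>  2     8.383000e-01
#>  3     9.745682e-16
#>  4     1.363251e-15
#>  5     3.272912e-16
```

A position-only detector (q = 2) leaves 84% of the phantom's L2 content
invisible — its kernel has rank one per lateral frequency, so depth cannot
be resolved. Measuring energy and/or direction as well (q >= 3) makes the
null space collapse to numerical zero: residual energy (or track angle)
pins down the path length of each straight alpha track and restores depth
information. Inspecting one system and one decomposition:

```r
summary(bundle$systems[["2"]])
#> CPET system summary (alpha, q = 2)
#>   modes with lambda >= 1e-06 per radial sample: 1 .. 1 (of 20)
bundle$decompositions[["2"]]
#> CPET null decomposition (alpha, q = 2, lambda_min = 1e-06)
#>   scaled null norm ||f_null||/||f|| = 0.8383
#>   <f_meas, f_null>/||f||^2 = -4.31e-17; norm-split residual 8.50e-17
```

`plot(bundle$decompositions[["2"]])` shows the object, measurement and null
components in the xz plane; `plot(bundle$systems[["3"]])` the eigenvalue
spectra; `make_report(bundle, out_dir = "report")` exports spectra,
cross-sections and the norm-vs-q table as CSV. The beta pipeline is the
same with `experiment_config("beta", n_particles = 1e5, ...)`, where the
PRFs come from the Monte Carlo module (a few minutes at 1e5 particles per
depth); there the null space collapses only once all five attributes are
measured.

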