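---
title: "Null functions of charged-particle emission tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null functions of charged-particle emission tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpetnull)
```

## The imaging problem

Charged-particle emission tomography (CPET) images the 3D distribution
$f(\mathbf{R})$ of an alpha- or beta-emitting label inside a tissue slab from
a *single projection*: a planar particle-processing detector (PPD) in contact
with one face of the slab. The PPD estimates, for every detected particle, a
subset of five attributes — the interaction position $(x_d, y_d)$ on the
detector plane, the direction cosines $(s_x, s_y)$ of the track, and the
residual energy $E$ — and stores them as continuous values in a list. With
$q \in \{2,3,4,5\}$ measured attributes (always including position), the mean
list-mode data for a unit exposure is

$$\bar u(\hat{\mathbf{A}}) \;=\; \int_{S_f} d^3R \, f(\mathbf{R})\,
  \mathrm{prf}(\hat{\mathbf{A}} \mid \mathbf{R}),$$

where the point response function (PRF) is the probability density of the
estimated attributes given an emission at $\mathbf{R}$, times the detection
sensitivity $S(\mathbf{R})$. Detector estimation uncertainty is deliberately
switched off ($\mathrm{pr}(\hat{\mathbf{A}}\mid\mathbf{A}) = \delta$): the
analysis characterizes the upper performance limit of an ideal detector.

A *null function* is a nonzero object with $\mathcal{L} f = 0$: it is
invisible to the system even in noise-free data. Any object splits uniquely
into a measurement component (the projection onto eigenfunctions of the
projection/backprojection operator $\mathcal{L}^\dagger\mathcal{L}$ with
eigenvalues above a cutoff) and a null component, and the *scaled null norm*
$\|f_{\mathrm{null}}\|_2 / \|f\|_2$ measures the invisible fraction. The
package computes this decomposition for the four detector types and both
particle species.

## Symmetry reduction

In a laterally uniform slab with a detector large compared to the object and
the particle range, the PRF is invariant under lateral shifts and rotations.
The kernel of $\mathcal{L}^\dagger\mathcal{L}$,

$$k(\mathbf{R}, \mathbf{R}') = \int d\hat{\mathbf{A}}\,
  \mathrm{prf}(\hat{\mathbf{A}}\mid\mathbf{R})\,
  \mathrm{prf}(\hat{\mathbf{A}}\mid\mathbf{R}'),$$

then depends laterally only on $\mathbf{r} - \mathbf{r}'$, so 2D Fourier
modes diagonalize the lateral directions and the eigenproblem factors into a
one-dimensional problem per spatial frequency $\boldsymbol{\rho}$:

$$\int_0^{z_{\max}} dz'\, K(\rho, z, z')\, W_j(\rho, z') =
  \mu_{\rho, j} W_j(\rho, z),$$

with $K$ depending only on the radial frequency $\rho$ by rotational
symmetry. On the binned attribute grid the package computes
$K[\rho, z_i, z_j] = \sum_b \hat P_b(\rho, z_i) \overline{\hat P_b(\rho, z_j)}$,
where $\hat P_b$ is the lateral DFT of the PRF slice of non-position
attribute bin $b$, evaluated along $(\rho, 0)$; rotational invariance of this
choice is verified numerically against $(0, \rho)$. The Gram form makes every
$K$ Hermitian positive semidefinite by construction. Sampling $N$ depths
turns each frequency into an $N \times N$ symmetric eigenproblem under the
$\Delta z$-weighted inner product (solved after a similarity transform with
the square-root weight matrix), giving exactly $N$ eigenvalues per frequency
— 20 on the default depth grids. Spectra are reported as
$\lambda_n(\rho) = \mu_n(\rho) / \mu_{\max}$ with a single global
$\mu_{\max}$ per system.

## Alpha forward model (analytic)

Alpha particles in water travel in nearly straight lines and lose energy
deterministically along the path. The model:

* **Range–energy relation.** A Bragg–Kleeman power law,
  $R(E) = R_0 (E / E_0)^p$, calibrated to the single well-established
  constant of the setup: a 5.15-MeV alpha (principal Pu-239 line) has a CSDA
  range of 39.4 um in water. The exponent $p$ (default 1.8, the standard
  value for MeV alphas) only reshapes the interior of the energy axis and is
  configurable; no external stopping-power tables are shipped.
* **Sensitivity.** Isotropic emission at depth $z$ reaches the detector iff
  the straight path $z / \cos\theta \le R_0$, giving
  $S(z) = (1 - z / R_0)/2$.
* **Exact binned PRF.** At fixed $z$ every attribute is a deterministic,
  monotone function of the emission direction $(\theta, \phi)$. Preimages of
  all $\theta$-bin and $E$-bin edges are radii in the lateral plane, so the
  package integrates $\sin\theta / 4\pi$ in closed form over elementary polar
  cells bounded by those radii (further subdivided to a configurable radial
  step and arc length, defaults 0.5 um and 1 um), and assigns each cell's
  exact mass to the Cartesian lateral bin containing its midpoint. Total
  mass per depth therefore equals $S(z)$ to floating-point accuracy, and the
  $q<5$ grids are exact marginals of the $q=5$ grid. The midpoint assignment
  is the only approximation; it is validated against an exact event sampler
  by chi-square tests.
* **Infinite-detector PRFs.** PRFs are tabulated for an unbounded detector
  plane (required by the shift-invariance argument); the finite
  160 × 160 um² extent is enforced only in list-mode sampling.

The continuous $q \ge 3$ PRF contains delta-ridge correlations between
radius, angle and energy; the package defines the PRF only on the binned
attribute grid (exact per-bin integrals), never as a continuous density.

## Beta forward model (condensed-history Monte Carlo)

Fast electrons scatter strongly, so the beta PRF is estimated by Monte
Carlo. The transport model is a deliberately simple condensed-history
scheme, a documented stand-in for a full simulation toolkit:

* collision stopping power of water from the Berger–Seltzer formula
  (mean excitation energy 75 eV), applied deterministically per step with a
  midpoint rule;
* Gaussian multiple scattering with Highland width
  $\theta_0 = (13.6\,\mathrm{MeV}/\beta c p)\sqrt{\Delta s / X_0}$ (no
  logarithmic correction), $X_0 = 36.08$ cm for water, applied in two
  orthogonal planes per step;
* step length $\min(1\,\mu m, 2\%$ of the residual CSDA range$)$;
  low-energy cutoff 10 keV (local absorption); lateral bookkeeping bound and
  a track-length guard;
* emission energies from the allowed-shape beta spectrum
  $p(E) \propto \sqrt{E^2 + 2 E m_e c^2}\,(E + m_e c^2)\,(Q - E)^2$ with
  $Q = 633.5$ keV for the default F-18-like source, or monoenergetic lines.

All constants are implementer-chosen defaults from standard references, not
fitted values. Omitted physics: energy-loss straggling, bremsstrahlung,
annihilation, secondaries, detector backscatter. Two consequences matter for
interpretation. First, quantitative agreement with a production transport code is not
claimed — only the structural trend of the null norm with $q$. Second,
because energy loss is deterministic here, residual energy and path length
are in exact correspondence, which makes direction-measuring detectors
($q \ge 4$) somewhat stronger in this model than they would be with
straggling; the $q = 4$ beta null norm is therefore expected to come out
lower than a full simulation would give, while the $q = 5$ conclusion (null
space essentially eliminated) is robust.

With scattering disabled and a power-law stopping model matched to the alpha
range–energy relation, the beta transport reduces exactly to the alpha
geometry; the test suite uses this ballistic limit as a cross-model oracle.

## Binning and list-mode conventions

Histograms use the analysis bins $\Delta\theta = \Delta\phi = 2^\circ$ and
$\Delta E = 20$ keV throughout; direction is binned in track angles
$(\theta, \phi)$ at the detector plane even though list-mode rows store
direction cosines. All bins are half-open $[\mathrm{low}, \mathrm{high})$ —
the boundary convention is declared, not inferred. Lateral bins are centered
on integer multiples of the bin width (an odd, zero-centered axis), which
makes the axis exactly reflection-symmetric and lets PRF slices act as
discrete convolution kernels on voxel grids of the same spacing. Lateral
offsets are always taken relative to the source's lateral position.

Monte Carlo histograms are symmetrized by averaging each event with its
point reflection $(x, y, \phi) \to (-x, -y, \phi + 180^\circ)$ before kernel
building. The true PRF has this symmetry exactly, so symmetrization is pure
variance reduction; it also makes the depth kernels real-symmetric to
machine precision, which the kernel builder enforces (an unsymmetrized
finite-count histogram fails its imaginary-residue check).

### Lateral sampling of the PRF

A subtle numerical requirement drives one departure from the 4-um Monte
Carlo histogram bin that is natural for beta list-mode storage: the
decomposition operates on the object's DFT grid, whose radial frequencies
extend to $\sqrt{2}$ times the per-axis Nyquist frequency. If the PRF is
tabulated laterally coarser than half the object voxel, frequencies beyond
the PRF's lateral Nyquist have no valid kernel (the lattice sum aliases),
and declaring them null imposes a purely numerical floor on every null norm
— about 0.3 for the default phantom at 2-um voxels with 4-um PRF bins,
which would swamp the physics entirely. The package therefore tabulates the
analytic alpha PRF at 1 um and histograms the beta PRF at 2 um for kernel
building, so the kernel's radial coverage contains the object spectrum's
full disc; the 4-um bin remains the default lateral bin for beta analysis
histograms viewed as data.

## Eigenanalysis and decomposition

* **Radial sampling.** Kernels are built at `n_rho = 64` equispaced radial
  frequencies from 0 to the PRF lateral Nyquist. For each distinct radius on
  the object's DFT grid, $K$ is interpolated *linearly in $\rho$* (convex
  combinations preserve symmetry and positive semidefiniteness) and
  eigendecomposed exactly there. Interpolating the kernel rather than the
  eigenpairs keeps the per-frequency operator an exact orthogonal projector
  — projector idempotence, component orthogonality and the Pythagorean norm
  split then hold to machine precision rather than to interpolation
  accuracy. A doubling test on `n_rho` (in the test suite) bounds the
  interpolation error on the reported norms.
* **Cutoff.** The measurement component retains eigenfunctions with
  $\lambda = \mu / \mu_{\max} \ge \lambda_{\min}$, default
  $\lambda_{\min} = 10^{-6}$, the conventional threshold below which
  numerically computed spectra of this problem are noise-dominated. The
  analytic alpha kernels have a much lower numerical noise floor, but the
  default is kept for comparability; it is configurable everywhere.
* **Numerical guards.** Eigenvalues in $[-10^{-10}\mu_{\max}, 0)$ are
  clipped to zero; anything more negative aborts. Kernel asymmetry and
  imaginary residues beyond $10^{-10}$ (relative) abort. The reassembled
  measurement component must be real to $10^{-9}$ (relative to the input).
* **Frequencies outside kernel coverage** (possible only if the PRF is
  tabulated coarser than recommended above) are treated as fully null.
* **Sum over modes.** The eigenfunction expansion of the measurement
  component is evaluated on the object's discrete DFT grid (sum over the
  grid's frequency vectors), not as a continuous integral with a frequency
  measure; with the recommended sampling both views coincide on the grid.

## The test phantom

The 7-cylinder phantom ships as a relative YAML config scaled by the slab
thickness: radii 10–30%, heights 25–60% of $z_{\max}$, distinct lateral
positions and depths, unit density. Exact dimensions are a package choice
(only relative proportions are dictated by the reference layout); the
acceptance properties — orthogonality, monotonicity with $q$, near-zero
alpha norms for $q \ge 3$ — are robust to the phantom details by
construction. Voxelization is by center-point test; depth slices coincide
with the kernel depth grid, so no depth interpolation ever occurs. Default
voxels: 2 um lateral (alpha), 4 um (beta); extent = detector extent.

## Study conditions and desk-scale choices

Defaults reproduce the standard setups: alpha — monoenergetic 5.15 MeV,
$R_0 = 39.4$ um, 40-um slab, 160-um detector, depths $\{1, 3, \ldots, 39\}$
um; beta — F-18-like spectrum, 100-um slab, 1024-um detector, depths
$\{5, 10, \ldots, 100\}$ um. The beta generator default is $10^5$ particles
per depth, a desk-scale setting one to two orders of magnitude below a
production Monte Carlo run; the extra Poisson error propagates into the
Monte Carlo tolerances used in the tests and is the reason near-zero beta
norms are asserted at 0.1 rather than at the alpha tolerance of 0.05. The
exposure time is a pure scale factor on all eigenvalues and is fixed at 1;
normalized spectra are unaffected.

## What the synthetic data do and do not show

The generators emulate the *geometry and transport* of the two modalities:
depth-dependent sensitivity, lateral spreading, the radius–angle–energy
correlations of straight alpha tracks, and the tortuous-path blurring of
electrons. They do not emulate detector estimation noise (switched off by
design), source spectra beyond a single line or one allowed-shape spectrum,
tissue heterogeneity, straggling, or count-limited acquisition. Passing
tests therefore demonstrate the intrinsic, best-case null-space structure of
the detector types, not the performance of any physical instrument; with
estimation uncertainty restored, measurement components would only shrink.

## Known limitations

* The beta transport is a simplified stand-in; its $q = 4$ null norm is
  likely optimistic (see above).
* Periodic (circular) lateral convolutions are used in the forward and
  adjoint operators; objects must stay clear of the lateral boundary by
  roughly the particle range for wrap-around to be negligible.
* The alpha $q = 5$ system is the known non-compact case in the continuum;
  it is analyzed only on the discrete depth grid, like the other systems.
* Monte Carlo kernels inherit statistical noise; eigenvalues below the
  noise floor are unreliable, which is exactly what the $10^{-6}$ cutoff
  excludes.

## A minimal run

```{r example, eval = FALSE}
cfg <- experiment_config("alpha", q = 2:5, seed = 1)
bundle <- run_experiment(cfg)
bundle$norms                      # scaled null norm vs q
plot(bundle$systems[["3"]])       # eigenvalue spectra lambda_n(rho)
plot(bundle$decompositions[["2"]])  # object / measurement / null views
make_report(bundle, out_dir = "report")
```
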