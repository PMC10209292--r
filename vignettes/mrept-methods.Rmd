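---
title: "Phase-based MREPT: model, pipeline design and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based MREPT: model, pipeline design and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrept)
```

## The measurement model

Magnetic resonance electrical properties tomography (MREPT) estimates
tissue conductivity from the radio-frequency field that a scanner already
measures. In its phase-based form, only the transceive phase
$\varphi_\pm$ of the complex image is used, under the assumption that the
transmit field magnitude varies slowly compared with its phase. The
working relation is

$$\sigma \;\approx\; \frac{\nabla^2 \varphi_\pm}{2 \mu_0 \omega},$$

with $\mu_0 = 4\pi\times10^{-7}$ H/m and $\omega = 2\pi f_0$ the Larmor
angular frequency ($f_0 = 127.76$ MHz at 3 T, giving
$2\mu_0\omega \approx 2017.5$; a phase Laplacian of 2017.5 rad/m$^2$
corresponds to 1 S/m). Everything in this package exists to evaluate that
Laplacian robustly on measured (wrapped, noisy) phase, and to quantify how
repeatable the resulting conductivity values are.

The pipeline is: **unwrap** the phase, optionally **denoise** it,
estimate the **Laplacian** by local parabola fits restricted to one
tissue, **convert** to conductivity, and **summarize** regions of
interest with repeatability statistics.

## Why the forward simulator solves the *discrete* Poisson problem

No scanner data ships with the package, so a forward simulator generates
the inputs. Given a piecewise-constant conductivity phantom it solves

$$L_7[\varphi] = 2\mu_0\omega\,\sigma$$

where $L_7$ is the 7-point finite-difference Laplacian with spacing in
meters and zero-Dirichlet values on the one-voxel grid boundary. The
solve diagonalizes $L_7$ with a type-I sine transform per axis
(implemented as dense orthogonal matrix products; grids here are small
enough that this costs milliseconds), so applying the same stencil to the
output reproduces the source at machine precision.

This is a deliberate design choice, not a physics simulation. Because the
generator and the inverse problem share the same discrete operator, a
perfect reconstruction is *representable*, and any deviation observed in
a round trip is attributable to the pipeline (unwrapping, fitting,
masking) rather than to discretization of a continuum model. The cost of
that choice is realism: no electromagnetic boundary conditions, no coil
phase, no banding, no $B_0$ inhomogeneity. Conclusions from these tests
therefore concern the *numerics* of the pipeline, not its behaviour on
real tissue; the boundary layer is excluded from all recovery metrics
(kernel restriction excludes it in real reconstructions too).

The built-in phantoms are a two-cylinder saline phantom at 0.540 and
1.069 S/m (the conductivities of 3.3 and 6.6 g/L NaCl near room
temperature) and a brain-like nested-shell phantom at the literature
tissue values 0.34 (WM), 0.59 (GM) and 2.14 (CSF) S/m. Noise is circular
complex Gaussian added to $M e^{i\varphi}$ with per-channel SD
$\overline{M}_{fg}/\mathrm{SNR}$, so the foreground phase noise SD is
$\approx 1/\mathrm{SNR}$. The study this emulates reports no SNR figures,
so the default SNR of 50 is a free parameter chosen once as typical for a
1 mm$^3$ balanced SSFP acquisition; it is set in the configuration, not
hard-coded.

## Phase unwrapping

The unwrapper is a region-growing scheme: the wrapped interval
$[0, 2\pi)$ is divided into six equal sub-intervals, 6-connected
components within one sub-interval become regions (no wrap can occur
inside a region), and the largest region grows by repeatedly absorbing
the neighbouring region with the largest shared border. Three details are
fixed so the result is deterministic:

* ties in "largest border" (and in the seed choice) go to the lowest
  region label;
* the absorbed region's offset is the integer $k$ minimizing the mean
  absolute phase jump $\overline{|D - 2\pi k|}$ across the shared border,
  ties to the smaller $k$;
* every correction is exactly $2\pi k$, so the output is congruent with
  the input modulo $2\pi$ voxel-by-voxel, and defined up to one global
  $2\pi$ multiple per connected mask component.

The published description this follows is a summary, not a bit-exact
specification of the original algorithm's interval boundaries and merge
scheduling; this implementation reproduces the contract (congruence,
determinism, wrap recovery) rather than a particular binary. Adjacent
voxel phase differences beyond $\pi$ are inherently ambiguous for any
spatial unwrapper; test fields are kept below that limit.

## Adaptive nonlinear denoising

Denoising is an explicit anisotropic (Perona–Malik style) diffusion of
the unwrapped phase,
$\varphi \leftarrow \varphi + \Delta t\,\nabla\!\cdot(g\,\nabla\varphi)$,
written in conservative face-flux form: the flux across each voxel face
uses the minimum of the two adjacent diffusivities, faces crossing the
mask boundary carry zero flux, and each update is a telescoping sum of
fluxes — so the mean phase over the mask is conserved exactly and tissue
edges block smoothing entirely.

Parameters (all in `diffusion_config()`):

* `iterations`, default 400, and `integration_constant` (the time step in
  voxel$^2$ units), default 0.18. The default step exceeds the classical
  explicit-scheme 3D stability bound of $1/6$; rather than silently
  diverge, the filter warns once and rescales any iteration whose largest
  update would exceed the total value range of the input (a
  total-variation style guard that preserves the conservation property).
  The reference pipeline reports this constant without defining whether
  it is a time step or a conductance constant; it is treated as the time
  step and left configurable.
* `diffusivity`: sigmoid $1/(1+e^{(s-\kappa)/w})$ by default (also
  exponential and inverse-quadratic), driven by the local phase gradient
  magnitude $s$. The edge scale $\kappa$ defaults to median + 2 MAD of
  the masked gradient magnitudes, re-estimated each iteration;
  $\kappa = \infty$ gives pure linear diffusion, which matches separable
  Gaussian smoothing with $\sigma = \sqrt{2\,\Delta t\,N}$ in the
  flat-field limit (a tested equivalence).
* edge classification: the cited filter differentiates noisy voxels from
  edge voxels with a geometric model that its description does not fully
  specify. Here a voxel is an edge when its relative magnitude gradient
  $|\nabla M|/M$ exceeds median + `edge_k` MAD (default 3) over the mask,
  and its faces are blocked. All constants are exposed.

A consequence worth stating plainly: on the synthetic fields used here
the *curvature of the phase is the signal*, so prolonged diffusion in a
compartment interior (where no edges stop it) biases the Laplacian — and
hence conductivity — toward zero. The filter's contract tests therefore
check noise-variance reduction, edge preservation and mean conservation,
while quantitative round-trip accuracy is assessed with denoising
disabled. On real data the bias/variance trade-off is the user's choice
via `iterations`.

## The average parabolic-fit Laplacian

For each voxel and each axis, up to `half_extent` neighbours per side are
collected walking outward, stopping at the first voxel that leaves the
mask, changes tissue label, or differs in image amplitude from the target
by more than 10% (`amplitude_tolerance`; the reference description says
"close image amplitudes" without a number, so the tolerance is a
configuration value). A least-squares parabola through the target and
each side gives two one-sided curvatures; their mean is the axis second
derivative, the sum over axes the Laplacian. Fits are computed in voxel
units and rescaled by $1/h^2$ afterwards, which keeps the $3\times3$
normal equations well conditioned at millimetre spacings.

The maximum kernel of $9 \times 9 \times 6$ voxels cannot be centred on
its even axis; it is read as the largest centred reach, one-sided depths
$(4, 4, 2)$. Whether the printed kernel is axis-ordered or
in-plane/through-plane is not stated; the extents are a configuration
vector, so either reading is available.

A voxel is *accepted* only if every axis produced at least one fit and
the aggregate Pearson correlation between fitted and measured phase
reaches 0.70. Two interpretation choices here were genuinely open:

* *Per-fit or per-voxel correlation?* The acceptance statistic aggregates
  the per-fit correlations per voxel (configurable `mean` or `min`).
* *Which fits count?* A one-sided fit through the minimum three samples
  interpolates exactly — its correlation is 1 by construction and carries
  no information about fit quality. Including such saturated fits in a
  mean would let pure noise pass the 70% gate (the two through-plane fits
  are always saturated at the default depths). The aggregate therefore
  averages only fits with residual degrees of freedom; saturated fits
  still contribute their curvature. Under this rule white-noise phase is
  rejected at a solid majority of voxels while exact quadratics are fully
  accepted, which is the behaviour the acceptance gate exists to produce.

Rejected voxels carry `NA` and are excluded from every downstream ROI
statistic — they are never interpolated.

On a noiseless 96$^3$ two-cylinder phantom the full chain (wrap, unwrap,
fit, convert) recovers the 0.540 S/m compartment mean to about 0.1% over
the interior eroded by the kernel half-widths; the residual is the
parabola's window bias on the smooth harmonic component of the phase, an
order of magnitude below the 1% acceptance band.

## Repeatability statistics

* `roi_summary()`: mean, sample SD ($n-1$) and CoV $= 100\,s/\bar\sigma$
  over valid voxels.
* `relative_error()`: $\|I_1 - I_2\|_2 / \|I_1\|_2$, scale-consistent.
* `bland_altman()`: bias and limits of agreement $\pm 1.96$ SD of paired
  differences.
* `tost_equivalence()`: the equivalence test is interpreted as a *paired*
  two-one-sided-tests procedure — the design scans the same subjects
  under both conditions, and only a paired design makes the reported
  between-arm correlation coefficient meaningful. $p$ is the larger of
  the two one-sided paired $t$ p-values, and the reported interval is the
  $(1-2\alpha)$ (i.e. 90%) CI of the mean difference with its absolutely
  larger endpoint as the headline bound.
* `tost_power()`: power under paired normals with difference SD
  $s_d = s\sqrt{2(1-\rho)}$. The primary estimator is seeded Monte-Carlo
  ($10^5$ replicates by default); an exact evaluation that integrates the
  acceptance probability over the sampling distribution of the difference
  SD is available as `method = "integration"` and agrees with the
  Monte-Carlo estimate to Monte-Carlo error. At $n=5$, $s=0.045$ S/m,
  $\rho=0.95$, margin 0.025 S/m and $\alpha=0.05$ both give 0.878. This
  quantity is sensitive to input rounding: perturbing the correlation or
  SD in their third printed digit moves the power by several points
  (e.g. $\rho = 0.949$ gives 0.866), so published power figures should be
  compared at that granularity.
* `session_anova()`: one-way repeated-measures ANOVA per comparison with
  subject (× ROI) blocks, Bonferroni-adjusted across comparisons.
  Degenerate tables (identical sessions) return $F = 0$, $p = 1$ rather
  than 0/0.

## Compressed-sensing degradation emulation

Accelerated acquisition is emulated, not reproduced: the vendor
reconstruction is proprietary, and only the qualitative behaviour —
image quality degrades as the acceleration factor grows — is claimed.
The emulator keeps a variable-density pseudorandom subset of k-space
(Gaussian density over normalized radius, width 0.25; an 8%-radius centre
always fully sampled; expected retention calibrated to $1/\mathrm{CS}$)
and reconstructs by 30 iterations of soft-thresholding in a separable
3-level Haar wavelet basis with a geometrically decaying threshold
(factor 0.7 from 5% of the largest coefficient), followed by exact
data-consistency on the sampled coefficients — so a factor of 1 is the
identity to numerical tolerance. The Haar transform is implemented
directly as orthogonal matrix products (about twenty lines); it is the
simplest orthogonal wavelet and nothing in the emulation depends on a
more sophisticated basis.

Masks drawn for the same seed are *nested* across factors: a single
uniform priority field is thresholded at different densities. Comparisons
across factors on one phantom therefore share their sampling pattern and
are not confounded by mask resampling.

At desk scale the per-voxel conductivity error after the Laplacian is a
volatile statistic: on a 48$^3$ phantom with a few-hundred-voxel common
valid mask, single-draw relative errors fluctuate by 1–2% between
adjacent factors. The monotonicity property is therefore evaluated on the
relative error averaged over four fixed simulation seeds (SNR 50, the
factor-1.3 reconstruction as reference, voxels valid in every
reconstruction), which is the claim's natural desk-scale form.

## Problem sizes and runtime choices

The test suite exercises the full chain at 96$^3$ for the noiseless
round trip, 48$^3$ for noisy and compressed-sensing runs, and 16–32$^3$
for operator-level contracts; these sizes keep the whole suite in the
minutes range on one core while leaving every numerical claim at full
strength (the forward solve is exact at any size, and fitting-bias terms
only shrink with larger phantoms). Power and coverage simulations use
$10^4$–$10^5$ replicates with fixed seeds.

## Known limitations

* The simulator's phase contains no transmit/receive asymmetry, no
  eddy-current or flow contributions, and no banding; passing round
  trips validate the numerics, not robustness to those effects.
* The transceive-phase approximation itself (its bias where $|B_1^+|$
  varies) is not modelled — the package starts from the phase.
* Heavy diffusion filtering biases conductivity toward zero in
  edge-free interiors (see above).
* The unwrapper assumes adjacent-voxel phase differences below $\pi$
  within the mask.
* At SNR 50 the per-voxel conductivity is noise-dominated without
  denoising; ROI means remain informative, single voxels do not.
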