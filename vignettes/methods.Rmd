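---
title: "Tissue-constrained wave modeling and volumetric EEG reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-constrained wave modeling and volumetric EEG reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its model, its numerical
choices, and the design decisions that were genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The wave model

In conductive dielectric tissue, retaining the displacement current in
Ampère's law while dropping magnetic induction (which is negligible in
biological tissue) turns charge continuity into a dynamical equation
for the electric potential $\phi$:

$$\partial_t \nabla^2 \phi \;=\; -\,\nabla\!\cdot\!\big(\Sigma\,\nabla\phi\big),
\qquad \Sigma = \sigma_{ij}/(\epsilon_{rel}\,\epsilon_0)\ \ [\mathrm{1/s}].$$

A linear plane-wave analysis with ansatz
$\phi \sim \exp[-i(\mathbf{k}\cdot\mathbf{x} - \Omega t)]$ gives the
complex dispersion relation implemented by `dispersion()`:

$$\gamma \equiv \Im\,\Omega = \frac{k^T \Sigma\, k}{|k|^2}, \qquad
  \omega \equiv \Re\,\Omega = -\frac{(\nabla\!\cdot\!\Sigma)\cdot k}{|k|^2}.$$

Two properties matter. First, $\gamma$ is independent of $|k|$ and set
purely by the local tissue: for average gray/white-matter conductivity
and permittivity ($\sigma \approx 2.75\!-\!2.77\times10^{-2}$ S/m,
$\epsilon_{rel} \approx 2.76\!-\!4.07\times10^{7}$), `damping_rate()`
gives $\gamma \approx 76\!-\!113\ \mathrm{s^{-1}}$ — waves in a
*homogeneous* medium with these properties are overdamped at EEG
frequencies. Second, $\omega \propto 1/|k|$: long waves oscillate
fastest, the opposite of electromagnetic dispersion, and the
oscillation exists only where the medium is *inhomogeneous*
($\nabla\!\cdot\!\Sigma \neq 0$). Weakly damped propagation therefore
lives at tissue boundaries. The idealized thin-boundary-layer
reduction (`boundary_layer_modes()`, `simulate_boundary_layer()`)
makes this extreme: the along-fiber mode obeys a damped-oscillator
equation with decay $|a|k^2$, while the cross-fiber mode obeys a pure
wave equation with $\Omega = -b/k$ exactly real — it conserves energy
and can persist indefinitely in the layer.

The electromagnetic-wavelength helper `em_wavelength()` implements the
classic estimate ($v = c/\sqrt{\epsilon_{rel}}$, $\lambda = v/\nu$,
giving 3000 km at 10 Hz and $\epsilon_{rel}=100$) that shows observed
slow brain waves cannot be electromagnetic propagation — they are the
boundary-guided modes above.

## Units: two views of the same coefficients

`property_fields()` stores the coefficients twice, deliberately:

* the *scaled* tensor $\Sigma = \sigma/(\epsilon_{rel}\epsilon_0)$ in
  1/s drives the time-domain equation, the dispersion relation and the
  damping-rate analytics;
* the *raw* pair ($\sigma$ in S/m, $\epsilon = \epsilon_{rel}\epsilon_0$
  in F/m) drives the frequency-domain operator, where the relative
  size of conduction and displacement currents is
  $\sigma/(\omega\epsilon)$ — order unity at EEG frequencies for brain
  tissue, which is exactly why the problem is dynamical. Mixing scaled
  conductivity with relative permittivity in one operator would
  misweight the permittivity-gradient term by many orders of
  magnitude; keeping the frequency-domain operator in raw units avoids
  that.

In the frequency domain ($\partial_t \to -i\omega$) the equation
becomes $(L - R)\,\phi_\omega = q_\omega$ with $L = \nabla^2$ and

$$R = P\Big[\, i\omega\,(\partial_i \epsilon)\,\partial_i
  - (\partial_i \sigma_{ij})\,\partial_j
  - (\sigma_{ij} - \bar\sigma\delta_{ij})\,\partial_i\partial_j \Big],
\qquad P = \frac{\bar\sigma + i\omega\epsilon}
                {\bar\sigma^2 + \omega^2\epsilon^2},$$

$\bar\sigma = \mathrm{Tr}\,\sigma/3$. The three bracketed terms pick
out permittivity interfaces, conductivity-gradient shells, and
anisotropy respectively; all vanish identically in a homogeneous
isotropic medium (`apply_R()` and its unit tests).

## Numerical core

Everything spatial is pseudo-spectral on a periodic voxel grid: FFT
derivatives, FFT Laplacian inversion with the zero-wavenumber
component pinned to zero (potentials are defined up to a constant; all
fields are zero-mean), and FFT Gaussian smoothing. Consequences and
guards:

* **Interface smoothing.** Spectral differentiation of discontinuous
  label-wise fields rings. Scalar property maps are Gaussian-smoothed
  *before* any tensor or gradient is formed; the default width is one
  voxel and is a configuration knob. Smoothing scalars first (rather
  than tensors later) keeps the tensor construction exactly rank-1 in
  the anisotropic case.
* **Periodic wrap-around.** The time-domain simulator multiplies the
  conductivity by a 3-voxel cosine edge taper (heads sit in a vacuum
  box; the taper suppresses flux through the periodic boundary). The
  frequency-domain solvers act on fields whose sources sit well inside
  the head, where the background's tiny conductivity floor
  ($10^{-6}$ S/m, keeping operators finite) makes wrap-around
  negligible.
* **Stability.** The RK4 stepper enforces
  $\Delta t \le 0.1/\max\Sigma$ up front and checks finiteness during
  integration; the error message names the violated bound.
* **DC bin.** Frequency 0 is excluded from every band: the prefactor
  $P$ is singular there and the mean of the potential carries no
  information.

## The forward study generator

`synthesize_study()` drives the wave equation with Gaussian source
blobs (default FWHM 3 voxels) oscillating at fixed frequencies inside
gray/white matter. Because the tissue damping rates
(76–113 s$^{-1}$ in brain, far larger in CSF under the default
placeholder permittivity) dwarf EEG frequencies, the transient from
any initial condition dies within tens of milliseconds and the driven
solution is the periodic steady state. The generator therefore solves
the steady state directly in the frequency domain — matrix-free
BiCGSTAB on the Laplacian-preconditioned operator
$(I - L^{-1}R)\phi = L^{-1}s$ — and synthesizes the 4D field from the
complex amplitude. This is not an approximation relative to explicit
time stepping; it *is* the long-time limit, and the test suite
verifies the equivalence against RK4 integration on a small non-stiff
two-tissue medium where explicit stepping is affordable. (Explicit
stepping at head scale is not: the stability guard at
$\max\Sigma \sim 2\times10^4\ \mathrm{s^{-1}}$ would force
$\Delta t \approx 5\,\mu s$ for a second-long recording.)

Sensor sampling is trilinear interpolation at world-mm electrode
positions, average-referenced by default (a named-channel reference is
supported because EEG dialects differ), with optional white noise at a
prescribed empirical SNR injected before referencing so the reference
identity holds exactly on the returned data.

## The inverse solver

`spectre()` estimates the complex volumetric potential per frequency
bin from the band-limited channel coefficients. The design was the
genuinely open part of this package, and the shipped algorithm was
chosen after quantitative rejection of simpler couplings on phantom
studies with known sources:

1. a *seed-and-scale* scheme (splat each channel coefficient at its
   electrode, invert the Laplacian, relax through $L^{-1}R$, fit one
   global complex scale) fits the sensors almost perfectly — each
   electrode's own splat reproduces its datum — but carries no depth
   information at all: band-power correlation with ground truth on
   deep-source phantoms is indistinguishable from zero;
2. an unweighted PDE-constrained minimum-norm source estimate fits the
   data exactly but shows the classic superficial bias: its power
   peaks near the scalp.

The shipped estimator keeps the physics and fixes both failures:

* **Sensitivity kernels.** For every electrode, the adjoint field
  $h_s = (L-R)^{-H} e_s$ is solved matrix-free (BiCGSTAB over the same
  FFT operators; the adjoint of each $\mathrm{diag}(c)\,\partial_i$
  term is $-\partial_i\,\mathrm{diag}(\bar c)$, exact for spectral
  derivatives). $e_s$ is the electrode's Gaussian sampling footprint
  (FWHM 2 voxels). Kernels are computed once per band at the
  band-centre frequency — within a narrow EEG band the operator's
  frequency dependence is mild — and reused for every bin.
* **Depth-weighted minimum norm on brain support.** Sources are
  restricted to gray/white-matter voxels (neural sources live there)
  and weighted by $\|g_v\|^{-2p}$ with $g_v$ the voxel's gain vector
  and $p$ the `depth` exponent. $p=0$ reproduces the superficially
  biased classic estimate; the default $p=2$ was calibrated on phantom
  studies with known deep sources, where it removes the superficial
  bias across source positions and depths. The sensor Gram matrix gets
  a relative ridge `lambda` (default $10^{-8}$; raise it for noisy
  data).
* **Physical read-out.** The returned potential is the wave-operator
  response $(L-R)^{-1} q$ of the estimated sources at each bin's own
  frequency, followed by the final complex least-squares scale over
  the sensors. Reporting the potential (not the source amplitudes)
  keeps the output on the same physical footing as the forward model
  and naturally reintroduces the tissue-boundary structure the
  operator encodes.

The whole pipeline is linear in the recording, maps zero data to a
zero potential, and degrades gracefully under sensor noise (the test
suite checks a 10 dB SNR study against the noise-free one). One
informative failure mode is worth naming: a source at the exact
geometric centre of a symmetric head produces a nearly common-mode
sensor pattern, which average referencing removes — no
reference-consistent method can recover what the reference annihilates.

## Mode decomposition

`efd()` implements a documented simplification of entropy-based mode
estimation: absolute temporal correlations between (subsampled) masked
voxel time courses form a nonnegative coupling matrix; its
eigendecomposition gives orthonormal spatial modes; the squared
leading eigenvector, normalized to unit sum, is the equilibrium
distribution $\mu^*$ of the maximum-path-entropy ensemble; mode time
courses are projections and the mode-$k$ power map is
$\psi_k^2\,\mathrm{var}(\tau_k)$. Absolute correlation is used because
path-entropy constructions need nonnegative weights; the displayed
summed map weights modes by eigenvalue (no canonical weight rule
exists, and the eigenvalue is the natural coupling strength), while
the unweighted sum over a complete basis reproduces the total masked
variance exactly — the package exposes both. The default of 10 modes
follows common practice for whole-brain summaries. Correlation
coupling is amplitude-blind: two voxels with proportional time courses
couple identically regardless of amplitude, so eigenmaps are
indicator-like over coherent regions rather than amplitude-weighted.
Degenerate coupling spectra (exactly exchangeable regions) make the
individual eigenmaps arbitrary within the degenerate subspace;
equilibrium and power summaries are unaffected.

## Phantoms and study conditions

`phantom_head()` builds nested ellipsoidal shells (scalp, skull, CSF,
gray, white) with an optional sinusoidal perturbation of the GM/WM
interface standing in for cortical folding; all randomness is the
perturbation phase, drawn from the seed. Default tissue properties:
the gray/white values quoted above; CSF 1.79 S/m, skull 0.01 S/m,
scalp 0.43 S/m with $\epsilon_{rel}=10^7$ as configurable
placeholders (no printed values exist for these tissues; they live in
the configuration, not the code); background gets the $10^{-6}$ S/m
floor. Isotropy is the default — anisotropy requires user-supplied
fiber directions and is exercised synthetically in the tests.

Problem sizes used by the test suite and reproduction script, chosen
as the smallest studies that exercise every mechanism: dispersion
fitting on a $128^2$ periodic domain (the wave packet sits at the
maximal-gradient point of a sinusoidal conductivity profile; window
and wavenumber are sized so that the packet's finite bandwidth biases
the $\omega\propto 1/k$ fit by well under the tolerance);
boundary-layer runs on 64-point lines; forward–inverse recovery on a
$48^3$, 2 mm phantom with 64 electrodes and one noiseless deep
(13 mm off-centre, white-matter) 10 Hz source, plus a $32^3$, 3 mm
replica for the faster module tests; mode decomposition on
constructed fields of tens of voxels.

## What the synthetic studies do and do not show

The phantom emulates tissue geometry, property contrasts, montage
geometry, band-limited sources and sensor noise. It does not emulate
real skull/scalp property uncertainty, electrode placement error,
artifacts (blinks, line noise), nonstationary or broadband sources, or
real cortical folding beyond a smooth sinusoidal perturbation. Passing
the recovery tests therefore demonstrates that the solver inverts its
own physics faithfully at realistic contrasts — not that any
particular clinical recording will reconstruct at the same fidelity.

## Known limitations

* Periodic boundary conditions are intrinsic to the spectral operators;
  the edge taper and the conductivity floor manage, but do not
  eliminate, wrap-around at head scale.
* The convergence of Krylov solves on $(I - L^{-1}R)$ degrades as
  property gradients sharpen; the smoothing width is the control, and
  poorly converged solves warn with their residual.
* The depth weighting exponent is a calibrated estimator parameter,
  not a law; gains are head- and montage-dependent and the default
  should be revisited for unusual montages.
* Reference-annihilated (common-mode) source configurations are
  unrecoverable in principle; see above.
* The time-domain simulator integrates the constant-permittivity form
  of the equation; permittivity gradients enter only through the
  frequency-domain operator.
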