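# spectre

Volumetric reconstruction of brain electric fields from scalp EEG,
built on a tissue-constrained wave model of brain electrodynamics.

## The problem

EEG measures the brain's electric potential at a few dozen scalp
electrodes. Under the textbook quasi-static approximation the
interior potential obeys a static Poisson equation, the inverse
problem collapses to placing equivalent dipoles, and deep activity is
considered unrecoverable. Retaining the displacement current — which
is *not* negligible in brain tissue, where the conduction and
displacement currents are comparable at EEG frequencies — turns the
potential equation into a wave equation with the tissue as its
coefficient field:

    d/dt ∇²φ = −∇·(Σ ∇φ),     Σ = σ/(ε_rel ε0)   [1/s]

Linear analysis (ansatz `exp[−i(k·x − Ωt)]`) gives the dispersion
relation

    γ = Im Ω = (kᵀΣk)/|k|²        (decay rate)
    ω = Re Ω = −(∇·Σ)·k/|k|²      (oscillation, ∝ 1/|k|)

Homogeneous tissue damps these waves at γ ≈ 76–113 s⁻¹ for average
gray/white-matter properties; weakly damped waves survive only in
thin layers at tissue boundaries, where the cross-fiber mode obeys a
pure (undamped) wave equation. Because the coefficients are the
measurable tissue properties, a segmented anatomical volume pins down
the operator, and the frequency-domain equation

    (L − R) φ_ω = q_ω,   L = ∇²,
    R = P [ iω(∂ᵢε)∂ᵢ − (∂ᵢσᵢⱼ)∂ⱼ − (σᵢⱼ − σ̄δᵢⱼ)∂ᵢ∂ⱼ ],
    P = (σ̄ + iωε)/(σ̄² + ω²ε²)

can be inverted for the full volumetric potential per frequency band.

This package provides, for R users working at simulation/phantom
scale: the head model and per-tissue bioelectric property fields, the
dispersion and boundary-layer analytics, a pseudo-spectral time-domain
simulator with wave-loop detection, a synthetic-EEG forward generator,
the frequency-domain inverse solver (`spectre()`, a classed model fit
with the usual `print`/`summary`/`coef`/`fitted`/`residuals`/
`predict`/`plot` methods), an entropy-based spatiotemporal mode
decomposition (`efd()`), and map-comparison statistics. Everything is
exercised end to end on synthetic phantoms; no external data are
needed.

## Worked example

Forward-simulate a 10 Hz source deep in the white matter of a
synthetic head, then reconstruct it from 48 scalp electrodes:

```r
library(spectre)

head_model <- phantom_head(c(32, 32, 32), voxel_size = 3, seed = 1)
props      <- property_fields(head_model)
montage    <- place_electrodes(head_model, n = 48, seed = 2)

src_pos <- voxel_to_world(head_model, c(21, 17, 17))
sources <- data.frame(x = src_pos[1], y = src_pos[2], z = src_pos[3],
                      freq = 10, amplitude = 1)
study <- synthesize_study(head_model, props, sources,
                          duration = 1, fs = 64, sensors = montage)
study$recording
#> EEG recording: 48 channels x 64 samples @ 64 Hz; average reference

fit <- spectre(study$recording, props, band = c(8, 12))
summary(fit)
#> Per-bin reconstruction summary:
#>  bin_hz alpha_mod rel_misfit solve_iter
#>       8    1.0120   0.048857         18
#>       9    0.9976   0.017973         19
#>      10    0.9835   0.007626         17
#>      11    0.9673   0.013330         16
#> kernel solve iterations: 16-18
```

`rel_misfit` is the residual of the fitted potential at the
electrodes relative to the data norm — under 5% in every bin here —
and `alpha_mod` is the final complex scale (≈1 when the source model
explains the data). Comparing the reconstruction's band-power map
with the known ground truth:

```r
power <- band_power(fit)
truth <- Mod(study$phi_hat[["10"]])^2
brain <- head_model$labels >= 4
cor(power[brain], truth[brain])
#> 0.895
arrayInd(which.max(power * brain), dim(power))
#> 22 17 17     (true source at voxel 21 17 17)
```

The deep source is localized to within one voxel and the volumetric
power pattern correlates at r = 0.9 with the truth. The tissue
analytics are one-liners:

```r
damping_rate(2.75e-2, 4.07e7)   # gray matter:  76.3 1/s
damping_rate(2.77e-2, 2.76e7)   # white matter: 113.4 1/s
em_wavelength(10, 100)$wavelength  # 3e6 m: EM waves can't be brain waves
```

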