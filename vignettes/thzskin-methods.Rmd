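---
title: "Methods: a layered deformation model for the THz response of compressed skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a layered deformation model for the THz response of compressed skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzskin)
```

## The physical picture

A reflection THz probe presses a quartz window onto skin. The skin surface
is not flat: ridges and furrows trap air between window and tissue, and only
the ridge crests initially touch the quartz. Under sustained contact force
the skin creeps — a fast elastic phase followed by a slow viscous one — the
contact area grows, trapped air is expelled, and the reflected THz pulse
loses amplitude. `thzskin` encodes this as a one-dimensional stratified
medium whose only time-varying quantity is the air volume fraction of the
topmost "ridge layer", `V_A1`.

The stack, from the incidence side down:

1. **Quartz window** — nondispersive, lossless, refractive index 1.98. By
   default it is the semi-infinite incidence medium: in window-contact
   probes the front-face echo of a 2 mm window arrives ~26 ps before the
   skin reflection and is removed by referencing, so only the quartz–skin
   interface matters. `include_quartz_layer = TRUE` keeps it as a finite
   layer instead (air incidence), for completeness.
2. **`L` ridge layers**, each of thickness `d_f` (micrometres). Layer `N`
   is a skin–air effective medium mixed by the Landau–Lifshitz–Looyenga
   cube-root rule, chosen because it imposes no inclusion-shape assumption
   — appropriate for the irregular skin/air geometry. The air fraction
   decays with depth as `V_A^N = V_A1 cos^2((N-1) pi / (2L))`.
3. **Bulk skin half-space** — by default the hydrated-skin permittivity at
   the bottom-layer hydration, so the bulk continues the profile; a
   measured bulk spectrum can be loaded instead (`bulk_spectrum`).

The skin phase itself is an effective medium of a dry biological background
(nondispersive, `eps_dry = 2.5` by default) and water, mixed by the same
cube-root rule at a volume fraction equal to the local hydration.

### Choices the source material leaves open

Three structural choices were genuinely open and are package decisions:

- **The squared-cosine argument.** A squared-cosine air profile that
  "progressively decreases" fixes neither period nor phase. We use
  `V_A1 cos^2((N-1) pi / (2L))`: layer 1 carries exactly `V_A1` (so the
  deformation knob has a direct meaning) and the profile decays over a
  quarter period, approaching but not forced to reach zero in the deepest
  layer. Forcing the bottom layer to zero would make `L` and the profile
  shape interact; this form keeps `V_A1` the single knob.
- **Hydration interpolant.** Hydration rises from 0.20 at the surface to
  0.65 at the bottom of the deepest layer, evaluated at each layer's centre
  depth `(N - 1/2) d_f`. The default interpolant is piecewise linear; a
  half-cosine ramp (`hydration_method = "cosine"`) is provided because the
  true curve shape between the endpoints is not tabulated anywhere we can
  cite, and the two bracket plausible smooth profiles.
- **Water dielectrics.** No specific water parameter set is mandated, so
  the default is a standard room-temperature double-Debye fit
  (`eps_inf = 3.5`, relaxation strengths 73.5 and 1.4, times 8.24 ps and
  0.18 ps). It is a configurable `debye_model`, not an assertion about any
  particular instrument's tissue data.

## Conventions and numerics

- **Sign convention.** Fields go as `e^{-i w t}`; passive permittivities
  have `Im(eps) >= 0`, complex refractive indices `Im(n) >= 0`, and a layer
  contributes a round-trip factor `e^{+2 i delta}` with phase thickness
  `delta = (2 pi / lambda) n d cos(theta)`. This is the convention in which
  the recursive Fresnel relation is written here, and it is enforced by the
  `material_spectrum` constructor (a tiny negative imaginary part from
  round-off, above `-1e-12`, is clipped).
- **Phase-thickness indexing.** The phase factor stepping across interface
  `i` uses the properties of layer `i+1` — the layer actually being
  traversed — with its own complex index and internal angle. This is the
  standard recursion and reduces correctly in all limits (zero-thickness
  layers are exact no-ops; two half-spaces give the closed-form
  coefficient).
- **Branch choices.** The normal wavevector component
  `q = sqrt(eps - eps_in sin^2 theta)` takes the branch `Im(q) >= 0`
  (decay into lossy media); the complex cube root in the mixing rule is the
  principal branch, which keeps passive inputs passive.
- **Polarization.** Default normal incidence, where polarization is
  irrelevant; for oblique work both `"s"` and `"p"` are supported, with
  `p` expressed in the admittance convention (`eta_p = eps/q`) so the two
  coincide exactly at normal incidence.
- **Oracle.** `transfer_matrix_reflectance()` re-derives the same quantity
  through 2x2 characteristic-matrix products and exists only as an
  independent cross-check; the test suite holds the two to 1e-10 on random
  lossy stacks of up to 30 layers.
- **FFT conventions.** Spectra use `S(f) = integral x(t) e^{+2 pi i f t} dt`
  (consistent with `e^{-iwt}`), sampled at the non-negative FFT bins after
  zero-padding to a power of two (default: the next power of two; no
  window function and no spectral filtering anywhere). Deconvolution masks
  bins where the reference magnitude falls below 1% of its peak rather
  than dividing through noise.
- **Alignment.** Before any pointwise pulse comparison the simulated pulse
  is shifted by the integer lag maximising its cross-correlation with the
  measured one (zero-filled, not circular). The loss is therefore invariant
  to a common time shift of both signals.
- **Loss.** `sum_t (E_sim - E_meas)^2`, the squared L2 norm of the signal
  difference. A squared-signal variant `sum_t (E_sim^2 - E_meas^2)^2` is
  available behind `loss_type = "squared_signal"` for sensitivity checks;
  it is not the default because squaring discards sign information and
  doubles the effective noise exponent.

## The optimiser

The fit minimises a smooth 1-D loss within box bounds, using Bayesian
optimisation with a Gaussian-process surrogate (squared-exponential kernel,
lengthscale re-selected each iteration by marginal likelihood over a small
candidate set, nugget 1e-8) and expected improvement maximised on a dense
grid. Defaults: 10 space-filling initial points, 40 iterations. All
randomness is derived from the control seed, so identical calls give
identical fits. Duplicate proposals are deflected to the largest gap; if
the surrogate degenerates (zero variance in the observations) the best
point so far is returned with a flag.

Two-stage fitting:

1. **Ridge-layer thickness.** `d_f` is optimised within [2, 10] um with
   `V_A1` fixed at 0.5. That constraint is only consistent with a pulse
   whose true deformation state is near 0.5, and which pulse that is cannot
   be known in advance — so the optimisation is run on a subset of
   stride-selected pulses (default 32 candidates) and the (pulse, `d_f`)
   pair with the lowest achieved loss wins. On synthetic data whose
   trajectory crosses 0.5 this removes the bias that fitting an arbitrary
   single pulse would introduce.
2. **Deformation trajectory.** `V_A1` is fitted within [0, 1] at every
   10th pulse (configurable stride), warm-starting each search at the
   previous optimum because the trajectory varies slowly; the first search
   starts from the centre of the bounds. The per-pulse root-mean-square
   error is recorded alongside each estimate.

The 101-point loss surface (`loss_surface()`) is the identifiability
diagnostic: for synthetic pulses it is unimodal with the minimum at the
generating value, and the minimum location moves monotonically with the
generating deformation.

## Choosing the number of ridge layers

`build_error_matrix()` simulates the signal over a grid of `V_A1` values
(default 10 spanning [0, 1]) and layer counts (default 1–15) at fixed total
ridge height `d`, scoring each combination by the squared-L2 error against
one measured pulse. The robustness metric per layer count combines the mean
and standard deviation of the error across `V_A1`:
`metric(L) = mean_L / max(mean) + sd_L / max(sd)` — the exact normalisation
is not prescribed anywhere, so we max-normalise both terms to make them
scale-free and equally weighted, with the weight exposed as an argument.
Layer counts within 5% of the minimum metric form the acceptable set; the
selected `L` is the smallest count present in every acceptable set across
the swept heights (default 15, 30, 45, 60 um), and an empty intersection
raises an explicit no-consensus error carrying the per-height sets.

Which pulse serves as "the measured signal" here is also unprescribed; the
command-line tool defaults to the middle pulse of the series, mid-way
through the deformation. In the synthetic recovery experiment the sweep
uses heights of 30 um and above: the generating height is 30 um, and
including a height far below it makes every candidate geometry inconsistent
with the data, which correctly triggers the no-consensus error rather than
a wrong answer (both behaviours are tested).

## What the synthetic generator emulates — and what it does not

`occlusion_scenario()` + `generate_series()` emulate a 90 s single-point
contact measurement at 12 pulses per second (1080 pulses). The deformation
trajectory is `va1_end + (va1_start - va1_end) e^{-tau/decay} - slope*tau`,
clipped to [0, 1]: an elastic exponential phase (default time constant
10 s) and an optional viscous linear phase. The default endpoints
0.57 → 0.38 make the synthetic study commensurate with a typical in vivo
volar-forearm measurement; the default linear slope is zero so that the
90 s trajectory spans exactly those endpoints (the exponential tail is
already quasi-linear; a nonzero slope is exercised in tests).

Noise is additive white Gaussian on the time-domain amplitude, default
standard deviation 0.002 mV against a unit-peak (1 mV) reference — peak
SNR 500, the order achieved by fibre-coupled time-domain spectrometers at
~12 Hz acquisition. The generator does **not** emulate baseline wander,
delay-line drift, system dispersion beyond the reference-pulse shape,
lateral inhomogeneity, or surface-roughness scattering. Passing recovery
tests therefore demonstrate correctness of the inference machinery under
the model's own assumptions, not robustness to every artefact of real
measurements; with real data the alignment step and the deconvolution mask
do some of that work, but drift in particular is uncorrected by design (no
filtering).

Problem sizes used throughout the validation suite are the defaults above:
512-sample references (25.6 ps records), full 1080-pulse series fitted at
every 10th pulse, 100-stack oracle comparisons. These run the entire suite
in about a minute on one core.

## Known limitations

- The model is strictly 1-D stratified: no lateral ridge geometry, no
  incoherent or partially coherent summation, no roughness-scattering
  correction beyond the effective-medium treatment.
- A single effective water component: no bound/free water distinction and
  no temperature dependence.
- Because a ridge stack of at most ~120 um (12 layers at the 10 um bound)
  is optically thin below 0.5 THz, the model's reflectance change under a
  deformation step grows with frequency over the 0.2–1.5 THz band and
  peaks near 0.7–1 THz; the change at the low end of the band is
  intrinsically suppressed (it vanishes as f → 0). Reports that low
  frequencies attenuate *more* than high frequencies during occlusion are
  consequently outside what this forward model can produce at such
  geometries — the corresponding check in the acceptance suite documents
  this as an expected failure. Only total ridge heights of ~200 um or more
  invert the ordering.
- `V_A1` and `d_f` are partially confounded (both scale the trapped-air
  optical mass); the two-stage fit resolves this by fixing `d_f` once, and
  the candidate-pulse selection above keeps that stage unbiased. Joint
  per-pulse fitting of both is deliberately not offered.
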