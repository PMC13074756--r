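---
title: "Spectral BRDF versus diffuse leaf optics in canopy light transport: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral BRDF versus diffuse leaf optics in canopy light transport: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`canopytrace` asks a concrete modelling question: when does it matter that
leaves reflect light *directionally* rather than diffusely?  Most
functional–structural plant models treat the leaf surface as Lambertian,
even though measured leaf reflectance has a pronounced specular lobe in
the blue and red wavelength ranges.  The package simulates spectrally
resolved light transport in virtual cucumber-like canopies twice — once
with a fitted Phong BRDF per wavelength bin and leaf side, once with the
spectrally equivalent diffuse reflectance — and quantifies the difference
in (a) per-leaf absorbed photon flux and (b) the spectral photon flux
density measured by small virtual sensors near the leaf surfaces.

This vignette documents the models, the numerical choices, and the design
decisions that were genuinely open.

## The leaf BRDF model

Each leaf side (adaxial/abaxial) in each 10 nm spectral bin carries an
energy-normalized modified Phong BRDF

$$f(\omega_i, \omega_o) \;=\; \frac{k_d}{\pi} \;+\;
  k_s\,\frac{n+2}{2\pi}\,\max(0, \cos\alpha)^n,$$

where $\alpha$ is the angle between the outgoing direction and the mirror
direction of the incident one, $k_d$ is the hemispherical albedo of the
diffuse term, $k_s$ the specular lobe weight and $n$ the shininess.  This
form is reciprocal, and at normal incidence its
directional–hemispherical reflectance (DHR) is exactly $k_d + k_s$.  At
oblique incidence part of the lobe dips below the horizon, so

$$\mathrm{DHR}(\theta_i) = k_d + k_s\,A(n, \theta_i),$$

with $A \le 1$ the above-horizon, cosine-projected energy fraction of the
lobe.  `lobe_albedo()` evaluates $A$ by fixed-order quadrature in the
lobe frame: substituting $v = \cos^{n+1}\alpha$ concentrates the
Gauss–Legendre nodes inside the lobe, so one order (64 × 128 azimuth
nodes) resolves shininess values from 0.5 to 500; the test suite checks
it against Monte-Carlo integration.  Transmission is diffuse
(Lambertian on the exit side) with a per-bin transmittance $\tau$, which
follows the leaf-optics literature: transmitted light exits the diffusing
mesophyll, not the cuticle.  There is no specular transmission.

Energy closure is enforced as a type invariant: DHR$(\theta_i) + \tau
\le 1.01$ for $\theta_i \le 40^\circ$ and $\le 1.06$ up to $85^\circ$ —
the looser grazing-angle band reflects the known mild non-conservation
of fitted Phong parameter sets at grazing incidence.

### Fitting and the diffuse equivalent

`fit_phong()` fits $(k_d, k_s, n)$ per bin/side to
gonioreflectometer-style samples by bounded multi-start least squares
(five log-spaced shininess starts; the $n$ landscape is multimodal),
under the *hard* anchor constraint $\mathrm{DHR}(40^\circ) = \rho_{\rm
ref}$, the hemispherical reflectance at the calibration incidence.  The
constraint is eliminated analytically — $k_s = s\,\rho_{\rm
ref}/A(n,40^\circ)$, $k_d = \rho_{\rm ref}(1-s)$ with $s \in [0,
s_{\max}(n)]$ — so every candidate satisfies it exactly and the
Lambertian model is the nested member $s = 0$.  That nesting guarantees
NRMSE(Phong) ≤ NRMSE(diffuse) on every bin, which the tests assert.
NRMSE is RMSE divided by the mean measured BRDF of the bin (the
normalizer is a design choice; mean-normalization is scale-free and
stable when specular peaks are sparse in the angle grid).

`diffuse_equivalent()` maps a Phong table to the Lambertian reflectance
with identical hemispherical behavior at the same anchor:
$\rho = \mathrm{DHR}(40^\circ)$, $\tau$ unchanged.  All Phong-vs-diffuse
comparisons in the package are against this equivalent, so any
difference is attributable to *directionality*, not to total albedo.

## Photon transport

The tracer (compiled, BVH-accelerated) emits rays from oriented disks
circumscribing the scene, one disk per active light source, with power
proportional to the source's horizontal irradiance.  Transport is
*analog and per-bin*: each ray carries the emitted power of one spectral
bin, drawn from the D65 photon spectrum, and interaction events
(diffuse reflection $k_d$, specular reflection $k_s A(n,\theta_i)$,
transmission $\tau$, absorption = remainder) are sampled from the exact
per-bin probabilities.  Specular directions are drawn from the
$\cos^n$ lobe with rejection on the outgoing cosine, restricted above
the horizon, which makes the Monte-Carlo reflected fraction agree with
the quadrature DHR by construction; below-horizon lobe energy counts as
absorbed.  Because every ray's weight ends in exactly one bucket, the
per-bin ledger *emitted = leaf + stem + ground + escaped + truncated*
closes to floating precision on every run — an invariant the tests
check on all scattering modes.

The alternative design — rays carrying all 30 bins with weight-correction
splitting at each interaction — was considered and rejected: the
per-bin weight corrections break exact ledger closure (it then holds
only in expectation) and couple the bins' variance.  Since all reported
quantities are band or total aggregates, the per-bin ray cost is
recovered by the fact that every ray contributes to its band; only
per-bin tallies at fixed total rays are noisier.

Paired runs use common random numbers: a run's ray stream is a pure
function of `(seed, ray index)`, so Phong vs diffuse (or full vs
restricted scattering) runs with the same seed share emission geometry,
bin assignment and event draws until their physics first diverges.  This
cancels most Monte-Carlo variance from the *differences*, which is what
the study's statistics are built on.

### Scattering modes and the indirect-light proportion

The indirect-light proportion of a tally is
$\eta = 1 - E_{\rm baseline}/E_{\rm full}$.  What the baseline run
suppresses decides what $\eta$ means, and the package exposes three
restricted modes:

* `"single_reflection"` — at most one reflection per path, diffuse
  transmission unrestricted.  $\eta$ then isolates the **multiply
  reflected** contribution.  This is the definition used by the
  pipeline and the acceptance analysis: in a leaf-area-index-4.6 canopy
  it yields central-plant leaf-order means peaking near 2–3% at the
  lower leaf orders, decreasing upward and increasing with the direct
  fraction.
* `"no_reflection"` — all reflection suppressed, transmission kept;
  $\eta$ counts any path containing a reflection (5–10% in the same
  canopy).
* `"none"` — paths end at the first surface interaction; $\eta$ counts
  *all* scattered light.  In a dense canopy the shaded lower leaves
  receive mostly scattered light, so this definition saturates (15–50%)
  and is useful only for open scenes or sensor diagnostics.

The choice matters by an order of magnitude, which is why it is a
documented mode rather than a hidden convention.  The multiple-reflection
reading is the one consistent with a low-single-digit percentage η in a
dense canopy; the implementation of all three was validated against a
closed-form five-layer radiosity stack (per-layer η matches to
Monte-Carlo noise).

### Sensors

Each leaf carries three reference points per side — the lamina's area
centroid and the midrib points at 1/3 and 2/3 arclength — offset 5 mm
along the local normal.  A sensor is a passive disk (default radius
2.5 mm) that accumulates the weight of rays crossing from its facing
side divided by its area; it never occludes or scatters anything.  The
default radius keeps the disk small relative to any leaf; property
tests that need low-variance sensor tallies at desk-scale ray budgets
use 20 mm disks instead, trading spatial resolution for counting
statistics (both are parameters, not constants).

## Synthetic plants and canopies

No measured plant scans or BRDF tables are distributed, so the package
generates both.  `generate_plant()` builds five-leaf cucumber-like
plants: cordate-outline laminae swept over curved (drooping) midribs on
a faceted stem cylinder.  Defaults encode the study conditions: mean
height 0.212 m (sd 0.03 m), per-plant one-sided leaf area 0.185 m² so a
3×3 grid at 0.2 m spacing has LAI $= 9 \times 0.185 / (9 \times 0.04) =
4.625$ in expectation, leaf areas rising from order 1 to 4 with the
youngest leaf smallest, and a 144° phyllotaxis with seeded jitter
(a generic dicot spiral; no angles are prescribed by the study).
Inclination/droop defaults were set once to a plausible cucumber habit;
adjacent leaf orders overlap in vertical projection, which is what makes
inter-leaf shading and reflection non-trivial.

What the generator does *not* emulate: real scanned geometry (petioles,
lobed margins, rugosity), biological variance beyond independent
per-plant jitter, and any correlation between leaf optics and leaf
order (one optics table per side is shared by all leaves).  Passing
tests therefore demonstrate correct transport and statistics on
*plausible* canopies, not agreement with any particular measured plant.

The packaged optics fixture (`fixture_optics()`) encodes the spectral
physiology of a green leaf: strong pigment absorption in blue and red
(DHR+τ ≈ 0.10), weak absorption in green (≈ 0.35, at the low end of the
plausible range for a thin leaf) and very weak absorption beyond the red
edge (≈ 0.85, the highest), with the specular *fraction*
$k_s/(k_d+k_s)$ largest in blue and red because the diffuse, subsurface
component is what pigment absorption removes.  Stems reflect a broadband
0.18 and do not transmit.  These curves are synthetic stand-ins shaped
like cucumber leaf optics, not measurements; the packaged CSV copies
under `inst/extdata/` carry a `synthetic_` prefix for the same reason
(`synthetic_cucumber_optics.csv` is the full Phong table;
`synthetic_gonio_samples.csv` / `synthetic_gonio_rho_ref.csv` are a
noisy four-bin gonioreflectometer-style sample set for exercising the
fitting interface and the CLI).

## Lighting

The diffuse sky is a uniform-radiance hemisphere discretized into 9
altitude × 12 azimuth = 108 directed sources at segment centers; ring
weights are the closed-form cosine-projected annulus integrals
$(\sin^2 h_1 - \sin^2 h_0)/2$, shared equally within a ring, so the
horizontal irradiances sum to $E_{\rm diffuse}$ exactly.  A single
directed source represents the sun.  The scenario sweep crosses direct
fraction 0.1–1.0 (step 0.1), four sun azimuths and nine altitudes — 360
scenarios — under constant global horizontal irradiance
$E_{\rm global} = E_{\rm diffuse} + E_{\rm direct} = 1000\,\mu\mathrm{mol\,
m^{-2}\,s^{-1}}$ (any constant works; every reported statistic is
scale-free).  The pure-diffuse case is a separate baseline, not one of
the 360 (a sun direction would be meaningless there).  Both components
share the D65 photon spectrum: the relative spectral power of the
standard daylight illuminant times $\lambda$ (photon energy
$hc/\lambda$), integrated per 10 nm bin at 1 nm resolution from the
embedded 5 nm CIE table.  Under this weighting the green band carries
≈ 34.5% of the photons — the analytic anchor behind the green-dominance
result.

## Statistics

* **MAPE** between paired Phong and diffuse tallies:
  $100/n \sum |\phi_{\rm phong} - \phi_{\rm diffuse}| / \phi_{\rm
  diffuse}$ per group; zero-denominator records are dropped with a
  logged count.
* **η** as above, reported per leaf and per sensor from seed-shared runs.
* **Band shares** of sensor flux; record groups with zero total flux
  (a fully shaded sensor) are undefined and dropped with a count.  At
  desk-scale budgets the per-scenario share is computed on flux pooled
  over sensors — the mean-of-ratios estimator the full-scale study uses
  needs per-sensor counting statistics that only billions of rays
  provide.
* **Quantiles** are type-7 (linear interpolation), the common default;
  the study's tables report Q25/Q50/Q90.
* **Paired t-tests** via the standard statistic with df = n−1;
  p-values are compared only as bounds in tests, since exact t values
  depend on the particular random canopy.

## Problem sizes and numerical defaults

Reference simulations in the original study design use $2 \times 10^9$
rays per run and reflection depth 50.  The package's default desk-scale
budget is $2 \times 10^6$ rays per replicate, three replicates, depth 50,
and a stratified scenario subset (all ten direct fractions at azimuth 0°,
altitudes 10/50/90°, plus the pure-diffuse baseline) — sizes chosen so a
full paired study of one arrangement completes in minutes on one core
while keeping the Monte-Carlo standard errors of the headline statistics
about an order of magnitude below the effects they measure.  Tally
standard errors are carried along (replicate spread), so every reported
mean has an uncertainty.  Depth-50 truncation is tallied explicitly
rather than rouletted, keeping the ledger exact; with leaf albedos below
0.9, path lengths are absorption-limited long before the cap.

Other numerical choices: Gauss–Legendre order 64 × 128 azimuth nodes for
hemispherical integrals (relative error below $10^{-6}$ over the tested
shininess range); ray–surface offsets of $10^{-7}$ m; Möller–Trumbore
intersection with two-sided faces; the struck leaf side is decided by
the face orientation against the incoming ray.  Degenerate triangles
(area below $10^{-12}$ m²) are dropped at mesh build time.

## Known limitations

* The Phong lobe is an empirical model; microfacet BRDFs would
  extrapolate better far from the 40° calibration angle.
* One optics table per leaf side — no per-leaf-order or intra-leaf
  variation.
* The sky is isotropic; no circumsolar brightening or spectral
  sun/sky difference.
* Sensor-level per-sensor MAPE at desk-scale ray budgets is noise
  dominated for weakly lit (abaxial, blue) sensors; the package's
  sensor-level statistics therefore pool flux over sensors, and the
  trend checks are formulated against Monte-Carlo error bars.
* The η definition depends on what the baseline run suppresses (see
  above); results quoting η must state the mode.
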