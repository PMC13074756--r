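# canopytrace

Spectrally resolved Monte-Carlo light transport in virtual plant
canopies, built to answer one question: **when does direction-dependent
(BRDF) leaf reflectance matter in canopy light simulations, and when is
the common diffuse (Lambertian) approximation good enough?**

Functional–structural plant models almost always assume leaves scatter
light diffusely, yet measured leaf reflectance carries a clear specular
lobe — strongest in the blue and red wavelength ranges, where pigment
absorption suppresses the diffuse, subsurface component.  `canopytrace`
simulates virtual cucumber-like canopies twice under identical light and
identical hemispherical albedo — once with a per-wavelength modified-Phong
BRDF, once with its spectrally equivalent diffuse reflectance — and
quantifies the difference in per-leaf absorbed photon flux and in the
spectral photon flux density at small virtual sensors 5 mm from the leaf
surfaces.

## The models in brief

* **Leaf BRDF** per 10 nm bin (440–740 nm) and leaf side:
  `f = kd/π + ks (n+2)/(2π) cosⁿα`, with `α` the angle to the mirror
  direction.  `DHR(θᵢ) = kd + ks·A(n, θᵢ)`, where `A` is the
  above-horizon energy fraction of the lobe (computed by quadrature).
  Diffuse transmission `τ` per bin; energy closure `DHR + τ ≤ 1` is a
  type invariant.
* **Fitting**: `fit_phong()` fits `(kd, ks, n)` per bin to
  gonioreflectometer-style samples by constrained multi-start least
  squares, holding `DHR(40°)` equal to the measured hemispherical
  reflectance; the diffuse model is the nested `ks = 0` member, so its
  NRMSE is never smaller.
* **Diffuse equivalent**: `diffuse_equivalent()` sets `ρ = DHR(40°)`,
  `τ` unchanged — comparisons isolate directionality, not albedo.
* **Lighting**: a 108-source uniform-radiance sky hemisphere
  (9 altitude × 12 azimuth segments) plus a directed sun;
  360 scenarios crossing direct fraction 0.1–1.0, four azimuths and nine
  altitudes at constant global irradiance (D65 photon spectrum).
* **Transport**: compiled BVH forward tracer; analog per-bin photon
  packets; exact per-bin energy ledger
  (emitted = leaf + stem + ground + escaped + truncated) on every run;
  common random numbers across paired runs.
* **Statistics**: indirect-light proportion `η = 1 − E_baseline/E_full`
  (the baseline permits at most one reflection, so η isolates multiple
  reflections), MAPE between paired Phong/diffuse tallies, band shares,
  Q25/Q50/Q90, paired t-tests.

Synthetic five-leaf plants (cordate laminae over curved midribs; mean
height 0.212 m, per-plant leaf area 0.185 m², LAI 4.625 at 0.2 m grid
spacing) and a packaged cucumber-like optics table stand in for measured
scans, so the whole pipeline runs reproducibly without external data.

## Worked example

```r
library(canopytrace)

fx <- fixture_optics()            # Phong + diffuse-equivalent leaf optics
set.seed(42)
canopy <- assemble_canopy("grid3x3", spacing = 0.2)
lai(canopy)
#> [1] 4.606563

index   <- build_index(canopy)
sensors <- sensor_nodes(canopy)
scen <- scenario_subset(scenario_sweep(), q_direct = 0.7,
                        azimuth = 0, altitude = 50)

phong   <- trace(index, scen, fx$phong,   n_rays = 2e6, sensors = sensors, seed = 1)
diffuse <- trace(index, scen, fx$diffuse, n_rays = 2e6, sensors = sensors, seed = 1)

pairs <- pair_tallies(phong, diffuse) |>
  dplyr::group_by(plant, leaf_order) |>
  dplyr::summarise(phong = sum(phong), diffuse = sum(diffuse), .groups = "drop")
mape(pairs)
#> # A tibble: 1 × 3
#>    mape     n n_dropped
#>   <dbl> <int>     <int>
#> 1 0.318    45         0

band_fraction(phong$sensors, value = "ppfd")
#> # A tibble: 4 × 3
#>   band     value share
#>   <fct>    <dbl> <dbl>
#> 1 blue    10320. 0.183
#> 2 green   19053. 0.338
#> 3 red     18127. 0.321
#> 4 far_red  8931. 0.158
```

The MAPE row says the Phong and diffuse models disagree by only ~0.3% in
spectrum-integrated absorbed flux per leaf (45 leaves, no dropped
records) — directionality barely matters for light interception.  The
band shares show green carrying ~34% of the sensor photon flux under
majority-direct D65 light, with far-red enriched above its 12.5%
illuminant share by scattered light inside the canopy.

A full paired study (arrangements × scenario subset × {Phong, diffuse} ×
{full, single-reflection} × 3 replicates) runs with `run_study()`:

```r
bundle <- run_study(run_config(seed = 1, arrangements = "grid3x3"))
report(bundle)
```

`autoplot()` methods exist for optics tables, fits and tally results;
`plot_mape()` and `plot_radiant_intensity()` reproduce the study's
figure types.  A thin CLI wrapper with `fit-brdf`, `gen-canopy`,
`gen-fixture`, `run` and `report` subcommands lives in
`inst/cli/canopytrace.R`.

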