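---
title: "Methods: comparing Southern Ocean NPP trends across platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing Southern Ocean NPP trends across platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonpp)
```

## The scientific problem

Net primary production (NPP) in the Southern Ocean — defined here, as is
common, as everything south of 40°S — feeds regional ecosystems and primes
the biological carbon pump. Three observing/modelling platforms give three
views of how it is changing: satellite ocean-colour algorithms applied to
merged reflectance records, biogeochemical Argo floats measuring
fluorescence, backscattering and light in the water column, and CMIP6-class
Earth System Models (ESMs) projecting the future under emissions scenarios.
The platforms disagree about the sign and size of the trend, so a pipeline
that treats all three consistently — same region, same trend machinery, same
integration conventions — is a prerequisite for saying anything about the
disagreement. `sonpp` implements that pipeline, together with a synthetic
data generator that produces every input class with known ground truth, so
the entire analysis is testable offline with recovery experiments.

## Satellite NPP algorithms

Six algorithms from three families are implemented, all taking a
`surface_pixel()` (chlorophyll, backscattering, absorption, attenuation,
PAR, SST, MLD, nitracline depth, salinity, position, date).

**VGPM family** (chlorophyll × temperature): the vertically generalised
production model

$$\mathrm{NPP} = s \cdot P^B_{opt}(T)\,\frac{E_0}{E_0 + E_{sat}}\,
\mathrm{Chl}\,Z_{eu}\,D$$

with scale $s = 0.66125$, light-saturation constant $E_{sat} = 4.1$ mol
photons m⁻² day⁻¹ and photoperiod $D$ from the geometric sunrise
hour-angle formula. $P^B_{opt}$ is either the 7th-order polynomial in SST
with its −1 °C/28.5 °C clamps (`"behrenfeld"`) or the exponential
$1.54 \cdot 10^{0.0275T - 0.07}$ (`"eppley"`). The euphotic depth $Z_{eu}$
comes from the Morel case-I relation between surface and column-integrated
chlorophyll, with its branch switch at 102 m.

**CbPM family** (carbon × growth rate): phytoplankton carbon from
backscattering, $C_{phyto} = 13000\,(b_{bp} - 0.00035)$, the
photoacclimation state $\theta = \mathrm{Chl}/C_{phyto}$, and a growth law

$$\mu = \mu_{max}\,
\mathrm{clamp}\!\left(\frac{\theta - \theta_{min}}
{\theta_{max}(I_g) - \theta_{min}}, 0, 1\right)
\left(1 - e^{-k_I I_g}\right),\qquad
\theta_{max}(I_g) = \theta_{lo} + (\theta_{hi} - \theta_{lo})e^{-k_\theta I_g}$$

driven by the median mixed-layer light
$I_g = (E_0/D)\,e^{-K_{d}\,\mathrm{MLD}/2}$. The surface form reports
$\mu\,C_{phyto}\,Z_{eu}$; the depth-resolved form applies the same law at
every depth with local PAR and local $\theta(z)$ and integrates
trapezoidally to 200 m. For satellite input the vertical structure is
reconstructed: uniform properties in the mixed layer, $\theta$ relaxing
linearly in optical depth towards $\theta_{max}(E(z))$ below the deeper of
the mixed layer and the nitracline (nutrient control switches the
relaxation off above the nitracline), and $C_{phyto}$ held to $Z_{eu}$ then
attenuated with a 100 m e-folding.

**Absorption family** (absorbed photons × quantum yield): absorbed flux
$AQ(z) = a_{ph} E_0 e^{-K_d z}$, spectrally integrated, converted to carbon
with an irradiance-dependent quantum yield and summed over depth,
$\mathrm{NPP} = 12\,\mathrm{g\,mol^{-1}} \sum_z \phi(E(z))\,AQ(z)\,\Delta z$.
The AbPM form uses $\phi = \phi_{max} E_k/(E_k + E)$; the CAFE form
$\phi = \phi_{max}(E_k/E)(1 - e^{-E/E_k})$ with $E_k$ acclimated to the
daily-equivalent median mixed-layer light. Both are bounded by the analytic
limit $12\,\phi_{max}\,a_{ph}\,E_0/K_d$, which the tests verify to 0.5 % at
1 m quadrature.

Treating attenuation with a single $K_d(490)$ rather than per-wavelength
radiative transfer is a deliberate simplification: the synthetic inputs
carry only $K_d(490)$ and the comparison operates at algorithm-family
level. All constants live in `npp_coefficients()` and are serialized with
results, so output is reproducible bit-for-bit from the coefficient set.
Which wavelength the backscattering input refers to is configurable;
`bbp_spectral()` converts with the $(\lambda/\lambda_0)^{-\eta}$ power law
either way.

## The float processing chain

The chain runs in a fixed, audited order: QC selection → vertical
regridding → (fluorescence: quenching correction → factor-2 slope →
despiking) and (backscatter: cleaning → despiking → carbon conversion) →
mixed-layer depth → NPP inputs.

* **QC**: only samples flagged 1, 2, 5 or 8 survive; profiles left without
  valid samples are dropped with a logged reason.
* **Regridding**: monotone (shape-preserving) piecewise-cubic Hermite
  interpolation onto a standard grid of 1 m steps to 300 m and 10 m steps
  to 1000 m, with *no extrapolation* — grid nodes outside the sampled range
  stay missing, and every later step preserves missingness (the despiking
  filter does not fill gaps).
* **Quenching**: daytime non-photochemical quenching suppresses surface
  fluorescence; the correction locates the fluorescence maximum inside the
  mixed layer and extrapolates it to the surface (the mixed-layer-maximum
  rule). Night profiles, classified by solar elevation at the profile time
  and position, pass unchanged. The factor-2 calibration slope is applied
  after the quenching correction; the order is a package decision since the
  chain's published descriptions list the steps without fixing it.
* **Backscatter**: negatives are masked; profiles are rejected as noisy
  when their median absolute successive difference exceeds 5× the
  profile-set median, or as anomalously deep when the median below 700 m
  exceeds 3× the set's deep median. These multiples are package defaults,
  not literature values, and are configurable. The non-algal baseline is
  the per-profile 850–1000 m median (deep backscattering being
  overwhelmingly non-algal), floored at zero; the residual is translated to
  470 nm with spectral slope magnitude 0.78 and converted to carbon with
  the slope factor 12128 (no intercept, matching the slope-only
  convention).
* **Despiking**: 11-point running median, window truncated at the edges.
* **MLD**: shallowest depth where potential density exceeds the 10 m
  reference value by 0.03 kg m⁻³. Density comes from a documented linear
  equation of state ($\rho_0 = 1025$, $\alpha = 2\times10^{-4}$ K⁻¹,
  $\beta = 7.6\times10^{-4}$); a full thermodynamic equation of state can
  be injected through the `eos` argument where higher fidelity is needed.
  The 10 m reference is a package decision; only the 0.03 criterion is
  fixed by convention.

Float NPP uses the measured profiles directly: the depth-resolved CbPM with
local PAR and Chl:C, and a volumetric reading of the VGPM
($npp(z) = s\,P^B_{opt}(T(z))\,\mathrm{Chl}(z)\,D\,E(z)/(E(z)+E_{sat})$),
both integrated over the top 200 m. The volumetric VGPM reading is marked
by an explicit mode flag since a layer-wise reading is also defensible.

## Trend machinery

Per-pixel trends follow a routed procedure. Series with less than 50 % of
the nominal time axis present get no trend. Series passing the
D'Agostino-Pearson omnibus normality test (α = 0.05; the test is only
attempted at n ≥ 20, below which its small-sample behaviour is unreliable
and the series routes nonparametrically) get a Huber regression with
ε = 1.35; samples whose final robust weight falls below 1 count as
outliers, and more than 50 % outliers suppresses the trend. All other
series get the Mann-Kendall test with the Theil-Sen (median-of-pairwise)
slope. Both engines are verified against brute-force all-pairs oracles and
frozen reference statistics from an independent implementation.

The default input cadence for pixel trends is calendar-year annual means
(deseasonalised by construction); an 8-day anomaly mode is available. No
significance mask is applied to trend maps — p-values are carried in the
output instead. Pixel areas are spherical,
$A = R^2 \Delta\lambda(\sin\varphi_2 - \sin\varphi_1)$; the 1° grid south
of 40°S sums to the analytic spherical cap within 0.1 %, and regional
totals convert as $\sum v\,A \times 365$ into Pg C yr⁻¹ (1 Pg = 10⁶ Gg;
`convert_trend_units()` moves between the Pg- and Gg-scale conventions).
Trend uncertainty uses a moving-window jackknife: every contiguous 20-year
sub-window of the annual regional series is refit with the same routed
estimator (internal consistency with the pixel procedure), and the mean ±
sd of window slopes is reported. Float trends are ordinary least squares on
calendar-year annual means south of 40°S, skipping empty years.

## ESM processing

Model members carry monthly depth-integrated NPP (`intpp`, mol C m⁻²
day⁻¹, with automatic 86 400× conversion when the declared unit is per
second), phytoplankton carbon, per-type surface biomass, and per-type iron
and light limitation terms (fractions of maximum growth rate; smaller =
more limited). Carbon is integrated over the top 100 m — the same horizon
as NPP — and limitation terms are weighted by each functional type's share
of total surface biomass, which keeps the community value inside the
component range. Fields are regridded from the native rectilinear grid
(default 1.5° × 1.25°, deliberately not 1°) to 1° by conservative
overlap-area binning with spherical weights; target cells not fully
covered are masked, so area-weighted means are preserved (0.1 % verified).
Curvilinear grids are out of scope and rejected explicitly.

Change fields are Δ = mean(2081–2100) − mean(1995–2014) per cell, with an
austral-summer (DJF) option that assigns December to the following year's
summer. Driver attribution regresses ΔNPP on ΔC_phyto, ΔLimFe and ΔLimIrr
across cells — the default pools cells in space, and an area-weighted
variant is provided since the weighting convention is not fixed by common
practice. Cumulative change series subtract the 1995–2014 baseline mean
from each year's regional NPP and summarise across members with equal
weights (one vote per model, the simplest defensible convention).
Contemporary (1998–2024) and future (2051–2100) ESM trends delegate to the
same routed trend machinery used for the satellite fields.

## The synthetic generator and what passing tests mean

`gen_rs_fields()` builds per-pixel series
baseline + trend·t + seasonal·sin(2π·doy/365 + φ) + AR(1) noise, clipped at
physical floors. AR(1) (default ρ = 0.3) mimics the autocorrelation of
real ocean-colour series; the default record is 8-day over 1998–2024 with
an NPP field of 300 mg C m⁻² day⁻¹ baseline, 150 seasonal amplitude,
−1.5 mg C m⁻² day⁻¹ yr⁻¹ trend and 30 mg noise — roughly 10 % noise on a
~10 Pg C yr⁻¹ region, a level comparable to interannual scatter in merged
ocean-colour records.

`gen_float_dataset()` draws raw depths at irregular 2–8 m spacing (so
regridding is exercised non-trivially), builds chlorophyll as a mixed-layer
plateau plus a Gaussian deep maximum over a two-layer density structure
with a known MLD (default 55 m), and encodes raw signals through the same
conventions the chain inverts: fluorescence = 2 × chlorophyll,
backscattering = carbon /(12128 × spectral factor) + a non-algal deep
baseline. Artifacts: daytime fluorescence multiplied by 0.6 above the
quench depth (the shallower of half the MLD and 20 m — the regime the
mixed-layer-maximum correction can repair), one multiplicative spike per
profile, 1 % negatives, 5 % bad QC flags, and a −5 % yr⁻¹ biomass factor
imposing a known NPP decline over the 2014–2024 float era.

`gen_esm_ensemble()` constructs each model's NPP change per cell as
α·ΔC_phyto + β·ΔLimFe + γ·ΔLimIrr + noise, where the three Δ patterns are
random fields made exactly mutually orthogonal (QR), ramped linearly
between the historical and future period midpoints, scaled per scenario,
and adjusted by a spatially uniform term so the prescribed regional
cumulative change (0.3/0.5/0.5 Pg C for the three scenarios) holds
exactly. Defaults α = 0.02, β = 0.01, γ = 0.015 put ~80 % of the ΔNPP
variance on biomass, with limitation contributions of the same order as
each other. The depth structure of model carbon is separable
(surface field × fixed exponential shape); depth integration is still
tested on explicit profiles.

What the generator does *not* emulate: sensor merging artifacts in
ocean-colour records, real Argo telemetry formats, curvilinear ocean-model
grids, spatially correlated noise, sea-ice masking, and driver patterns
that are correlated (as they surely are in real models). Recovery tests
passing therefore show the chain is *internally consistent and unbiased
under its own conventions* — they do not validate the published magnitudes
of real-data trends, which depend on multi-decadal external archives.

Driver-coefficient recovery is asserted on the native grid, where the
orthogonality premise holds exactly; the 1° regridding step mixes
neighbouring cells and so leaks variance between patterns (a realism the
orthogonal construction deliberately excludes), and its correctness is
established separately by the conservation and brute-force overlap tests.

## Numerical choices

* Trapezoidal quadrature throughout; depth-resolved results change < 1 %
  between 1 m and 0.5 m steps (tested). Absorption integrals extend to six
  attenuation e-foldings (capped at 500 m).
* Surface extension: the shallowest sample extends to 0 m as a constant;
  interior gaps interpolate linearly; integrals with > 50 % missing levels
  in range are reported missing.
* Huber fits run up to 100 IRLS iterations with MAD scale; an exact line
  (zero residual scale) short-circuits to OLS, where the two estimators
  coincide by construction.
* Mann-Kendall uses the tie-corrected variance and continuity-corrected
  normal approximation; constant series report slope 0 with p = 1.
* Degenerate MLD profiles (no threshold crossing) return the deepest valid
  level, flagged, rather than missing — a mixed layer deeper than the
  profile is the physically conservative reading.
* Polar-night profiles have zero photoperiod and hence zero NPP in both
  the processed and truth chains; recovery ratios are computed over
  productive profiles.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes while every recovery experiment keeps
enough replication to be meaningful: 20 × 20 pixels × 27 years (8-day) for
regional trend recovery across 20 seeds, 110 float profiles with all
artifacts active, ~5 100 model cells for driver recovery, 10⁴ random
pixels for the algorithm property scans, and 1 000 random series for the
trend-engine oracle. The machinery itself is resolution-agnostic.

## Known limitations

Spectrally-integrated absorption models; slope-only carbon calibration;
linear EOS default for density; equal-weight ensemble statistics;
rectilinear grids only; no spatial-autocorrelation correction of trend
significance; no sea-ice physics (masks are inputs). File interchange uses
CSV/JSON sidecar containers with exact round-trip semantics.
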