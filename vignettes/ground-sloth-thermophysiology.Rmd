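---
title: "Methods: from tooth carbonate to thermoneutral zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tooth carbonate to thermoneutral zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenotherm)
```

`xenotherm` chains three independent lines of evidence — isotope
geochemistry, allometry, and biophysical heat balance — into a single
question: what pelage could a multi-tonne ground sloth carry and remain in
energy balance across its geographic range? This vignette documents the
models, the parameters that matter, the numerical choices, and what the
package's synthetic tests do and do not demonstrate.

## Body temperature from clumped isotopes

The abundance anomaly of ¹³C–¹⁸O bonds in carbonate (Δ₄₇, ‰) is set by the
temperature at which the mineral formed, independent of bulk composition.
We use the quadratic-in-1/T calibration

$$\Delta_{47} = \frac{a}{T^2} + b, \qquad
  T = \sqrt{\frac{a}{\Delta_{47} - b}},$$

with defaults $a = 0.0391\times10^6$ ‰ K² and $b = 0.154$ ‰ on the I-CDES
reference frame, under which bioapatite behaves like inorganic calcite.
Both constants are arguments of `d47_calibration()`, so alternative
calibrations drop in without code changes. Values of Δ₄₇ at or below $b$
are non-physical and rejected rather than clamped.

**Standards correction.** Raw sample Δ₄₇ is projected into the accepted
frame with an affine map fitted by OLS to up to 10 standards on either side
of each replicate in run order (`correct_with_standards()`, window
configurable). Real data-reduction software separates nonlinearity and
transfer steps; at desk scale a single affine fit per window recovers any
affine instrument distortion exactly (verified against synthetic runs with
known slope/offset), and the recorded per-window slope is the equivalent QC
diagnostic.

**Uncertainty.** Temperature SE is the delta-method image of the Δ₄₇ SE,
$|dT/d\Delta_{47}|\cdot SE$, with a central-finite-difference mode as a
cross-check; both agree to a few percent at realistic SEs. With $n = 4$
replicates the estimated SE is itself noisy: a ±2·SE interval has nominal
coverage $P(|t_3|\le 2)\approx 86\%$, not 95%. The package reports the SE
and leaves interval construction to the user; anyone needing calibrated
95% intervals at $n = 4$ should multiply by $t_{0.975,3} = 3.18$ rather
than 2. The Monte-Carlo recovery tests in the suite make this distinction
explicit.

**Formation water.** Water δ¹⁸O is back-calculated from carbonate δ¹⁸O
(converted V-PDB → V-SMOW by the standard scale map) through the
carbonate–water fractionation $1000\ln\alpha = 18.03\,(10^3/T_K) - 32.42$.
A phosphate-thermometry strategy ($T = 117.4 - 4.50(\delta_p-\delta_w)$) is
selectable for phosphate inputs. The carbonate expression is the default
because it reproduces measured carbonate-derived waters to within their
reported spread; published water values for fossil material carry
substantial scatter and should not be treated as exact targets.

## Diagenesis screening

Fossil bone takes up rare-earth elements during burial far faster than
dense orthodentine. After PAAS normalisation (which removes the
Oddo–Harkins even–odd abundance sawtooth), the index

$$R = \frac{\sum \mathrm{REE}_N(\text{orthodentine})}
           {\sum \mathrm{REE}_N(\text{cortical bone})}$$

classifies alteration: $R > 1$ significant, $0.5 < R \le 1$ mild–moderate,
$0.35 \le R \le 0.5$ low, $R < 0.35$ minimal. The source literature's
verbal rule ("ratios > 0.35 indicate little to no alteration") contradicts
its own worked usage, where values like 0.42 and 0.86 are treated as
altered-but-acceptable and 0.02 as unaltered; we therefore read the
minimal-alteration condition as $R < 0.35$ and label the 0.35–0.5 gap
"low". Elements missing in one tissue are dropped from both sums together
(dropping from one side only would bias the ratio); non-REE ICP-MS
analytes are excluded from the index by construction. The
carbonate–phosphate δ¹⁸O offset screen is a closed-interval band check;
the default 7–10 ‰ band is a literature-informed placeholder that must be
configured against whichever extant-vertebrate compilation the user trusts.
A Δ₄₈ mean above 1.0 ‰ (strict inequality, configurable) flags isobaric
contamination such as incompletely removed organics.

## Metabolic scaling

Two power laws frame the energetics: the xenarthran relationship
$3.14\,M^{0.69}$ (M in grams, ml O₂ h⁻¹) and the typical-placental Kleiber
form $3.3\,M^{0.76}$ (M in kg, watts). Respirometric output converts to
watts with an oxyjoule equivalent of 20.0 J per ml O₂ — the standard value
for herbivore metabolism, and the one that reproduces the published daily
target-zone bound for the largest genus from its stated mass to within
0.01%. Daily comfort bounds are BMR and FMR (= 2×BMR by default) sustained
for 24 h, i.e. watts × 86.4 kJ. The Kleiber-form output is taken as watts
directly, with no respiratory-quotient adjustment, matching how the
comparison is conventionally presented.

## The heat-balance model

The animal is a prolate spheroid (axis ratio 2:1 by default) of
body density 1000 kg m⁻³ — closed-form volume, area and trunk diameter,
replacing sculpted meshes while staying mass-consistent. Fur is a
conducting shell of depth $d$; its slab conductance uses the area at
mid-depth, $K = k_{coat} A_{mid}/d$.

The coat conductivity has two parts:

* the fibre–air mixture $k_{eff} = k_{air} + (k_{hair}-k_{air})f$, with
  $f$ the fibre volume fraction from hair density and diameter
  (`fur_effective_conductivity()`), and
* a bypass term $k_{byp}\,e^{-\rho/\rho_0}$ ($k_{byp} = 0.25$ W m⁻¹ K⁻¹,
  $\rho_0 = 600$ hairs cm⁻²) representing free convection and thermal
  radiation across the gap, which dense pelage suppresses.

The bypass is the package's own design choice, and it matters: fur
insulates because it immobilises air, not because keratin conducts less
than air (it conducts *more*). A pure mixture slab would make a
2,000 hairs cm⁻² coat a slightly *worse* insulator than an
8.5 hairs cm⁻² one and would make a zero-density "coat" a perfect
still-air blanket — both physically wrong. With the bypass, insulation
improves monotonically with hair density through the densest coat
considered (~2,000 hairs cm⁻²), and the zero-density limit conducts like
an open air gap. $k_{byp} = 0.25$ W m⁻¹ K⁻¹ is the order of the combined
radiative (16σT³/3β) and free-convective transport across a
centimetre-scale gap at ~300 K; $\rho_0$ places sparse pig-like coats
(≈8.5 cm⁻²) near the open-gap limit and horse-flank density (≈1,300 cm⁻²)
near full stilling, consistent with those animals' thermal behaviour.
Above roughly 2,500 hairs cm⁻² the rising fibre-conduction term would
dominate again; the model is not intended there.

At the outer surface, losses are convection with the cylinder-in-crossflow
correlation $Nu = 0.35 + 0.56\,Re^{0.52}$ (film-temperature air
properties, floored at the $Nu = 2$ conduction limit so zero wind is
well-defined), net thermal infrared at emissivity 0.95 against the radiant
temperature, and absorbed solar as absorptivity 0.8 × silhouette
interception 0.25 × (1 − shade). Skin resistance is neglected relative to
the coat (the classical skin-conduction flux is retained as a standalone
diagnostic, `skin_conduction_flux()`); the skin sits at core temperature.

**Numerics.** The surface temperature is the unique root of a strictly
decreasing balance function; we bisect, expanding the bracket up to ±200 K
before failing with a flux dump, and iterate until the bracket is below
10⁻³ K *and* the residual below 0.05 W — the convergence criterion is the
energy mismatch itself, which keeps the closure guarantee (<0.1 W) valid
even for very thin, highly conductive coats. Evaporation is a fixed
fraction (default 0.05) of metabolic production, so
$M_{req} = \text{load}/(1-f_{evap})$; negative $M_{req}$ is reported, not
clipped, and flagged as a net heat load.

**Thermoneutral zones.** A metabolic chamber is emulated as
$T_{rad} = T_{air}$, wind 0.1 m s⁻¹, no sun, sweeping air temperature over
[−60, 50] °C in 0.5 °C steps; the TNZ is the contiguous band where the
requirement stays within ±5% of BMR, its endpoints the lower and upper
critical temperatures. Monotonicity of the requirement in air temperature
makes the band contiguous by construction; halving the step moves the
endpoints by at most one step. Published critical temperatures for these
genera come from a proprietary modelling system with unpublished internal
coefficients, so they serve as directional anchors (dense 50 mm coats
reach well below −10 °C; deeper and denser coats always extend the zone
downward), not exact targets. Evaporative escalation (panting, sweating)
is deliberately absent, so the upper critical temperature follows purely
from the ≤0.95·BMR suppression criterion.

Core temperature is fixed per run. For Mylodon, which lacks a usable
isotope estimate (the congener-scale sample failed the REE screen and its
apparent temperature is ectotherm-like), the default comes from the
extant-xenarthran mass regression $T = 34.908\,M^{-0.01}$ evaluated at
1,986 kg (≈32.4 °C).

## Microclimate and daily budgets

Monthly climate rows (Tmax/Tmin, RH, cloud, wind, additive paleo-offset)
become hourly drivers on the 15th of each month, every day of a month
assumed identical. Air temperature follows half-cosine segments anchored
at the minimum at (integer-rounded) sunrise and the maximum at 14:00 local
solar time — rounding sunrise to a sampled hour makes the stated extremes
attained exactly. Solar flux is $1361\cdot0.7^{m}\cos z\,(1-0.75c)$ with
air mass $m = 1/\cos z$ capped at 38; sky radiant temperature uses the
empirical clear-sky emissivity
$\varepsilon = 1 - 0.261\,e^{-7.77\times10^{-4}(273-T_K)^2}$ blended to
blackbody with cloud. In the sun option the radiant environment averages
sky and ground (taken at air temperature) half-and-half; in shade it is
air temperature with solar blocked.

Each hour the animal adopts whichever of the two shade options brings its
requirement closest to BMR. Hours with negative requirement integrate as
zero production (an animal cannot produce negative heat) and are counted
as heat-load hours. Daily energy is the trapezoidal integral over the
periodic 24-h cycle — exactly the hourly mean × 86.4 kJ, so a constant
1,000 W trace gives exactly 86,400 kJ and the integral is invariant under
rotation of the trace. Days are classified against the taxon's comfort
bounds: above the FMR bound is cold stress, below the BMR bound heat
stress. "Active hours" counts hours in which the full-sun requirement is
at least 0.95×BMR — i.e. basal output is sustainable without retreating to
shade; the 0.95 threshold mirrors the TNZ suppression criterion and is a
documented choice, as no published threshold exists. Annual summaries pick
the fur configuration with the fewest stressed months per locality, ties
broken towards thinner then sparser coats (the cheaper integument).

Forage intake divides daily energy by gross energy × digestibility of dry
matter, then by the dry-matter fraction. The default leaf diet
(18 MJ kg⁻¹ DM, 0.45, 0.30) is an editable fixture: the feed-composition
entries behind published intake magnitudes are supplementary-only, so
absolute intake is not a target; seasonal *shape* is summarised by the OLS
quadratic fit with $R^2$ defined as 0 for constant data.

## Synthetic data: what it shows and what it cannot

The generators produce exactly the structures the pipeline consumes, with
recorded truth and explicit seeds (global RNG state is saved and
restored). Δ₄₇ noise is normal at the replicate level — a pragmatic choice
where only SDs/SEs are reported; concentrations are lognormal
(non-negative support); climate regimes are seasonal sinusoids with
bounded uniform jitter, amplitude growing with |latitude|, tropical
output confined to roughly 2–30 °C. Passing recovery tests therefore
demonstrates correctness of the *computational chain* — correction,
aggregation, calibration, indexing, balance closure — under idealised
noise. It does not validate the physics against living animals, nor cover
instrument drift spectra, correlated replicate errors, real soil/substrate
microclimates, snow, burrows, or behavioural thermoregulation beyond
binary sun/shade choice.

## Problem sizes and runtimes

The test suite uses the study-scale configuration throughout: 4 genera,
fur grids of 3 depths × dense/sparse, chamber sweeps of 221 temperatures,
3 localities × 12 months for annual runs, 200–1,000 random draws for
closure and recovery properties, and 1,000 seeds for coverage Monte
Carlo. The complete suite and the acceptance script each run in well
under a minute on a single core; the full genus × fur × locality × month
grid is a few tens of seconds.

## Known limitations

Steady state only — no thermal inertia, which for multi-tonne bodies is
substantial and would buffer diurnal extremes; no regional heterothermy or
countercurrent limb exchange; evaporative physiology reduced to a fixed
fraction; one shape ratio for all taxa; fur treated as homogeneous and
dry (wet coats conduct far better); the carbonate–phosphate offset band
and the active-hours threshold are conventions, not measurements. The
heterothermic relaxation mode (choosing the in-range core temperature
minimising |M − BMR|) is intentionally simple and not a model of torpor.
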