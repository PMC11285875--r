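---
title: "Methods: carbon budgets from dual-radioisotope incubations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon budgets from dual-radioisotope incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralcarb)
library(dplyr)
```

coralcarb analyses dual-radioisotope (⁴⁵Ca + ¹⁴C) vial incubations of
calcifying red algae (maerl / rhodoliths), quantifying how calcification
and photosynthesis share one carbon pool: how much of the bicarbonate an
alga takes up ends as skeletal carbonate, how much as organic matter, how
much of the CO₂ generated by calcification is recycled into
photosynthesis, and how much escapes to the water. This vignette explains
the models, the estimators, the numerical choices, and what the synthetic
experiment does and does not establish.

## The incubation design

Single algal branches sit in 20 ml vials of filtered seawater labelled
with 600 kBq each of ⁴⁵CaCl₂ and NaH¹⁴CO₃. Half the vials receive
ethoxyzolamide (+EZ), a membrane-permeable inhibitor of carbonic
anhydrase (internal and external), which suppresses the cell's
carbon-concentrating machinery. Eight replicate vials per treatment are
sacrificed at 0.5, 1.5, 3 and 5 h (64 vials total). Scintillation
counting after sequential acidification separates four channels per vial:
skeletal ⁴⁵Ca, skeletal (inorganic) ¹⁴C, organic ¹⁴C, and ¹⁴CO₂
recovered from the medium. Net O₂ production is recorded by optode.

## Tracer bookkeeping

The specific concentration of a label, `Con` (nmol kBq⁻¹), converts a
counted activity into moles of the traced species:
`Con = carrier_pool / activity_added`. For ⁴⁵Ca the carrier pool is
seawater calcium (10.28 mmol kg⁻¹ at S = 35 in a 0.02 kg vial); for ¹⁴C
it is the vial's DIC (default 2.1 mmol kg⁻¹). Neither value is an
observable of the experiment, so both are configuration with explicit
defaults (`label_specs()`).

Incorporation follows

$$\text{rate} = \frac{\text{activity} \times Con}{M \times T},$$

with `M` the dry skeletal mass (g) and `T` the incubation time (h);
absolute incorporation is rate × `T`. Rates default to cumulative;
`interval_rates()` offers per-interval rates between consecutive
timepoints computed from group means.

Two adjustments follow:

* **Mg adjustment** (`mg_adjust()`). The skeleton is high-Mg calcite, so
  carbonate deposition exceeds what calcium alone traces. Rates scale by
  (1 + Mg/Ca); the Mg/Ca molar ratio defaults to 0.15, typical of
  high-Mg calcite, and is configurable. A flag prevents double
  application.
* **Direct-deposition blank** (`correct_direct_deposition()`). Freshly
  snapped branches expose bare skeleton on which labelled bicarbonate can
  deposit abiotically. The correction subtracts a per-timepoint blank
  rate — supplied by configuration or estimated from dedicated blank
  vials — flooring at zero; every clamp is reported as a message. We
  model the correction this way because it preserves the stated intent
  (avoid overestimating incorporation) behind an explicit, testable
  contract; more elaborate schemes would require information the vial
  table does not carry.

Radioactive decay is ignored: both isotopes have half-lives (163 d,
5730 y) that are irrelevant over 5 h, and counting efficiency is outside
scope.

A note on units: a deposition rate of order 1 nmol Ca+Mg h⁻¹ g⁻¹
corresponds to a skeletal mass gain of order 10⁻⁴ % day⁻¹
(`mass_gain_percent_per_day()`), three orders of magnitude below
percent-level daily gains reported by buoyant-weight methods. The two
observables are not interchangeable; the conversion is provided for
transparency and is deliberately not part of any quantitative check.

## The organismal release ratio ψ_I

The per-vial estimator is

$$\psi_I = \frac{^{14}\mathrm{CO_2}\ \text{production} - \text{organic}\ ^{14}\mathrm{C}\ \text{fixation}}{^{45}\mathrm{Ca}\ \text{incorporation (Mg adjusted)}},$$

computed from the +EZ treatment only: with carbonic anhydrase inhibited,
CO₂ uptake through the carbon-concentrating machinery is suppressed, so
the medium ¹⁴CO₂ signal isolates calcification-derived CO₂. ψ_I can be
negative in noisy early-timepoint records; such values are reported with
a warning and never clamped, because they are informative about noise.

`summarise_psi_i()` reports two group statistics: the mean ± sd of
per-vial ratios (the descriptive per-timepoint table) and
`psi_i_pooled`, the ratio of group-mean rates. The pooled form is the
cohort-level estimator used in recovery checks: a mean of per-vial ratios
inherits an E[1/Y] bias from multiplicative measurement noise (about
+2.3% at a 15% CV), whereas the ratio of group means is first-order
unbiased.

## Seawater chemistry and the buffered release ratio ψ

Because seawater is buffered, precipitating carbonate does not release
CO₂ mole for mole. For a parcel in gas-exchange equilibrium with an
unchanged ambient pCO₂, precipitating one mole of CaCO₃ (ΔDIC = −1,
ΔTA = −2) leaves the water holding less DIC at the same pCO₂; the
excess carbon is evaded as CO₂ gas. ψ is that evaded amount per mole
precipitated — about 0.6–0.8 in surface seawater — and is the
no-recycling expectation against which ψ_I is compared.

`solve_carb()` speciates the CO₂ system from any two of pH, total
alkalinity, DIC and pCO₂. Constants (`carb_constants()`) are kept on the
total hydrogen-ion scale: K0 from Weiss (1974); K1/K2 from Lueker et al.
(2000) by default — the Mehrbach refit reported directly on the total
scale, which avoids a seawater-scale conversion in the default path —
with the Dickson & Millero (1987) refit and Roy et al. (1993) as
selectable alternatives; K_B Dickson (1990); K_w Millero (1995); total
boron 0.000416·S/35 (Uppström). NBS-scale pH is accepted at the boundary
and converted through the Takahashi activity factor. The alkalinity
balance carries carbonate, borate, water and free-hydrogen terms;
nutrients and pressure corrections are out of scope for surface
incubations. Total alkalinity and DIC are µmol kg⁻¹ and pCO₂ µatm at
the interface, mol kg⁻¹ internally.

Root-finding is a bracketed search on pH ∈ [2, 12] (deterministic, no
randomness) converged to machine precision; the residual of the
alkalinity equation is checked against 10⁻¹² mol kg⁻¹. Two identities
hold on every solved state and are enforced in tests: the speciation
sums close to DIC and carbonate alkalinity to 10⁻¹⁰ relative, and the
equilibrium relation a_H · [HCO₃⁻] = K₁ · K₀ · pCO₂ holds to 10⁻⁸
relative. (Transcriptions of this relation sometimes circulate with the
fraction inverted; as written here it is the definition of K₁
rearranged, and the inverted form is dimensionally inconsistent with a
hydrogen-ion concentration.)

### The analytic model and its oracle

With carbonate alkalinity $A$, hydrogen-ion concentration $a_H$ and

$$P = \frac{K_B T_B}{(a_H + K_B)^2} + \frac{K_w}{a_H^2} + 1,\qquad
Q = a_H + 2K_2,\qquad R = AQ + 2K_2A + PQa_H,$$

implicit differentiation of the constant-pCO₂ system gives the closed
form

$$\psi = \frac{2AQ}{R} - 1
       = 2\left(\frac{\partial \mathrm{DIC}}{\partial \mathrm{TA}}\right)_{pCO_2} - 1.$$

The derivation is three lines: at constant [CO₂], each species is a
function of $a_H$ alone, $d\mathrm{DIC}/da_H = -A/a_H$ and
$d\mathrm{TA}/da_H = -R/(Q a_H)$, and the evaded CO₂ per mole
precipitated is $2(\partial \mathrm{DIC}/\partial \mathrm{TA})_{pCO_2} - 1$. The buffer-capacity
sum $P$ (in which the water and proton terms use the same free-hydrogen
convention as the solver) and the structure of $R$ are exactly the
intermediates that published statements of this model print, which is a
useful cross-check on the derivation. A further combination of the
intermediates, `CS`, circulates in print in a form whose typography does
not survive extraction into plain text; it is reported as a diagnostic
field of `psi_result` but plays no role in ψ here.

The model is never trusted on its own: `psi_finite_difference()` is a
model-free perturbation oracle that simulates the precipitation
(TA − 2δ, DIC − δ), re-solves the system at the original pCO₂ and
measures the evaded CO₂ as a central difference (second-order in δ,
default δ = 10⁻⁹ mol kg⁻¹). Tests assert agreement within 10⁻³
absolute over a temperature × pH × alkalinity × salinity grid; in
practice the two agree to ~10⁻⁹. Note that the *instantaneous*
closed-system quotient −Δ[CO₂]/Δ[CO₃²⁻] (no gas exchange) is a much
smaller number (~0.03–0.10) because the bicarbonate pool buffers the
perturbation; the gas-exchange form is the one whose value (~0.6 at
25 °C and ~350 µatm) carries the familiar positive-feedback
interpretation, and the one used throughout.

```{r psi}
st <- solve_carb(15, 35, ph = 8.1, total_alkalinity = 2300, ph_scale = "NBS")
c(analytic = psi_analytic(st)$psi, oracle = psi_finite_difference(st)$psi)
```

### The reference value at the incubation temperature

The incubation water's exact pH and alkalinity are not observables of the
vial experiment, so `psi_reference()` sweeps plausible west-Scotland
summer conditions (15 °C, S 34–35, TA 2300 µmol kg⁻¹, pH 8.05–8.10
NBS) and anchors on the grid state whose solved pCO₂ is nearest
atmospheric (420 µatm): the water had equilibrated in aerated mesocosms
for ten weeks, so near-air-equilibrium is the physically defensible
representative state. The anchored ψ is reported to one decimal — the
precision at which such reference values are conventionally quoted —
with the full sweep returned alongside so the sensitivity (ψ spans
0.74–0.76 across the band) is never hidden. All three K1/K2
formulations give the same one-decimal value.

## The carbon-budget partition

Terminal sinks at the organism scale are skeletal carbonate ($P$, carbon
units via the 1:1 C : Ca+Mg assumption), organic matter ($O$) and net
CO₂ released ($N$). Under the bicarbonate-use stoichiometry
2 HCO₃⁻ → CO₃²⁻ + CO₂ + H₂O, each mole precipitated generates one mole
of CO₂, so CO₂ produced equals $P$ and the gross inorganic-carbon demand
of calcification is $2P$. Total uptake is $U = O + P + N$ — terminal
sinks only, so the recycled CO₂ (counted once inside calcification
demand and once inside organic fixation) is never double-counted in $U$.
Derived quantities: recycled fraction of produced CO₂ $(P-N)/P$,
released fraction $N/P$, total fixed $(O+P)/U$.

The seawater-buffered ψ of the previous section is deliberately *not*
used in this partition: the stoichiometric 1:1 production is the only
choice under which the three measured sinks and the derived percentages
close into a single consistent budget; ψ is reported alongside as the
expectation for an organism that recycled nothing. The gap between ψ_I
(~0.38) and ψ (~0.7) is the recycling signal.

One derived reading is intentionally ambiguous: recycled CO₂ "as a share
of organic-matter carbon" can mean percentage points of total uptake or
a fraction of the organic pool; the two differ (≈15 points vs ≈38%),
so `budget_partition()` reports the primitive fractions and leaves that
composite to the reader.

Uncertainty propagates by Monte Carlo (`budget_propagate()`): each input
is drawn from a normal truncated at zero, centred on the group mean with
the standard error of the mean as spread, the partition runs per draw,
and each output is summarised as mean ± sd. Draws are seeded and
reproducible. A first-order delta-method propagation
(`budget_propagate_delta()`) serves as an analytic cross-check; the two
agree within Monte-Carlo error whenever the standard errors are small
against the means. Truncation matters only when an input mean sits
within ~2 standard errors of zero, where the normal assumption itself is
questionable.

```{r budget}
budget_partition(organic = 39, skeleton = 38, net_release = 23) |>
  round(3)
```

## Statistics

Group comparisons use the tie-corrected Kruskal–Wallis test
(`kw_test()`; mid-ranks, tie correction always applied since real
scintillation data tie rarely but simulated integer data can) with the
chi-square approximation — adequate at eight replicates per group,
though slightly conservative: its measured type-I error at 8 × 8 under
the null is ≈0.039 at nominal 0.05. Post-hoc pairwise contrasts use Dunn
z statistics on mean ranks with tie-corrected pooled variance and Šidák
adjustment over all k(k−1)/2 pairs (`dunn_sidak()`; m is reported so the
correction is auditable). Association uses the Pearson coefficient with
the t-based p value (`pearson_cor()`). Groups are treatment × timepoint
cells (8 groups, df = 7) — the pooled convention implied by 7-df test
statistics in this literature; no exact permutation option is provided
at these group sizes.

## The synthetic experiment

`sim_vials()` forward-simulates the design: true cumulative
incorporation per channel is rate × time × mass, inverted to activities
through the label specific concentrations, then degraded by two
multiplicative lognormal layers with unit mean — a per-vial individual
multiplier shared across channels (biological variability, CV 0.30,
reflecting the wide between-individual spreads such budgets exhibit) and
an independent per-measurement factor (counting noise, CV 0.15).
Lognormal noise keeps activities positive and right-skewed; unit mean
keeps pipeline estimators unbiased. Dry masses are lognormal around
0.5 g (CV 0.25), a typical single-branch mass.

Truth parameters default to the study conditions: control Ca+Mg
deposition 1.47 nmol h⁻¹ g⁻¹, +EZ 0.19 (the CA-inhibition effect);
terminal sinks 38/39/23% in the control; ψ_I = 0.38 under +EZ;
external-DIC share of skeletal carbon 0.646. Organic-fixation and
CO₂-release rates are *derived* from these fractions
(organic = 1.47 × 0.39/0.38, release = 1.47 × 0.23/0.38, +EZ release =
0.38 × 0.19), so the generator is calibrated to the printed fractions
rather than to unprinted absolute rates — a calibration, not a
measurement. O₂ production defaults to 1.2 µmol h⁻¹ g⁻¹ in the control
with the inhibited group scaled down by 1.86 from 3 h (no effect at
0.5 h, intermediate at 1.5 h).

What passing recovery tests establish: the estimator chain
(incorporation → Mg adjustment → ψ_I → budget) inverts the forward
model without bias at realistic noise, and the Monte-Carlo machinery is
calibrated. What they cannot establish: correctness of the noise model
for real scintillation counts, the true Mg/Ca ratio, the blank
magnitude, or any boundary-layer, circadian or decay effect — none of
which the generator simulates.

Problem sizes are chosen to make every check precise but quick: 200
cohorts for recovery, 10⁴–10⁵ draws for propagation checks, 2 × 10⁴
null data sets for the rank-test calibration.

## Reproducibility

All randomness flows from explicit integer seeds (`withr::with_seed`, so
the caller's RNG state is never disturbed). `run_pipeline()` snapshots
its configuration, seed and package version into a manifest and, when
writing output, records md5 checksums; identical manifests reproduce
identical checksums. `scripts/acceptance.R` recomputes the two headline
quantities (the anchored ψ and the recovered control calcification rate)
from scratch against the installed package.

## Known limitations

* The carbonate solver is a surface-seawater tool: no nutrient
  alkalinity, no pressure correction, salinity fits trusted over S
  roughly 19–43.
* The budget's 1:1 CO₂-per-carbonate stoichiometry is the closing
  assumption, not a measurement; organisms with different proton
  handling would need a different production term.
* The blank correction is only as good as the supplied blank rate; the
  package provides the contract, not the blank.
* Exact reproduction of any given experiment's test statistics requires
  its raw per-vial data; with only printed group statistics, checks are
  limited to derived arithmetic and calibrated recovery, which is what
  the test suite and acceptance script implement.
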