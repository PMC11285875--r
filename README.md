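# coralcarb

Carbon budgets for coralline algal calcification and photosynthesis from
dual-radioisotope (⁴⁵Ca + ¹⁴C) vial incubations.

Coralline algae (maerl / rhodoliths) build vast calcified reefs in which
two carbon processes run side by side: photosynthesis consumes CO₂ while
calcification generates it. Whether such a reef is a net carbon sink
hinges on the fate of the calcification-derived CO₂ — released to the
water, or recycled internally as photosynthetic substrate. coralcarb is
the analysis toolchain for the vial experiment that answers this at the
organism scale, and for marine ecophysiologists and blue-carbon
researchers who want the whole chain — tracer arithmetic, carbonate
chemistry, budget closure, inference — reproducible and testable.

## What it computes

**Tracer incorporation.** Scintillation activities become deposition and
fixation rates through the label's specific concentration:

    rate = activity × Con / (M × T)        [nmol h⁻¹ g⁻¹]

with Mg adjustment for high-Mg calcite (× (1 + Mg/Ca)) and an optional
blank correction for abiotic deposition on bare skeleton.

**The organismal release ratio.** From the carbonic-anhydrase-inhibited
(+EZ) treatment,

    ψ_I = (¹⁴CO₂ production − organic ¹⁴C fixation) / ⁴⁵Ca incorporation (Mg-adjusted)

measures the moles of CO₂ actually released per mole of carbon
precipitated.

**The buffered seawater expectation.** For seawater in gas-exchange
equilibrium at fixed ambient pCO₂, the analytical carbonate-system model
gives the CO₂ evaded per mole of CaCO₃ precipitated,

    ψ = 2AQ/R − 1,   P = K_B·T_B/(a_H+K_B)² + K_w/a_H² + 1,
                     Q = a_H + 2K₂,   R = AQ + 2K₂A + PQ·a_H,

validated against a finite-difference perturbation oracle
(TA − 2δ, DIC − δ, re-equilibrate, measure evaded CO₂). ψ ≈ 0.7 at
15 °C: the no-recycling expectation. ψ_I well below ψ is the recycling
signal.

**The budget partition.** Terminal sinks (skeleton P, organic O, net
release N) close to the total uptake U = O + P + N; CO₂ produced = P
(1:1 under 2 HCO₃⁻ → CO₃²⁻ + CO₂); calcification demand = 2P; recycled
fraction of produced CO₂ = (P − N)/P. Uncertainties propagate by seeded
Monte Carlo from group means and standard deviations, cross-checked by a
delta-method linearisation.

**Inference.** Tie-corrected Kruskal–Wallis, Dunn post-hoc contrasts
with Šidák adjustment, Pearson correlation — implemented from the rank
definitions and cross-checked against base R in the test suite.

**A forward simulator.** `sim_vials()` generates the full 2 × 4 × 8
design (64 vials) with configurable truth parameters and lognormal
biological + measurement noise, writing the same CSV schema the analysis
reads, so the entire pipeline is testable without any external data.

## Worked example

```r
library(coralcarb)

run <- run_pipeline(sim_config(), seed = 42, n_draws = 10000)
run
#> <coralcarb_run>
#>   64 vials; seed 42; package 0.1.0
#>   terminal sinks: skeleton 37% / organic 39% / net release 24%
#>   calcification demand 74% of uptake; recycled 35% of produced CO2
#>   psi_I (+EZ, pooled, last timepoint) 0.436; seawater psi 0.737
```

One simulated cohort, analysed end to end: of the bicarbonate this
virtual alga took up, 37% ended as skeleton and 39% as organic matter;
calcification's gross carbon demand was 74% of uptake, and 35% of the
CO₂ that calcification generated was recycled into photosynthesis
rather than released (the generator's truth values are 38%, 39%, 76%
and 39% — one noisy cohort scatters around them). The per-timepoint
release ratio in the inhibited treatment:

```r
inc <- incorporation(run$vials) |> mg_adjust()
summarise_psi_i(psi_i_records(inc))
#> # A tibble: 4 × 6
#>   treatment timepoint_h mean_psi_i sd_psi_i     n psi_i_pooled
#>   <chr>           <dbl>      <dbl>    <dbl> <int>        <dbl>
#> 1 EZ                0.5      0.379   0.0643     8        0.363
#> 2 EZ                1.5      0.353   0.0732     8        0.347
#> 3 EZ                3        0.399   0.0550     8        0.382
#> 4 EZ                5        0.437   0.0857     8        0.436
```

ψ_I ≈ 0.35–0.44 per mole precipitated — half the buffered seawater
expectation at the same temperature:

```r
st <- solve_carb(15, 35, ph = 8.1, total_alkalinity = 2300, ph_scale = "NBS")
psi_analytic(st)$psi
#> [1] 0.73747
```

Budget uncertainty, propagated from the cohort's group statistics:

```r
run$budget_mc
#> # A tibble: 9 × 3
#>   quantity               mean     sd
#>   <chr>                 <dbl>  <dbl>
#> 1 total_uptake         21.4   1.30
#> 2 frac_skeleton         0.369 0.0300
#> 3 frac_organic          0.390 0.0294
#> 4 frac_net_release      0.241 0.0278
#> 5 frac_co2_produced     0.369 0.0300
#> 6 frac_calc_demand      0.738 0.0600
#> 7 frac_total_fixed      0.759 0.0278
#> 8 recycled_of_produced  0.340 0.114
#> 9 released_of_produced  0.660 0.114
```

`reproduce_headline()` recomputes the derived percentages of the closed
39/38/23 budget (76% demand, 77% fixed, ~39% recycled / ~61% released),
the 87% calcification reduction under carbonic-anhydrase inhibition, the
35.4% metabolic share of the calcification carbon source, and the
anchored ψ. `plot_incorporation()`, `plot_psi_grid()` and `autoplot()`
on a propagated budget give the standard diagnostic figures, and
`inst/scripts/coralcarb` exposes the pipeline as shell subcommands
(`simulate`, `incorporate`, `psi`, `budget`, `stats`, `run-all`,
`headline`).

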