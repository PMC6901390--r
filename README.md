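# cascadekin

Kinetic modelling of a cell-free, four-enzyme cascade that converts
D-mannose into L-lactic acid without phosphorylation and with internal
NAD⁺/NADH recycling:

> mannose —AldT→ mannono-1,4-lactone —(hydrolysis)→ mannonate —ManD→
> 2-keto-3-deoxygluconate (KDG) —KDGA⇌ pyruvate + glyceraldehyde
> —LDH→ lactate

AldT reduces NAD⁺ to NADH; LDH re-oxidises it, closing the cofactor loop.
Only the pyruvate half of each cleaved C6 skeleton becomes lactate, so the
stoichiometric ceiling is 1 mol lactate per mol mannose (50% of substrate
carbon). The cascade runs hot (323 K), so AldT and ManD deactivate with
half-lives of 9.8 h and 1.4 h, and the aldol cleavage is endergonic
(ΔG°′ = +6.2 kJ/mol), pulled forward only by LDH scavenging pyruvate.

The package provides:

* **Rate laws** — Michaelis–Menten kinetics with exponential thermal
  deactivation per enzyme, saturating NAD⁺/NADH dependence, and a
  thermodynamically consistent reversible aldol step whose net rate
  changes sign exactly at the equilibrium mass-action ratio.
* **Simulation** — `simulate_onepot()` and `simulate_sequential()`
  (timed enzyme additions and cofactor spikes) on `deSolve`, with carbon
  and cofactor conservation diagnostics.
* **Mass balance** — yield/titre arithmetic, Beer–Lambert assay
  conversions, and recovery-corrected sugar accounting for biomass
  (spent coffee ground) hydrolysates.
* **Synthetic data** — generators mimicking real-time NMR relative
  integrals, HPLC concentration triplicates and residual-activity decay
  assays.
* **Fitting** — bounded multi-start Levenberg–Marquardt estimation of
  cascade parameters (with a censored-mean refinement for zero-clipped
  data), half-life fits, AIC comparison of irreversible vs reversible
  aldol mechanisms, and Monte-Carlo recovery/discrimination studies.

## Worked example

```r
library(cascadekin)

tc <- simulate_onepot(cascade_recipe("onepot_standard"))
tc
#> <timecourse> concentration_mM, 10 species x 167 times (0.00-17.98 h), replicate 1

la <- tail(tc_species(tc, "LA"), 1)
cat(sprintf("LA at 18 h: %.2f mM (%.1f%% of theoretical max)\n",
            la, percent_yield(la, 5)))
#> LA at 18 h: 2.76 mM (55.3% of theoretical max)

cb <- carbon_balance(tc)
max(abs(cb - cb[1])) / cb[1]
#> [1] 2.13e-15

# half-life from a synthetic residual-activity assay
assay <- generate_decay_assay(9.8, seed = 2)
fit_half_life(assay$times, assay$activity)$half_life
#> [1] 10.06978
```

Longer narratives live in `analysis/` (numbered scripts writing tables to
`results/`) and in the methods vignette
(`vignettes/cascade-kinetics.Rmd`).

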