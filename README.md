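# commflux

Constraint-based analysis of microbial community metabolism in R, built to
compare the two ways of reading a genome-scale metabolic model (GEM):
**flux balance analysis** (FBA), which picks the single growth-optimal flux
state by linear programming, and **flux sampling**, which draws
approximately uniform flux states from the entire steady-state polytope
`{v : S v = 0, lb ≤ v ≤ ub}` and so captures the sub-maximal, heterogeneous
states a community can actually occupy.

Both readings run across the three standard community constructions:

* **Compartmentalized pairing** — two GEMs joined through a shared lumen
  compartment; mono-cultures are simulated by shutting one organism off,
  co-cultures with both active, and the growth changes are classified
  against a ±10% threshold into six ecological motifs: mutualism (+/+),
  commensalism (+/0), neutralism (0/0), amensalism (−/0), parasitism
  (+/−), competition (−/−).  Sampling mode adds a basal-growth bound (10%
  of each organism's mono-culture FBA optimum), per-sample interaction
  calls, growth-rate regime maps, and community growth ratios.
* **Lumped pooling** — a single "supra-organism" network retaining one
  biomass reaction per species, with per-species optimization, the max-min
  optimal community growth `g* = max g s.t. v_bio_k ≥ g ∀k`, pathway-level
  flux summaries, per-reaction bidirectional Kullback–Leibler divergence
  between flux distributions, and metabolite turnover via the flux-sum
  `Φ_i = ½ Σ_j |S_ij v_j|`.
* **Costless secretion** — organisms simulated separately on a shared
  medium that iteratively absorbs metabolites secreted at no growth cost,
  until the medium is stable; sampling mode decides secretion by the
  fraction of sampled flux states that secrete (*all* / *most* / *any*),
  and outcomes are labeled N/C/M-#-a/b (cross-feeding direction, carbon
  sources supplied, competition) plus a no-growth category.

Everything runs on a self-contained stack: a bounded-variable two-phase
simplex (deterministic via Bland's rule), an artificial-centering
hit-and-run sampler over a null-space parameterization of `S`, SBML Level 3
(fbc) and JSON model I/O, and a synthetic-data module that generates small
mass-balanced microbe models with *engineered, provable* ground-truth
interactions — so every pipeline stage is testable without external model
downloads.

## Worked example

A mutualistic pair: organism A ferments glucose and secretes a byproduct B
can salvage; B ferments fructose and returns the favor.

```r
library(commflux)

pair <- make_crossfeeding_pair("mutualism")
call <- pairwise_protocol_fba(pair$a, pair$b, pair$diet)
print(call)
#> <interaction_call> mutualism  [A: 10 -> 20 (faster); B: 10 -> 20 (faster)]
```

Each organism grows at 10 h⁻¹ alone and 20 h⁻¹ in co-culture (the partner's
byproduct doubles the biomass yield), beyond the +10% threshold for both,
hence mutualism.  The sampling reading explores the whole polytope instead:

```r
res <- pairwise_protocol_sampling(pair$a, pair$b, pair$diet,
         sampler_settings(n_samples = 500, steps_per_point = 100, seed = 1))
print(res)
#> <pairwise_sampling_result> modal call: mutualism
#>    mutualism commensalism   neutralism   amensalism   parasitism  competition
#>        0.998        0.002        0.000        0.000        0.000        0.000

ratios <- community_growth_ratio(res)
round(range(ratios), 1)
#> [1] 10.2 83.7    # percent of the FBA co-culture sum (40 1/h)
```

99.8% of the per-sample calls agree with the FBA motif, and the summed
sampled growth spans 10.2–83.7% of the FBA co-culture optimum — bounded
below by the basal-growth rule (2 × 10% × 10 h⁻¹ over a 40 h⁻¹ optimum) and
above by the polytope maximum.  `build_regime_map(res)` bins the two
organisms' sampled growth rates into quantile cells and reports the modal
interaction per cell, phase-diagram style.

The same fixtures drive the other two constructions, e.g.

```r
pool <- apply_diet(pool_models(list(pair$a, pair$b)), pair$diet)
optimal_community_growth(pool)$g_star        # max-min community growth

fx <- make_costless_pair("commensal")        # A secretes acetate; B needs it
rec <- run_costless(fx$models, fx$media, fx$carbon_sources,
                    aerobic = FALSE, mode = "fba")
label_costless_interaction(rec)              # "C1a", converged at iteration 2
```

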