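---
title: "Methods: optimization- and sampling-based community metabolism in commflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimization- and sampling-based community metabolism in commflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commflux)
```

## The modeling problem

A genome-scale metabolic model (GEM) describes an organism as a stoichiometric
matrix $S$ (metabolites $\times$ reactions) with flux bounds
$lb \le v \le ub$.  At steady state, feasible flux vectors form the polytope
$\{v : Sv = 0,\ lb \le v \le ub\}$.  Flux balance analysis (FBA) selects one
point of this polytope by maximizing an objective — almost always a biomass
reaction — with linear programming.  Flux sampling instead draws many
(approximately uniform) points from the whole polytope, characterizing every
flux state the constraints allow rather than only the growth-optimal one.

`commflux` implements both readings across the three standard constructions
for modeling a microbial community:

1. **Compartmentalized pairing** (`join_compartmentalized()`): two GEMs are
   merged into one stoichiometric matrix through a shared *lumen*
   compartment.  Each organism's exchange reaction becomes a reversible
   transport between its own extracellular space and a lumen species, and
   one community-level exchange per lumen species connects the lumen to the
   environment.  Diets therefore constrain the community boundary only;
   metabolites move freely between organisms through the lumen.
2. **Lumped pooling** (`pool_models()`): all reactions and metabolites are
   pooled into one single-compartment "supra-organism" network, ignoring
   any separation between cells.  Reactions with identical stoichiometry
   are consolidated to one copy; each organism's biomass reaction is kept,
   so per-species growth remains readable inside the pooled network.
3. **Costless secretion** (`run_costless()`): organisms are simulated
   separately on a shared medium; metabolites secreted at an optimal (or
   sampled) flux state — i.e. at no growth cost — are added to the medium,
   and the loop repeats until the medium is stable.

## Conventions and tunable parameters

* **Sign convention.**  Every exchange reaction is written export-positive
  (`met ->`); an uptake capacity of $c$ mmol gDW$^{-1}$ h$^{-1}$ means a
  lower bound of $-c$.  This matches the dominant SBML/fbc usage and is
  applied uniformly: `apply_diet()` writes caps into exchange lower bounds
  and leaves secretion unconstrained.
* **"Unbounded" fluxes** are encoded as $\pm 1000$ mmol gDW$^{-1}$ h$^{-1}$,
  the conventional box used by constraint-based tooling.  Keeping every
  bound finite guarantees a bounded polytope, which the sampler requires;
  genuinely infinite bounds are accepted by the LP layer but rejected by
  the sampler with an instruction to cap exchanges.
* **Pairwise threshold $\delta$** (default 0.10): an organism counts as
  growing *faster* in co-culture when its growth exceeds
  $(1+\delta) \times$ its mono-culture growth, *slower* below
  $(1-\delta)\times$.  The label pair maps onto six motifs (mutualism,
  commensalism, neutralism, amensalism, parasitism, competition).  When
  mono-culture growth is exactly zero the relative rule is undefined; the
  organism counts as faster only above an absolute floor of $10^{-6}$
  h$^{-1}$.
* **Basal growth** (default fraction 0.1): before sampling, each organism's
  biomass flux is bounded below by 10% of its mono-culture FBA optimum,
  excluding zero-growth states from the sampled polytope.  This is why
  community growth ratios of a pair whose co-culture FBA optimum equals the
  summed mono-culture optima span exactly 10–100% of the FBA value.
* **Sampler defaults**: 1000 samples at 200 steps per point, warmup
  $\max(1000, 10k)$ steps for a $k$-dimensional polytope.  Warmup and the
  thinning interval are declared choices; results in this package are
  insensitive to doubling either on all shipped fixtures.
* **Solver tolerances**: feasibility and optimality $10^{-9}$; activity
  threshold for comparing alternate-optima supports $10^{-6}$.
* **Secretion floor** $\varepsilon_{sec} = 10^{-6}$ mmol gDW$^{-1}$
  h$^{-1}$: anything below LP noise is not secretion.  Threshold modes for
  sampled secretion: *any* (> 0 of samples), *most* (strictly > 50%; 750
  of 1000 qualifies, 500 of 1000 does not), *all* (every sample).
  Newly added media metabolites default to an uncapped (1000) uptake.

## Linear programming core

`commflux` carries its own LP core: a dense bounded-variable two-phase
revised simplex (`commflux:::lp_solve`) using Bland's rule throughout.
Owning the solver keeps every numerical decision (pricing, tie-breaking,
tolerances) inspectable and identical across platforms.  Bland's rule
is slower than Dantzig pricing but cannot cycle, which makes the solver's
behavior on the degenerate optima that pervade metabolic networks fully
deterministic — the property every protocol above relies on.  Equality rows
are native (steady state), inequalities enter through slack variables, and
artificial variables with pinned bounds keep redundant rows harmless.  The
solver distinguishes infeasible from unbounded outcomes, and the test suite
cross-checks it against an independent interior-point/simplex implementation
(SciPy's HiGHS interface) on randomized bounded LPs.  At the package's toy
scale (tens to a couple of hundred variables) each solve is milliseconds.

## Flux sampling

`sample_fluxes()` runs artificial-centering hit-and-run (ACHR) over a
null-space parameterization.  Variables pinned by their bounds (e.g. a
shut-off organism) are eliminated first; an orthonormal basis $N$ of the
null space of the remaining columns of $S$ (SVD, relative rank tolerance
$10^{-10}$) turns the equality constraints into coordinates: every chain
position $v = v_0 + N\alpha$ satisfies $Sv = 0$ to one matrix product's
rounding, so feasibility error cannot accumulate along the chain.  The
start point $v_0$ maximizes the uniform margin to all non-fixed bounds (a
Chebyshev-center-like LP).  During warmup, directions are isotropic in the
null space; afterwards they pass through the running center and a stored
previous point, which adapts proposals to the polytope's shape.  Degenerate
line searches (on faces) count as zero-length moves, so a zero-volume
polytope correctly yields its unique point.

The target distribution — uniform on the polytope — is what matters for
every downstream claim; the particular MCMC kernel is interchangeable, and
hit-and-run was chosen because it is verifiable at desk scale: on a
one-degree-of-freedom cycle fixture the sampled flux must be uniform on its
interval, and the suite checks this with a Kolmogorov–Smirnov test at
$n = 1000$, significance 0.01, alongside a hard 100%-feasibility
postcondition on every emitted sample set.

Chains are seeded deterministically (`seed`, plus `seed + iteration` inside
the costless loop), so all sampling results are bit-reproducible.

## The pairwise protocol and two places it is underdetermined

The protocol is: join two models through the lumen, apply the diet, obtain
each organism's mono-culture growth with the partner shut off (all its
bounds zeroed), obtain co-culture growths with both active, classify with
the $\delta$ rule.  Two steps admit more than one reading, and the package
had to commit:

**Co-culture FBA reading.**  Optimizing each organism's biomass in its own
LP ("separate") can never register a growth *reduction*: the partner's open
network is a strict superset of its shut-off version, so each co-culture
optimum dominates the mono-culture optimum.  Under that reading,
competition, amensalism and parasitism are unreachable by construction —
yet antagonistic outcomes are the empirically dominant FBA prediction for
gut-microbe pairs.  The default (`co_mode = "joint"`) therefore maximizes
the *summed* community growth, then resolves the (typically degenerate)
optimal face deterministically by maximizing the smaller of the two growths
at the fixed optimal sum.  This equitable point expresses resource
conflict: on a shared substrate the joint optimum splits it, and both
organisms read as slower.  The separate reading remains available
(`co_mode = "separate"`) and is itself tested for its superset property.

**Sampling-mode reference growth.**  Classifying each co-culture sample
against a *fixed* mono-culture summary (median or FBA optimum) misreads
wide growth distributions: when co-culture and mono-culture distributions
are identical — the no-interaction case — roughly a quarter of samples land
in each faster/faster, faster/slower, slower/faster, slower/slower corner,
and the modal call becomes parasitism for a pair that interacts in no way.
The default (`reference = "quantile"`) compares each co-culture sample to
the mono-culture growth at the same rank, i.e. it compares distributions
quantile-by-quantile.  Identical distributions then read as unchanged,
uniformly shifted distributions read as faster/slower at every quantile,
and the per-sample calls vary meaningfully with growth rate — which is what
the regime maps (`build_regime_map()`) display, binning co-culture growths
into quantile bins (default 20 per organism, modal call per cell, ties
broken by a fixed type order).

## Lumped analytics

* `iterative_biomass_optimization()`: one FBA per biomass reaction with all
  others free.
* `optimal_community_growth()`: the max-min growth $g^\* = \max g$ s.t.
  $v_{bio,k} \ge g$ for every organism — one LP with an auxiliary variable;
  the constrained model raises every biomass lower bound to $g^\*$ for
  community-constrained sampling.
* `pathway_flux_summary()`: per reaction, $|v|$ normalized by the maximum
  $|v|$ that reaction attains across the two compared conditions (so both
  axes live in $[0,1]$), then medians within subsystem across reactions and
  observations.  Per-reaction (not per-subsystem) normalization was chosen
  so a single high-flux reaction cannot rescale its whole subsystem.
* `reaction_divergence()`: bidirectional Kullback–Leibler divergence per
  reaction from histograms on 30 shared equal-width bins spanning the
  pooled range, additive pseudocount 1 per bin, natural log.  With $n =
  5000$ points per side this estimator recovers the analytic symmetrized
  divergence of $N(0,1)$ vs $N(1,1)$ (exactly 1 nat) to within $\pm 0.2$,
  and it is monotone in distributional separation; both properties are
  frozen into the suite.  The low/medium/high classes cut the summed
  divergence at 0.05 and 1.0 — declared defaults, since no canonical
  thresholds exist.  Degenerate (zero-spread) pairs compare as point
  masses.
* `flux_sum()`: $\Phi_i = \tfrac12 \sum_j |S_{ij} v_j|$, the steady-state
  turnover rate of metabolite $i$ (the literature-standard definition);
  medians across samples are reported.

A qualitative contract worth stating: on a fixture with a side pathway that
contributes nothing to biomass, FBA pins the pathway at zero while sampling
reports a positive median flux — growth maximization systematically hides
flux the polytope allows.  The suite reproduces this on a toy conversion
pathway.

## Synthetic data: what the toys emulate, and what they do not

`make_toy_microbe()` expands a small declarative spec into a mass-balanced
network: sugar import (transporter capacity = `uptake_cap`, default 10
mmol gDW$^{-1}$ h$^{-1}$), a fermentative route (yield `anaerobic_yield`
biomass precursors per substrate, secreting declared byproducts), an
oxygen-consuming respiratory route at higher yield where
`aerobic_yield > anaerobic_yield` (the oxygen stoichiometry is the
mass-balancing degree of freedom), optional salvage of a partner's
byproduct, optional growth-free conversion routes, polymer ("fiber")
degradation for designated degraders, and a single biomass drain.  Every
non-exchange, non-biomass reaction conserves a declared metabolite mass
vector — `check_mass_consistency()` asserts this for every generator.

Diet analogs: the sugar diet supplies the monosaccharides directly (10
each); the fiber diet supplies only a 4-mer polymer that must be degraded
intracellularly, so non-degraders starve on it.  The oxygen cap encodes the
aerobic/anaerobic state.

`make_crossfeeding_pair()` engineers one pair per interaction motif such
that the pairwise protocol provably returns that motif — the recipes
(reciprocal salvage for mutualism, shared capped substrate for competition,
carbon diversion through an altruistic conversion route for parasitism,
yield-asymmetric byproduct compensation for amensalism) are documented on
the function and verified by hand-solved LPs in the suite.
`make_capped_crossfeeding_pair()` caps both biomasses at their mono-culture
optimum, making cross-feeding invisible to FBA but available to sampling:
the reference fixture for growth-ratio envelopes.
`make_community()` wires random byproduct-to-salvage edges at a stated
density, seeded and reproducible.

What the toys deliberately do **not** emulate: real taxa, gene–protein–
reaction rules, realistic diet compositions, thermodynamic or enzyme-
capacity constraints, and network scale (tens, not thousands, of
reactions).  Passing tests therefore demonstrate that the *methods* behave
as specified on networks whose ground truth is provable — not that any
biological conclusion about a real community transfers.

## Numerical and degenerate-input choices

* Alternate optima are enumerated by iteratively forcing members of
  previously seen active sets to zero and re-solving, breadth-first in
  reaction order — an LP-only exclusion scheme with deterministic output
  order, capped by `max_solutions` and an LP budget.
* Pooling consolidates reactions with identical stoichiometry after id
  canonicalization, ignoring bounds; merged bounds take the interval hull
  (the widest feasible box).  Biomass reactions are never consolidated.
* Organism tagging reserves the `__` delimiter (SId-safe); clonal pairings
  append copy indices.
* Zero mono-culture growth, empty polytopes, unbounded boxes, degenerate
  sample distributions and zero FBA denominators each have an explicit,
  tested behavior (absolute growth floor, infeasibility error, capped-
  exchange error, point-mass comparison, `NA` ratios respectively).

## Problem sizes used in the shipped checks

The suite runs entirely on generated fixtures: microbes of 8–15 reactions,
joined pairs of ~35–45 reactions, sampling chains of 200–500 samples for
unit checks and 1000 samples at 200 steps per point where a distributional
claim is asserted (uniformity, growth-ratio envelopes, modal motif calls).
These sizes keep every expected value computable by hand or by exhaustive
reasoning while exercising the same code paths a real GEM would.

## Known limitations

* The simplex is dense; beyond a few hundred reactions a sparse
  factorization-based backend would be needed (the LP layer is one function
  behind which such a backend can be swapped).
* Hit-and-run mixes slowly on strongly elongated or nearly degenerate
  polytopes; diagnostics (`convergence_diagnostics()`) are advisory, not a
  proof of convergence.
* Costless-secretion competition labeling uses a flux test (shared uptake
  of a capped metabolite in the final iteration), one of several defensible
  operationalizations.
* The lumped construction pools without abundance weighting; proportional
  pooling is out of scope.
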