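---
title: "Entropic flux balance analysis of synaptic and non-synaptic neuronal bioenergetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic flux balance analysis of synaptic and non-synaptic neuronal bioenergetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofba)
```

## The problem

Dopaminergic neurons of the substantia nigra are selectively vulnerable in
Parkinson's disease (PD), and a leading hypothesis ties that vulnerability to
bioenergetics: the synaptic terminal and the soma rely on mitochondria with
different enzymatic capacities, and PD is marked by reduced Complex I
activity and reduced dopamine release. `neurofba` provides a constraint-based
modeling workflow for studying these questions on compartment-specific
metabolic models: a strictly convex entropic flux balance solver with full
dual information, ATP-contribution accounting under energy-demand scans,
Complex I inhibition and substrate-sensitivity scans, classification of
control-versus-PD exchange-flux changes against cerebrospinal-fluid (CSF)
metabolomics directions, and single-reaction knockout/flux-forcing rescue
scans. A deterministic generator supplies a toy dopaminergic-neuron network
in four variants (synaptic/non-synaptic x control/PD) that serves as the
workflow's test bed.

## The entropic flux balance model

A metabolic model consists of a stoichiometric matrix split into internal
(`N`) and exchange (`B`) columns, flux bounds `l <= v <= u`, optional
flux-coupling rows `C v <= d`, and a metabolite accumulation right-hand side
`b` (zero at steady state). Every internal reaction is split into strictly
positive forward and reverse unidirectional fluxes, `v = vf - vr`, and the
fitted flux distribution minimizes

```
g * (vf' log vf + vr' log vr) + ce' w + 1/2 (v - h)' H (v - h)
subject to   N (vf - vr) + B w = b,   C (vf - vr) <= d,   l <= [v; w] <= u
```

with entropy weight `g = 2` by default, an optional linear coefficient `ce`
on exchange fluxes, and an optional diagonal quadratic penalty pulling named
reactions toward target fluxes `h`. The objective is strictly convex in
`(vf, vr)`, so the unidirectional fluxes are unique, and the solution cannot
contain thermodynamically infeasible cycles. The dual variable of each
mass-balance row, `y_N`, prices the marginal objective cost of that
metabolite's steady state and is interpreted as its chemical potential;
bound and coupling duals are returned alongside.

### How the solver works

No convex-cone solver is required. Summing the two stationarity conditions
of any internal reaction cancels every term that enters `vf` and `vr` with
opposite signs, leaving `log(vf * vr) = -2`: at an optimum the unidirectional
fluxes always satisfy the *interior product law* `vf * vr = exp(-2)`,
independent of `g` and of the constraint set (the nonnegativity bounds on
`vf`, `vr` are never active because the entropy terms have infinite slope at
zero). Substituting `vf = (r + v)/2`, `vr = (r - v)/2` with
`r = sqrt(v^2 + 4 exp(-2))` reduces the problem to a smooth strictly convex
program in the net fluxes alone, with per-reaction objective derivative
`(g/2) log(vf/vr)` and curvature `g/r`.

The reduced problem is solved by a dense primal-dual interior-point method:
coupling rows become equality rows with nonnegative slacks, bound
multipliers are iterated explicitly with fraction-to-boundary steps, and the
barrier parameter tracks the average complementarity gap. Two numerical
details matter on biochemical networks:

* conserved moieties (ATP/ADP, NAD/NADH, FAD, the quinone pool) make
  mass-balance rows linearly dependent; an independent row subset is
  selected by QR factorization and the final iterate is checked against the
  full row set;
* once the complementarity gap is small, an active-set polish pins the
  clearly active bounds and re-solves the now-interior problem, after which
  all duals are recovered in one least-squares step (stationarity must hold
  exactly on variables with inactive bounds, which determines `y_N`; active
  bounds absorb the remaining gradient gap as their multipliers). Rows
  untouched by any interior column — e.g. the boundary pools of uptake
  chains pinned at capacity — are gauged so that scarcity rents appear on
  the bound multipliers with valid signs.

Accepted solutions satisfy mass balance to `1e-8` and stationarity to
`1e-6`; `kkt_residuals()` re-derives all residual blocks from scratch and is
used in the test suite to gate every solve. Infeasible constraint sets are
diagnosed with an elastic feasibility program whose positive optimum
certifies infeasibility and names the most-violated balances. The same
machinery with a linear objective solves the flux-maximization problems of
`validate_core_functions()` (all default bounds are finite, so these LPs are
bounded).

```{r solver-example}
model <- build_toy_model(toy_spec("synaptic", "control"))
sol <- solve_entropic_fba(model)
glance(sol)
kkt_residuals(model, entropic_objective(), sol)
```

## The toy dopaminergic-neuron network

`build_toy_model()` deterministically constructs a ~55-reaction network
emulating the structure of condition-specific neuronal models: glycolysis
resolved into its canonical steps (with phosphoglycerate kinase and pyruvate
kinase as separate ATP-producing reactions), reversible lactate
dehydrogenase and lactate exchange, a reversible NADH shuttle, pyruvate
transport, a lumped citric acid cycle with a substrate-level phosphorylation
step and FADH2 production, the respiratory chain (Complex I with a capacity
bound, a Complex II FADH2 entry that bypasses Complex I, lumped Complex
III/IV consuming oxygen, ATP synthase driven by a proton-motive-force
pseudo-metabolite), the ATP maintenance demand, a dissipation demand served
by either a proton leak or a futile ATP-hydrolysis cycle, an ornithine
transaminase axis coupled to the urea cycle, amino-acid degradation lumps,
and — in synaptic variants only — a tyrosine-to-dopamine release branch with
vesicular ATP cost.

The PD overlay (`toy_pd_overlay()`) applies exactly three kinds of edits to
a control build: the Complex I capacity is scaled to 82% (the complement of
the smallest reported post-mortem activity reduction), the mandatory
dopamine-release minimum is quartered (synaptic only, following the striatal
dopamine concentration ratio), and the mandatory minimum uptakes of glucose
and oxygen are removed. The ATP maintenance bounds are 10.62 and 600
µmol/gDW/h: the lower value derives from the residual gray-matter energy
consumption (10 µmol ATP/g wet weight/min, times 60 min/h, times the dry
fraction 1 − 0.823 = 0.177, giving 106.2 µmol/gDW/h) reduced tenfold for the
rat-derived mitochondrial constraint basis; the upper value is a configured
constant. `derive_literature_constraint()` exposes this arithmetic. Note
that the wet-to-dry conversion *multiplies* by the dry-mass fraction — this
reproduces the published arithmetic as printed; a per-dry-weight rate would
physically call for division, and we deliberately reproduce the printed
convention rather than re-derive it.

### Fixture calibration

All remaining capacities are fixture parameters (`toy_params()`), not
literature values. They were chosen once so the network reproduces the
qualitative behaviour expected of the real condition-specific models, and
the choices are frozen and tested:

* **Oxidative-phosphorylation plateau.** Complex I capacities (6 synaptic,
  8 non-synaptic, µmol/gDW/h) are low enough that oxidative ATP production
  saturates near a demand of 60 µmol/gDW/h; above that, marginal demand is
  met glycolytically. In the demand scans the oxphos ATP flux rises by less
  than 5% from demand 60 to 100 while glycolytic ATP more than doubles.
* **Orderings.** The synaptic capacity is below the non-synaptic one, so
  the synaptic variants have a lower oxphos share at equal demand; the PD
  capacity factor 0.82 lowers the PD oxphos share against control; and the
  PD variants reach their Complex I inhibition inflection at an equal or
  smaller inhibition fraction than control.
* **Substrate sensitivity.** With oxygen withdrawn the quinone pool cannot
  be reoxidized, Complex I and II stall, and ATP synthase flux collapses to
  zero. With glucose withdrawn, lactate (and pyruvate/oxoglutarate) imports
  substitute the carbon and redox supply one-for-one; only the two
  substrate-level ATP per glucose are lost, and the mandatory glucose
  minimum is small (0.1), so ATP synthase flux changes by less than 10%.
  This is why glycolysis is resolved into individual steps: the marginal
  entropy cost of the longer chain keeps baseline glucose uptake small, so
  its removal perturbs little.
* **Anaerobic redox closure.** A pyruvate import (mandatory minimum 0.5)
  provides cytosolic pyruvate that is not paired with glycolytic NADH, so
  the mitochondrial NAD+ demand of the mandatory nitrogen pathways can be
  met through the reversed shuttle and lactate dehydrogenase even at zero
  oxygen.

### The rescue axis

The ornithine transaminase analog (`ORNTAm`) is the designed rescue target
and its surroundings are engineered so that the flux-increase scan recovers
it uniquely:

* `ORNTAm` lumps the transaminase with glutamate-5-semialdehyde
  dehydrogenase and the glutamate-dehydrogenase oxidation of both derived
  glutamates: ornithine + 3 NAD+ -> oxoglutarate (net) + 2 NH4+ + 3 NADH,
  with a basal minimum activity of 0.25. It competes with an ornithine
  decarboxylase/putrescine branch (ATP-coupled efflux) for a fixed
  ornithine uptake of 0.28, so forcing it reallocates nitrogen without
  changing total influx.
* The urea-cycle lump fixes two mitochondrial ammonium nitrogens per urea
  at a cost of 2 ATP. Because mitochondrial ammonium export is pinned at
  its ceiling, urea output is mechanically `a + const` in the transaminase
  flux `a`: forcing the transaminase raises urea excretion one-for-one.
* Under control conditions at mid-range demand the control model retains
  Complex I headroom, so the transaminase's NADH is worth more than the
  putrescine route's ATP saving and the control optimum runs the
  transaminase at its ornithine ceiling; in the PD variant, with Complex I
  saturated, it stays pinned at the basal minimum with a strict utility
  margin. Control urea excretion therefore exceeds PD urea excretion, and
  only a *direct* forcing of the transaminase — not nudges through akg,
  shuttle or pyruvate forcing — moves it. The rescue scans run at demand
  31 (non-synaptic) and 22 (synaptic), the mid-range demands at which this
  control/PD separation holds; they were chosen once from the capacity
  analysis above.
* Competitors are excluded structurally: the amino-acid uptake chains and
  the ornithine transport run at transport capacity (forcing them is
  infeasible); forcing the urea lump by 10% needs more nitrogen
  reallocation than the ornithine pool's slack allows (also infeasible);
  glutamate dehydrogenase is supply-pinned by the fixed histidine/glutamine
  uptakes; and fuel-route forcings (pyruvate, oxoglutarate, shuttle,
  respiratory chain) leave urea untouched because the nitrogen system is
  decoupled from them (lysine/methionine nitrogen is untracked for this
  reason).

In increase mode, exchange bounds are "relaxed to the generic bounds" — for
the toy these are its native bounds, so the relaxation is an identity — and
a diagonal quadratic penalty (weight 1) pins every exchange to its baseline
flux. Improvement calls are made against the penalty-pinned unforced
baseline, so a forcing factor of exactly 1 is neutral by construction.
Knockout mode instead sets both bounds of one reaction to zero and asks
whether ATP synthase and glycolytic ATP return to within 5% of control; the
designed fixture case is the proton leak, whose knockout reallocates the
dissipation demand to the ATP-hydrolysis route and frees proton-motive flux.

```{r rescue-example, eval = FALSE}
csf <- toy_csf_directions()
cfg <- rescue_config(mode = "increase", demands = 31, atps_id = "ATPS4mi",
                     csf_table = csf[csf$reaction_id == "EX_urea[e]", ],
                     tol = 1e-3)
scan <- increase_scan(build_toy_model(toy_spec("nonsynaptic", "pd")),
                      build_toy_model(toy_spec("nonsynaptic", "control")),
                      cfg)
scan[scan$overall, ]
```

## Exchange-change classification

Exchange fluxes follow the convention negative = uptake, positive =
secretion. `classify_exchange_change()` compares a control/PD flux pair at
an absolute tolerance of `1e-4` (four printed decimals): `same` within
tolerance; otherwise `lower_uptake`/`higher_uptake` on the uptake side,
`lower_excretion`/`higher_excretion` on the secretion side, and
`sign_change` for strictly opposite signs (not present in the published
tables but reachable with arbitrary models; it is evaluated permissively).
`consistency_call()` then maps CSF directions onto the change: a metabolite
increased in PD CSF is consistent with lower uptake or higher excretion, a
decreased one with higher uptake or lower excretion; entries with
conflicting reports match on either direction; `same` is not evaluable.
The packaged tables `csf_exchange_table()` carry the published 17-row
control/PD flux pairs for both components; applying the classifier
reproduces all 34 printed change and consistency labels, with six consistent
metabolites per component. Blocked entries (dopamine release disabled in
non-synaptic models) are reported as "No excrete" rather than classified.

For rescue triples, `classify_improvement()` uses the one rule that
reproduces all 15 published calls: energy improves when the rescued flux
exceeds the PD baseline (the PD baseline, not control — one published ATP
synthase row has PD above control and still counts as improved); an
exchange improves when the rescued flux moved from the PD baseline in the
direction of control, by more than tolerance on both legs, with overshoot
allowed.

## Count normalization and gene weights

`median_of_ratios()` computes per-sample size factors as the median, over
genes with all-positive counts, of the ratio of counts to the gene's
geometric mean across samples; zero-total genes are removed and genes with
any zero are kept in the output but excluded from factor estimation.
`gene_weights()` takes `log2` of the mean normalized expression with an
activity threshold of −3 (mean expression 0.125); the log2 scale for the
threshold is an assumption recorded here — the originating workflow does
not state the scale. One exact property worth noting: scaling one of `m`
samples by `c` changes its factor by `c^((m-1)/m)` and every other factor
by `c^(-1/m)`, because the geometric-mean reference itself moves by
`c^(1/m)`; relative factors change by exactly `c` and the normalized matrix
by the common factor `c^(1/m)`. The naive statement "the scaled sample's
factor changes by `c` and its normalized column is unchanged" holds only in
the large-`m` limit.

## Numerical choices and degenerate inputs

* Solver tolerances: feasibility `1e-8`, stationarity `1e-6`,
  complementarity gap `1e-10`; all reported to the caller and re-checked by
  `kkt_residuals()`.
* Reactions with bounds fixing the net flux (including to zero) stay in the
  problem; their unidirectional components still satisfy the product law
  and their bound duals absorb the stationarity gap.
* Dual gauge: duals of mass-balance rows made redundant by conserved
  moieties are determined up to the left null space; the least-squares
  recovery fixes a deterministic gauge, and the stationarity identity
  `g log(vf/vr) = 2 N' y` is asserted only where it is gauge-invariant
  (interior, unconstrained reactions).
* Demand scans report infeasible grid points as flagged rows; a model in
  which nothing produces ATP yields an explicit undefined-shares flag
  rather than a division error.
* Control toy variants carry a mandatory oxygen minimum, so near-complete
  Complex I inhibition is genuinely infeasible for them (the forced oxygen
  cannot be consumed); the full-inhibition identity (Complex I flux zero)
  is exercised on PD variants, whose overlay removes the minimum.
* The inhibition-scan inflection threshold (1% ATP-synthase drop) and the
  rescue slack (5%) are configurable report parameters.

## Problem sizes and what the tests show

The packaged analyses run at desk scale: the toy network has ~50
metabolites and ~55 reactions per variant, demand scans use grids of three
to ten points, and the rescue scans visit every internal reaction of the
toy PD variants. The test suite solves a few hundred entropic programs in
well under a minute. Passing tests demonstrate that the *methods* behave as
specified — unique thermodynamically consistent fluxes with verified
optimality certificates, correct classification logic against all published
rows, and parameter recovery of a designed rescue target on a network whose
ground truth is known. They do not demonstrate anything about genome-scale
models: the toy's capacities are calibrated constructs, its nitrogen
bookkeeping is deliberately simplified (no elemental balance, untracked
amino groups on two lumps), and the published absolute fluxes of real
condition-specific models are not reproducible without those models'
supplementary constraint sets.
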