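---
title: "Constraint-based modelling with gemflux: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling with gemflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemflux)
```

# The model

A metabolic reconstruction is a list of metabolites (with compartment `c`,
`p` or `e`, an optional elemental formula and charge), reactions (signed
stoichiometry, flux bounds in mmol·gDW⁻¹·h⁻¹, a GPR boolean rule, subsystem
and a 1–4 curation confidence), a gene list, and named biomass objectives.
The stoichiometric matrix S has one row per metabolite and one column per
reaction, so steady state is S·v = 0; flux balance analysis (FBA) maximizes
the biomass flux — the specific growth rate in h⁻¹ — over the polytope
`{S v = 0, lb ≤ v ≤ ub}`. Reversibility is encoded purely by a negative
lower bound; confidence values are metadata and never affect solving.

The assumptions are the usual ones for FBA and worth keeping in mind when
reading any result below: the cell is at metabolic steady state; the
objective of the organism is (proportional to) biomass production;
regulation and kinetics enter only through the bounds. Where those
assumptions bite, the expression-integration layer (below) is the corrective
the package offers.

## Media and maintenance

A `medium()` is a map of exchange-reaction bounds. At solve time all
exchange uptakes are first closed (lb = 0) and secretion opened (ub =
+1000), then the medium's entries are applied, so a medium fully determines
the boundary condition. Minimal media open each nutrient at
−30 mmol·gDW⁻¹·h⁻¹ — large enough that only the carbon source limits —
and anaerobic media force the O2 exchange shut. Non-growth ATP maintenance
(NGAM) defaults to 0.92 mmol·gDW⁻¹·h⁻¹ under oxic and 0.15 under anoxic
conditions, switchable per medium. NGAM is applied as a *floor*
(lb = NGAM, ub = 1000), the ATPM convention: a pinned maintenance flux
would leave the adenylate pool with no dissipation outlet and artificially
couple every ATP-producing flux to growth, which distorts, for example, the
storage-polymer demand sweep.

## Degenerate optima

FBA optima are typically degenerate: the objective value is unique, the
flux vector is not. Wherever a *representative* distribution is reported
(flux-ratio maps, substrate hierarchies), the package minimizes the total
absolute flux at the fixed optimal objective (a parsimonious, pFBA-style
tie-break, `parsimonious = TRUE`). The objective value itself always comes
from the plain FBA solve. Flux ratios are reaction flux divided by carbon
uptake, so the uptake reaction maps to 1.

# The linear-programming kernel

No LP library is assumed: the package carries a dense two-phase simplex for
box-bounded variables (shift to non-negative variables, explicit
upper-bound rows with slacks, artificials on the equality rows). The pivot
rule is Dantzig's most-negative reduced cost, switching to Bland's rule —
which provably cannot cycle — after a run of 40 degenerate pivots. Pivot
tolerance is 1e−9; after termination the basic values are re-solved from
the final basis by a dense QR solve, which brings ‖S·v‖∞ to machine
precision (the `flux_solution` contract asks for ≤ 1e−9). Infinite bounds
are clipped at ±1e6. The solver is dense and aimed at the small-to-medium
networks this package targets (tens to a few hundred reactions); it is
cross-checked in the tests against brute-force vertex enumeration on random
networks and against an independent tableau implementation on random
inequality problems. Inequality rows (used by the GIMME penalty problem and
the pFBA objective-fixing row) are converted to equalities with slack
variables.

# Screens built on FBA

**Source screening** follows the uptake scheme: candidate exchange at −10
mmol·gDW⁻¹·h⁻¹, every other nutrient of the minimal medium (including O2)
at −30, the default carbon source removed for C roles, ammonium removed for
N roles, both for C+N. "Grows" means growth above 1e−6 h⁻¹ — an absolute
threshold, chosen because the screening literature speaks of binary
growth/no-growth calls; the exact numerical cut is not critical and is
exposed nowhere as a tunable. Carbon-source growth is additionally divided
by the candidate's carbon count, which is how fatty acids reveal themselves
as the more efficient substrates per atom.

**Essentiality** closes every reaction whose GPR evaluates false under the
deletion (AND = all subunits required, OR = any isozyme suffices, orphan
rules always true) and re-solves. Essential means deletion growth below the
same absolute 1e−6 h⁻¹.

**Uptake fitting** inverts growth(uptake) by bisection on [0, u_max]
(default u_max = 50, 60 iterations, growth tolerance 1e−4 h⁻¹). Growth is
monotone non-decreasing in the uptake magnitude for these models, which the
bracket probe verifies implicitly: an unreachable target raises an error.

# Dynamic FBA

The batch simulation is the static-optimization scheme: at each step of
length Δt each tracked exchange i is capped at
`-min(|fixed uptake|, C_i / (X̄ Δt))`, FBA is solved, then
`X ← X·exp(µΔt)` and `C_i ← C_i + v_i·X̄·Δt`, with X̄ the within-step
*average* biomass `X·(exp(µΔt)−1)/(µΔt)`. Because the cap itself involves
X̄, the step iterates cap → solve → X̄ to a fixed point (tolerance 1e−12,
at most 50 passes; in practice 2–3). Two properties follow by construction:
concentrations never go negative, and the single-substrate batch matches
the closed-form exponential depletion exactly up to the grid step on which
the substrate runs out. The default configuration uses Δt = 1 h for 200
steps; the refinement test halves Δt and requires final biomass to move by
under 1%. When a substrate needed for maintenance runs out the LP becomes
infeasible and the run terminates with that status recorded; a culture that
merely stops growing is extended flat. Product toxicity is not modelled — a
documented, off-by-default shutoff hook halts growth above a user-set
nitrite concentration, because rate inhibition by nitrite is real biology
the steady-state formalism cannot express.

# Expression integration (GIMME)

A gene counts as unexpressed when its FPKM is below the first quartile of
the profile's values — computed genome-wide over every gene in the table,
not only model genes, because the quartile of a whole transcriptome is the
robust quantity (a `model_genes_only` switch supports sensitivity checks,
and the quantile itself is an argument, so cut-offs around the quartile can
be swept). The quantile uses linear interpolation between order statistics
(`stats::quantile` type 7), so `{1,2,3,4}` gives 1.75. Reaction-level
expression maps AND to min (a complex is limited by its scarcest subunit)
and OR to max (isozymes add capacity); genes without data are transparent,
and orphan or fully data-less reactions are never flagged — absence of
evidence is not evidence of absence.

Flagged reactions are not deleted outright. A penalty LP minimizes the
summed absolute flux through them subject to the objective keeping at least
a `required_objective_fraction` (default 0.9, the method's canonical
setting) of the parent optimum; only flagged reactions idle in that
solution are closed. The resulting condition model is re-solved and the
fraction asserted after every build.

# Flux sampling

`sample_flux_space()` is an artificially-centered hit-and-run walk. Warm-up
points are the coordinate minima and maxima of the polytope (2n LP solves);
directions are drawn as (random warm-up point − running center), which
keeps every step inside the null space of S exactly, and the step length is
uniform on the feasible segment of the box. Defaults: 1000 discarded
warm-up steps, thinning 100, and a mandatory seed — the chain is
deterministic given the seed. On a one-dimensional throughput segment the
samples are uniform, which the tests check against the analytic mean.

# Reconstruction utilities

Ortholog calling is reciprocal-best-hit: mutual best (lowest e-value,
identity as tie-break) with identity ≥ 40, coverage ≥ 80 — applied to both
query and subject, since the stricter reading is the safer ortholog call
and a switch relaxes it — and e-value < 1e−20. The separate GPR curation
filter uses the strict thresholds identity > 30, both-protein coverage
> 70, e-value < 1e−5. Draft projection rewrites each donor reaction's GPR
over the target's genes (unmapped genes deleted from the expression; an AND
losing a mandatory subunit becomes unsatisfiable, an OR drops dead
branches) and keeps the reaction iff the rule stays satisfiable; orphans
are carried as-is; reactions shared between donors merge once with their
GPRs OR-ed and a provenance tag.

Biomass coefficients come from sequence: amino-acid coefficients
proportional to residue frequencies across the proteome, dNTPs from genome
base composition on both strands, NTPs from the coding-strand composition
as a transcript proxy (an expression-weighted transcriptome can be
substituted). All residue masses are monomer minus water, so polymer mass
closure is exact by construction: each class's coefficient-weighted residue
mass equals its mass fraction × 1000 mg·gDW⁻¹. Default fractions (protein
0.55, RNA 0.205, DNA 0.031, lipid 0.095, murein 0.03, ions 0.01, soluble
0.079) are standard gram-negative values used when organism-specific
measurements are unavailable; a sphinganine precursor takes a 10% share of
the lipid class, reflecting a sphingolipid envelope without LPS, and
growth-associated maintenance (default 40 mmol ATP·gDW⁻¹) appends the
ATP + H2O → ADP + Pi term.

Uptake rates are regressed from time courses as the slope of C(t) against
the cumulative biomass integral ∫X dτ (trapezoidal), which is exact for a
constant specific rate and far more robust than two-point differencing; the
standard error comes from the regression. The producibility report adds a
transient demand per biomass precursor and maximizes it; a conserved-moiety
carrier such as ATP cannot be drained outright, so when the biomass
reaction pairs a precursor with a product of equal magnitude (ATP/ADP) the
demand returns the partner — a documented heuristic that makes the check
meaningful for currency metabolites.

# The synthetic toy network

The generator emulates the central metabolism the analyses assume: substrate
funnels delivering acetyl units plus reducing equivalents (a C4
3-hydroxybutyrate-like acid, a C10 dicarboxylate through β-oxidation, a C10
tetralin-like aromatic whose oxygenases cost 2 O2 per molecule, lactate,
and a glucose that deliberately lacks a transporter), a lumped TCA cycle,
the glyoxylate shunt as anaplerotic route (gene `aceA_toy`) plus an
alternative gluconeogenic condensation (`gcsA_toy`) so that
conditional-essentiality contrasts are expressible, oxidative
phosphorylation at P/O = 2, a nitrate-reductase branch yielding one ATP per
nitrate and secreting nitrite equimolarly, PHB storage with a demand
reaction, NGAM, and aerobic/anaerobic biomass reactions.

Chemistry uses three pseudo-elements — C, N and R (reducing equivalents) —
with exact integer bookkeeping, so internal reactions are elementally
balanced by construction and the balance checker has something real to
verify. Substrate formulas are *derived* from the funnel yields, so the
network stays balanced under any yield parameterization. The default yields
place the substrates in the qualitative order the analyses expect: the C10
fatty acid beats lactate per carbon (the lactate funnel carries no net NADH
and pays a 2-ATP activation cost, making it the energy-poor substrate), and
tetralin is the expensive substrate under O2 limitation. These contrasts
hold by construction; no numeric agreement with any real organism is
claimed for the toy, and passing tests on it demonstrate the *machinery* —
balance checking, LP correctness, GPR logic, bookkeeping — not the biology
of real genome-scale models, which differ in scale (1000+ reactions),
redundancy, and the messiness of curated formulas.

Expression profiles are generated genome-wide: several hundred background
genes fix the first quartile, condition-specific "off" genes sit far below
it and all other model genes safely above, so the GIMME flag set is exactly
the intended reaction set for any seed. Batch time courses are forward dFBA
runs plus Gaussian measurement noise.

# Problem sizes and runtime

The suite and the acceptance script run on: the 40-reaction toy model,
random networks of ≤ 8 reactions for vertex-enumeration cross-checks
(100 instances), 200-step anaerobic and 400-step fine-grained batch
simulations, 5000 hit-and-run samples on the 1-D segment, and 20 noisy
uptake-estimation replicates. These sizes were chosen so every check is
exact or statistically well-powered while a full run stays in the minutes
range on a single core; all of them scale up transparently when a
genome-scale model is supplied, with the caveat that the dense simplex is
the limiting factor well before memory is.

# Known limitations

- The LP kernel is dense; thousand-reaction models solve, but slowly.
  Swapping in a sparse or compiled solver behind `lp_solve()` would be a
  contained change.
- No flux variability analysis, MOMA/ROOM knockouts, or thermodynamic
  constraints — out of scope by design.
- The SBML reader targets Level 3 + fbc version 2 as written by this
  package and by the common COBRA exporters; exotic SBML (species
  references with units, local parameters) is not handled.
- dFBA uses fixed maximal uptake rates, not Michaelis–Menten kinetics, and
  no product inhibition beyond the optional shutoff hook.
- The toy network's pseudo-chemistry cannot surface real curation errors
  (wrong protons, charge imbalance across membranes); it verifies logic,
  not biochemistry.
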