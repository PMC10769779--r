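---
title: "Community flux balance prediction of butyrate production capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community flux balance prediction of butyrate production capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
```

`gutflux` turns 16S-derived taxon abundances plus per-species metabolic
models into a per-sample *butyrate production capacity*, and compares that
capacity between clinical responder groups across two visits. This vignette
is the package's own account of the method: the model and its assumptions,
the parameters that matter, what the synthetic data do and do not emulate,
and the design choices made where the design was genuinely open.

## From amplicons to a community model

An OTU representative sequence stands for a taxon. It is matched to the 16S
gene of a reference genome by exact Smith–Waterman local alignment with
affine gap penalties and BLASTN-like scores (match +2, mismatch −3, gap
open 5, gap extend 2). We deliberately use the exact algorithm rather than a
seeded heuristic: inputs at package scale are small, exactness makes the
operation testable against an independent dynamic-programming oracle, and
the two quantities the filters act on — percent identity and query
coverage — are algorithm-level definitions, not implementation artifacts.
Conventions worth stating because they change numbers:

* identity = 100 × matches / alignment columns, gap columns counted in the
  denominator (the BLAST convention);
* query coverage = 100 × aligned query span / query length;
* the ambiguity code `N` scores as a mismatch and never counts as a match —
  conservative and deterministic;
* both query orientations are aligned and the better-scoring one kept.

A hit survives if identity ≥ 97% and coverage ≥ 95%; among survivors only
hits within `1e-9` of the maximum identity are retained. When several
references tie at the maximum, each OTU must still feed exactly one model
downstream, so the lexicographically smallest reference id is assigned and a
warning is emitted; the ambiguity is visible in the mapping table
(`n_tied_hits`).

## Community assembly

Taxa with relative abundance strictly greater than 0.1% in a sample become
community members; their abundances are renormalised to weights summing
to 1. Renormalisation is a choice, not a given — dropping sub-threshold mass
without renormalising would shrink every weight — but the coupling below
requires weights on the simplex, so we renormalise and treat the excluded
mass as diagnostics (`dropped_mass`).

Member models are merged into one multispecies model with a shared
extracellular compartment, here called the **lumen**:

* internal metabolites and reactions get a `species|` prefix; lumen
  metabolites are pooled by id;
* member boundary exchange reactions are absorbed into a single community
  exchange per lumen metabolite, written `metabolite -> (out)` so that
  positive flux is outflow; its bounds are the element-wise widest member
  bounds (a lumen metabolite no member exchanges gets a closed `[0, 0]`
  exchange);
* each member's biomass flux is tied to one community growth variable:
  `v_biomass,i = w_i * mu`.

Two of these rules are the key modelling commitments. **Hard proportional
coupling** makes the community grow as a single unit at fixed composition:
a member that cannot grow on the available medium forces `mu = 0` for the
whole community. It is the scheme consistent with maximising a single
community biomass rate; alternatives (e.g. fixed-point growth balancing as
in SteadyCom) are out of scope. **Widest member bounds** for community
exchanges keep each member's own medium assumptions without inventing a
diet; the synthetic models set their exchange bounds explicitly, so in the
tested configurations the community medium is fully determined.

## Parsimonious FBA

Fluxes are predicted by a single LP. Each reaction flux is split into two
non-negative variables `v = v+ − v−`, making total absolute flux linear,
and the objective is

> maximise `mu − λ · Σ_j (v+_j + v−_j)`, λ = 1e-5,

subject to steady-state mass balance for every metabolite, the coupling
constraints, and bounds mapped onto the split variables. The penalty λ is
small enough that growth is never sacrificed on these models (the growth
loss is bounded by λ times the optimal total flux) yet breaks ties among
alternative optima in favour of minimal total flux; the test suite verifies
on a deliberately redundant toy network that the longer of two parallel
pathways carries zero flux. We keep the one-LP formulation (growth and
parsimony in a single objective) rather than the two-stage variant because
it matches the combined objective stated above exactly and is simpler to
reason about; λ ∈ {1e-3, 1e-5, 1e-7} convergence to the pure-FBA optimum is
part of the test suite.

The LP is solved with the GLPK simplex solver (`glpsol`), driven through
CPLEX-LP problem files and GLPK's plain-text solution files. Two low-level
conventions matter for correctness and are worth recording: IEEE negative
zero must be normalised before writing bounds (GLPK misreads `<= -0`), and
GLPK numbers solution columns by first appearance in the LP file, so every
variable is listed in the objective (zero coefficients included) to pin the
order. Cohort runs cache the weight-independent part of the LP text per
distinct member set, since only the coupling rows change between samples
with the same membership. The canonical per-sample path and this cached path
are verified equal in the tests. Solutions are accepted with mass-balance
and coupling residuals below `1e-8`.

The per-sample statistic is the **butyrate production rate**
`r = outflow(butyrate) / mu`. Degenerate cases are deliberate choices:
a community that grows but has no butyrate pathway has `r = 0`; a community
with `mu ≤ 1e-10` has an *undefined* rate (`NA`, excluded from statistics
and counted in diagnostics) because 0/0 is not evidence of absent
production. The community exchange flux is a *net* outflow: modelled
butyrate uptake by members, if present, is netted against production.

## Response labelling and the four tests

Response is a decrease of the Lichtiger clinical activity score (0–21) of
at least 50% from baseline V1 to week-4 V2, with baseline eligibility
requiring a score ≥ 4. The cohort comparison mirrors the two-panel design:
unpaired rank-sum tests of responders vs nonresponders at V1 and at V2
(each visit uses all samples with a defined rate — patients missing a V2
sample still contribute at V1 because the clinical response label does not
depend on the V2 *microbiome* sample), and paired signed-rank tests of V1 vs
V2 within each group (patients with both rates only).

Both tests are **permutation-exact under ties**: observations receive
mid-ranks, and the p-value enumerates all `choose(nx+ny, nx)` group
assignments (rank-sum) or all `2^m` sign assignments of the nonzero
differences (signed-rank), implemented by integer subset-sum dynamic
programming on doubled ranks. Zero differences are dropped, per the
classical Wilcoxon convention, and counted. Two-sided p-values double the
smaller one-sided tail, capped at 1 — the common exact-test convention.
Beyond 25 combined observations (rank-sum) or 20 nonzero differences
(signed-rank) the tie-corrected normal approximation with continuity
correction is used and flagged in the output (`method = "approx"`); at the
default cohort sizes all four tests are in this regime. No multiplicity
correction is applied to the four tests. The exact enumerations are tested
against brute-force oracles (explicit `combn`/sign enumeration) written
independently in the test suite.

## What the synthetic cohort emulates

The generator produces the study conditions end to end: 69 responders and
24 nonresponders sampled at V1 (93 samples), of whom 63 and 22 retain a V2
microbiome sample (85 samples); every patient keeps clinical scores at both
visits. Twenty species stand in for a genome catalogue, 40% of them
butyrate producers. Producer models hard-wire butyrate co-production to
growth (1 glucose → 1 biomass + 1 butyrate) so that composition shifts
translate deterministically into community butyrate capacity — the cleanest
testable mechanism for the hypothesis that producer enrichment drives
predicted butyrate. Per-species glucose uptake capacities are drawn
uniformly from [5, 15].

Abundances are Dirichlet on the simplex: V1 ~ Dirichlet(1) (a flat prior;
log-normal realism is explicitly not attempted), and V2 is a Dirichlet
drift centred on V1 with concentration 100 for *all* patients — on a 40%
producer share that is a standard deviation of roughly five percentage
points, a modest week-scale compositional change. Responders additionally
have 0.15 of absolute abundance mass moved proportionally from non-producers
onto producers. Because the drift is common to both groups, setting the
enrichment to zero yields a fully exchangeable null cohort — the property
the type-I-error simulations rely on. Lichtiger trajectories are generated
only to exercise the labelling rule (responders: V1 in 8–14, V2 =
⌊V1·(1−u)⌋ with u ~ U[0.5, 0.9]; nonresponders: u ~ U[0, 0.4] with a
ceiling); the floor/ceiling pair guarantees the label matches the group,
and no clinical realism is claimed. OTU representatives are the reference
sequences (random 250-nt stand-ins) mutated at 1% per site, which keeps
them above the 97% identity threshold by construction.

What passing tests therefore show: the pipeline recovers a planted
composition→capacity effect through mapping, merging, LP and testing, and
holds its error rate on null cohorts. What they do not show: robustness to
real 16S features (sequencing error, chimeras, copy-number variation,
phylogenetic structure), to gap-filled draft metabolic models, or to real
diet-dependent media — none of which the toy generator emulates.

## Numerical choices and problem sizes

* Solver residual tolerances: invariants asserted at `1e-8` (mass balance,
  coupling, single-member equivalence); identity ties at `1e-9`; abundance
  sums accepted within `1e-6` and renormalised exactly.
* All randomness flows from one seed through named streams
  (species/cohort), so simulate-and-run is byte-deterministic at a fixed
  seed; two serialisations of the same model are byte-identical (sorted
  keys, full-precision numbers).
* Simulation sizes used by the test suite, chosen to give stable checks at
  desk scale: 100 random communities for the conservation suite; 1000
  mutated OTUs for mapping recovery (binomial check at ≥ 99%); 200 null
  cohorts for the type-I check, with the empirical rejection rate required
  to fall inside the binomial 99% confidence band around α = 0.05 for that
  number of cohorts; 50 planted cohorts for effect recovery (signed-rank
  p < .05 within responders in ≥ 90% of cohorts, ≤ 10% within
  nonresponders, responder median increase in every cohort).

## Known limitations

Hard proportional coupling cannot express facultative cross-feeding
equilibria; the widest-bounds medium is permissive rather than curated; the
exact tests switch to the normal approximation at the default cohort sizes
(inherent to exactness, and flagged per test); assignment of an OTU tied
between references is deterministic but arbitrary; and absolute flux units
are conventional (mmol·gDW⁻¹·h⁻¹ scale) with no unit conversion — the
butyrate production rate is a ratio and is interpreted as relative capacity,
not as an absolute secretion measurement.
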