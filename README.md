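# gutflux

Predicting the butyrate production capacity of gut microbial communities
from 16S amplicon data and genome-scale metabolic models, and testing how
that capacity changes in a two-visit patient cohort.

## The problem

Butyrate, a short-chain fatty acid made by gut bacteria, feeds the colonic
epithelium and dampens mucosal inflammation; loss of butyrate producers is a
recurring feature of ulcerative colitis. 16S rRNA sequencing tells you *who*
is in a stool sample but not *what the community can do*. `gutflux` closes
that gap with community flux balance analysis: each taxon in a sample is
matched to a species-level metabolic model, the member models are merged
into one abundance-weighted multispecies model, and the community's maximal
butyrate output per unit of growth is computed by linear programming. Applied
to a cohort sampled before (V1) and after (V2) a course of therapy, the
per-sample capacities feed exact nonparametric tests comparing clinical
responders with nonresponders.

The package is written for microbiome researchers who want the complete
chain — OTU mapping, community model construction, parsimonious FBA, and the
longitudinal statistics — as small, composable, tested functions operating on
tibbles and plain-text formats (FASTA, TSV, JSON), with a synthetic-data
generator so the entire pipeline runs and is testable without any external
download.

## The model

Per sample, with member species *i* at relative abundance *w_i* (taxa at
or below 0.1% abundance are excluded, survivors renormalised to sum to 1):

* Members share one extracellular **lumen** compartment; species internals
  are namespaced. One community exchange reaction per lumen metabolite
  controls in/outflow, with bounds as the widest member bounds.
* Each member's biomass flux is hard-coupled to a single community growth
  variable μ in proportion to abundance: *v*_biomass,*i* = *w_i* · μ.
* Fluxes solve the **parsimonious FBA** linear program
  (absolute values handled by splitting each flux into v⁺ − v⁻):

  maximise μ − 10⁻⁵ · Σ_j (v⁺_j + v⁻_j) subject to S·(v⁺−v⁻) = 0,
  v_biomass,i = w_i·μ, and the flux bounds.

* The **butyrate production rate** is r = (butyrate outflow) / μ.

OTU representatives are matched to reference 16S genes by exact local
alignment (Smith–Waterman, affine gaps, BLASTN-like scores) with ≥97%
identity and ≥95% query coverage; among multiple hits only maximum-identity
hits are retained. Response is a ≥50% drop of the Lichtiger score from V1 to
V2; the cohort comparison uses exact Wilcoxon rank-sum tests (responders vs
nonresponders at each visit) and exact Wilcoxon signed-rank tests (V1 vs V2
within each group).

## Worked example

```r
library(gutflux)

# a toy butyrate producer: glucose -> biomass + butyrate, uptake capacity 10
s1  <- producer_model("S1")
sol <- solve_pfba(formulate_pfba(build_community(list(s1), weights = 1)))
sol$mu                    # 10      (community growth rate)
sol$fluxes[["EX_but"]]    # 10      (butyrate outflow)
sol$objective             # 9.9995  (mu - 1e-5 * total |flux| of 50)
butyrate_rate(sol)        # 1       (outflow / mu)

# half producer, half non-producer sharing the glucose pool
s2 <- nonproducer_model("S2")
pair <- solve_pfba(formulate_pfba(build_community(list(s1, s2), c(0.5, 0.5))))
butyrate_rate(pair)       # 0.5

# a full synthetic cohort: simulate inputs, run the pipeline, read the tests
dir <- tempfile()
pipeline_simulate(sim_config(seed = 1), dir)
run <- pipeline_run(dir)
run$result$tests
#> # A tibble: 4 x 5
#>   test             statistic  p_value     n method
#>   <chr>                <dbl>    <dbl> <int> <chr>
#> 1 rs_V1                  847 8.71e- 1    93 approx
#> 2 rs_V2                 1096 5.38e- 5    85 approx
#> 3 sr_responders         2016 5.29e-12    63 approx
#> 4 sr_nonresponders       109 5.81e- 1    22 approx
```

The four rows are the cohort's statistical design: at baseline responders
and nonresponders are indistinguishable (`rs_V1`, p = .87), after therapy the
responders' communities have a higher predicted butyrate capacity (`rs_V2`),
driven by a within-responder V1→V2 increase (`sr_responders`, p ≈ 5e-12)
that is absent in nonresponders (`sr_nonresponders`, p = .58) — the planted
effect of the simulated cohort, recovered through the whole mapping →
merging → LP → testing chain. `tidy()`, `glance()` and `autoplot()` methods
summarise and plot a cohort result; `inst/scripts/gutflux.R` exposes
`simulate` / `run` / `report` subcommands for shell use.

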