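---
title: "Methods: trait indices, growth-form classification and trait-environment models for grazed grasslands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait indices, growth-form classification and trait-environment models for grazed grasslands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasslawns)
```

## The problem this package addresses

Frequent grazing can push a grass community toward a *grazing lawn* — a
short, leafy, high-forage-value sward maintained by positive feedbacks with
grazers — or toward *overgrazing*: loss of basal cover, spread of unpalatable
species, and bare ground. Which outcome occurs depends on grass life history
strategies and on environmental context (rainfall, soil texture and
fertility). This package implements, as a tested and reusable pipeline, a
trait-based workflow for quadrat surveys of frequently grazed grass
communities:

1. **Trait indices** — four species-level indices from field records.
2. **Growth-form classification** — hierarchical clustering on principal
   components (HCPC) of the indices, with v-test cluster description.
3. **Fourth-corner trait–environment modelling** — a binomial GLM linking
   dominant-species presence to trait × environment interactions, with AICc
   subset selection and a site-block resampling ANOVA.
4. **Environmental ordination** of sites with interpolated growth-form cover
   surfaces.
5. **Bare-ground regressions** — degradation risk as a function of rainfall,
   sand and a dung-based grazing-pressure proxy, split by whether lateral or
   tufted attractor grasses dominate.

A seeded synthetic survey generator with ground truth makes every stage
testable without field data.

## Data model

A survey is three tables. `observations` holds one row per species per
quadrat: percent aerial cover, median leaf table height (mm; the visually
assessed ~80th quantile of leaf biomass), culm orientation (six ordered
categories from `lateral` to `upright`, including the two hybrid codes
`geniculate-lateral` and `geniculate-upright`), stolon presence, rhizome
class (`none`/`short`/`long`) and a tufted-base flag. `meta` holds per-quadrat
percent bare ground and dung presence. `sites` holds mean annual rainfall
(mm/yr), percent sand, cation exchange capacity (cmol(+)/kg) and pH.
Validation is total: every out-of-range value, enum violation or dangling
reference is reported with its row and field; nothing is silently coerced.
Summed species cover within a quadrat may exceed 100% because canopies
overlap; only per-species cover is bounded. Sites with fewer than 15 quadrats
(the study protocol's minimum) warn rather than fail.

The tufted-base flag is stored as an explicit observation and is *not*
derived from short rhizomes, although short rhizomes are defined as
tuft-building; keeping the raw observation and the derived index separable
lets users adopt either convention upstream.

## The four trait indices

For each species, over all its quadrat records across all sites:

* **Culm orientation index** — mean of the ordinal codes
  lateral = 1, geniculate-lateral = 2, geniculate = decumbent = 3,
  geniculate-upright = 4, upright = 5. Range [1, 5].
* **Lateral index** — proportion of records with stolons or long rhizomes
  (vegetative lateral spread). An exact fraction k/n of the record count.
* **Tuft index** — proportion of records with a tufted base.
* **Grazer use index** — for each record, the ratio r of leaf table height to
  the *site-level median* height (over all species × quadrat records at the
  site, each record counting once, unweighted); ratios above 1 are
  reciprocated (r → 1/r); the index is the flat mean of transformed ratios
  over all the species' records pooled across sites. It lies in (0, 1]:
  species sitting at the site median — where grazer use is assumed maximal —
  score 1, and both much-taller (accessible but unused) and much-shorter
  (inaccessible) species score low.

Two conventions were genuinely open and are fixed here: the site median is a
flat median over records (not cover-weighted, not per-species first), and
records at exactly the median (r = 1) are left at 1 — the reciprocal rule
applies strictly to r > 1. Species pooled across sites use a flat mean over
records, not a mean of site means. These choices give the index two exact
invariances that the test suite checks as properties: rescaling all heights
at a site by any positive constant changes nothing, and records at ratio r
and 1/r contribute identically.

Species occurring in more than 10 quadrats are `clustered`; rarer species
are assigned to growth forms via a manual override table, because including
them in the formal clustering destabilises the clusters.

## Growth-form classification (HCPC)

The clustered species' four indices are range-standardized to [0, 1], then
decomposed by PCA. PCA is run centred *and* unit-variance scaled by default
(correlation-matrix PCA, the default of the procedure this workflow
follows); a flag switches to covariance PCA. All four components are
retained — with four variables, truncation would be an extra assumption.
Sign indeterminacy is resolved deterministically: the largest-magnitude
loading of each component is made positive.

Ward's minimum-variance agglomeration is then run on the PC scores
(squared-Euclidean Lance–Williams update; heights on the distance scale,
i.e. the modern "Ward.D2" behaviour). The tree is cut into k groups
(default k = 4, the ecologically interpretable cut; k is a parameter, not an
automatic criterion). Merge ties have probability zero for continuous PC
coordinates; the implementation is deterministic for a fixed input order,
and an exhaustive-search oracle test verifies the merge sequence for small
n. The optional k-means consolidation step some HCPC implementations apply
after the cut is deliberately not applied.

Each cluster is described by a **v-test** per trait:

$$v = \frac{\bar x_k - \bar x}{\sqrt{\frac{s^2}{n_k}\,\frac{N-n_k}{N-1}}}$$

where $\bar x_k$ is the cluster mean, $\bar x$ and $s^2$ the overall mean
and *population* variance of all N clustered species, and $n_k$ the cluster
size — the denominator is the standard deviation of the mean of a random
size-$n_k$ subset drawn without replacement. Two-sided p-values use the
standard normal reference; the v statistic itself is the primary quantity,
since the reference distribution convention (normal vs t) is not decisive
for description.

With k = 4 the clusters are mapped onto the four named growth forms by
their v-test signatures, claimed greedily in a fixed precedence order:
**lateral attractor** (highest lateral-index v), **resister** (highest
culm-orientation minus grazer-use v), **tufted attractor** (highest tuft
plus grazer-use v), **avoider** (remainder; lowest grazer-use plus tuft).
Near-ties are flagged `ambiguous` rather than silently resolved.

## Fourth-corner trait–environment model

For each site, the community is reduced to the *minimal 90%-cover set*: the
shortest descending-cover prefix of species whose cumulative share of total
site-mean cover reaches 90% (ties alphabetical; the share is relative to
summed cover, the only well-defined reading when summed cover differs from
100%). These dominant species are scored present/absent, giving the L
matrix; R is the standardized site × environment table and Q the
standardized species × trait-index table.

One binomial (logit) GLM is fitted to the vectorized L:

$$\mathrm{logit}\,P(y_{ij}=1) = \alpha_j + \mathbf{e}_i^\top \boldsymbol\gamma
 + \sum_{q,e} t_{jq}\, b_{qe}\, e_{ie}$$

species intercepts $\alpha_j$, environment main effects $\boldsymbol\gamma$,
and the 4 × |env| fourth-corner coefficients $b_{qe}$. Trait main effects
are species-constant and therefore absorbed by the species intercepts.
Fitting is plain maximum likelihood by IRLS — no LASSO penalty, because AICc
comparison across environment subsets presumes likelihood-based fits; on
complete separation the fit falls back to a lightly ridge-penalised IRLS
(λ = 0.01) with a warning. All 15 non-empty subsets of
{rainfall, sand, CEC, pH} are fitted and ranked by
$AICc = -2\log L + 2p + 2p(p+1)/(n-p-1)$ with n the number of site × species
cells; a species-intercepts-only model anchors the ladder as a reference but
does not compete for "best".

The overall trait–environment interaction is tested by a **site-block
resampling ANOVA**: the observed statistic is the likelihood-ratio deviance
between the models with and without all trait × environment terms; the null
distribution re-pairs whole sites' species blocks with resampled environment
rows, refitting both models each iteration (999 by default), and
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$. The default re-pairing
is a permutation of sites, which is exchangeable under the null hypothesis
of no trait–environment association and therefore yields a calibrated test —
the property the suite verifies by simulation; drawing sites with
replacement is available as `method = "bootstrap"`. The published workflow's
PIT-trap residual resampling is under-specified at this level of detail;
exact equivalence to it is explicitly not claimed, only the same block
structure (sites) and iteration count.

## Ordination and cover surfaces

Sites are ordinated by correlation-matrix PCA of the four environment
variables. Per-site growth-form cover is the mean over quadrats of the
summed per-species cover of each form's species — *all* species at the site,
not just the 90% set, and absolute cover, not relative composition (absolute
cover interacts correctly with bare ground and has a meaningful 0 floor).
Cover is interpolated across the first two ordination axes by
piecewise-linear barycentric interpolation on a Delaunay triangulation of
the site scores (built directly by the circumcircle criterion — O(n⁴), ample
for tens of sites), evaluated on a grid_n × grid_n grid restricted to the
convex hull. The method is parameter-free, exact at the sites, and bounded
by the observed cover extremes — chosen precisely to avoid the extrapolation
artifacts smooth-spline surfaces can produce. No extrapolation outside the
hull: unsampled environmental space stays `NA`. Contour levels run from 0 in
10-percent-cover steps.

## Bare-ground analyses

Sites are split by dominance — whichever of the lateral-attractor or
tufted-attractor forms has greater cover (exact ties are flagged and
excluded) — and mean bare ground is compared between groups by a standard
one-way F on (1, n − 2) df. Within each group, percent bare ground
(untransformed, as recorded) is regressed on mean annual rainfall, percent
sand and the proportion of quadrats with dung (a site-level grazing-pressure
proxy). Every sub-model of the three-way factorial that respects marginality
(an interaction only ever appears with its main effects) is fitted by OLS
plus the intercept-only model, and ranked by Gaussian AICc with the residual
variance counted as a parameter. Sub-models violating marginality are not
enumerated — "all nested models" is read as the standard hierarchy-respecting
lattice. A known statistical consequence, verified by simulation during
development: with 18 non-null candidates at n ≈ 20, the intercept-only model
wins on pure noise only about two thirds of the time — multiplicity, not a
defect of AICc.

## The synthetic survey generator

`simulate_survey()` emulates the survey's generative structure with study
conditions as defaults: 33 sites × 30 quadrats (minimum 15 enforced),
rainfall 336–987 mm/yr and sand 44–93% gradients (CEC 1–30 cmol(+)/kg,
pH 4.5–8.5), a 60-species pool in four archetypes whose latent index
distributions qualitatively mirror the four growth forms. Species occurrence
follows the same fourth-corner logit model the analysis fits
(`alpha_s + t_s' B e_i`), with default B encoding the qualitative field
pattern (tuft, lateral and culm orientation increasing with rainfall; culm
orientation decreasing with sand and CEC and increasing with pH; grazer use
weakly increasing with CEC). Quadrat covers are Dirichlet over occurring
species scaled by a total-cover draw; the Dirichlet concentration defaults
to 0.3, which yields the strongly dominance-structured communities implied
by per-site minimal 90%-cover sets of roughly 2–12 species. Quadrat bare
ground is intercept 25 + 15 × site dung proportion + N(0, 8), clipped to
[0, 100] — about 32.5% mean bare ground at average grazing pressure. Each
stage (pool, sites, presence, quadrats, meta) draws from its own RNG stream
derived from the single master seed, so stages can be regenerated
independently and every run is byte-reproducible.

Grazer use is deliberately *induced* rather than set: each species carries a
height multiplier ρ relative to the site baseline, ρ = 1/g for tall-habit
species and ρ = g for short-habit ones (g the latent grazer-use value), with
tall/short assigned so the pooled record distribution is symmetric on the
log scale. The site median then converges to the baseline and the derived
index recovers g — exercising the full height → median → ratio → reciprocal
pipeline. One honest caveat: when the pool's height ratios leave a gap
around 1 (e.g. few species, all attractors at g ≈ 0.75), the sample median
sits at the edge of that gap rather than the baseline, offsetting recovered
values by up to ~10%. The consistency tests therefore use dense pools whose
ratios straddle 1; users planting precise grazer-use values should do the
same. This does not affect sign or rank recovery of planted fourth-corner
coefficients, which are monotone in the index.

What the generator does *not* emulate: spatial structure within sites,
temporal dynamics or grazing feedbacks, observer error in visual cover
estimates, and phylogenetic correlation among species traits. Passing
recovery tests on synthetic data therefore demonstrates the estimators and
the pipeline plumbing, not field validity of the ecological conclusions.

## Numerical choices and degenerate inputs

* Range standardization refuses constant variables; PCA refuses rank-0 and
  missing input; unit-variance scaling refuses constant columns.
* Constant traits in a v-test are flagged `degenerate` and report v = 0.
* GLM separation triggers the ridge fallback (warning), never silent
  failure; coefficients above |15| on the logit scale are treated as
  separated.
* AICc returns `Inf` when n − p − 1 ≤ 0 (saturated), so saturated
  candidates lose the ladder without aborting it.
* Collinear site scores make triangulation impossible; the error suggests
  jittering.
* Exact attractor-cover ties make dominance undefined; such sites are
  excluded from the split with a warning.
* p-values from B resampling iterations are bounded below by 1/(B + 1);
  fewer than 99 iterations warn about resolution.

## Problem sizes used in the test suite

Simulation-based checks run at deliberately moderate sizes chosen so each
check is statistically meaningful: archetype recovery on 48-species pools
(100 replicates); fourth-corner sign recovery over 50 replicates at 40
sites; type-I calibration of the resampling ANOVA over 500 null replicates
at 199 iterations each, on surveys sized so the cell count comfortably
exceeds the parameter count (a near-saturated GLM produces tied resampling
statistics and a conservative test); bare-ground slope recovery over 50
replicates. The acceptance script simulates one full study-scale survey
(33 × 30) and runs every stage, including the 999-iteration ANOVA.

## Known limitations

* The growth-form name mapping assumes k = 4; other k values get generic
  cluster names.
* The fourth-corner model is presence/absence only — no abundance (count)
  models, by design.
* No spatial autocorrelation handling, beta regression for proportions,
  bootstrap cluster-stability analysis, or automatic choice of k.
* Published coefficient values obtained with penalised fits may differ from
  this package's unpenalised ML coefficients; model rankings and the
  resampling test are the comparable quantities.
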