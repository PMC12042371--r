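---
title: "Time-stratified DEC-family models for historical biogeography"
author: "decstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-stratified DEC-family models for historical biogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decstrat)
```

## The model

`decstrat` estimates how geographic ranges evolved on a time-calibrated
phylogeny.  A range is a subset of discrete *operational areas*; with $n$
areas and a maximum observed range size $m$ the state space contains
$1 + \sum_{k \le m} \binom{n}{k}$ states (the empty "null" range is a legal
interior state of the Markov process — a lineage can lose its last area and
go extinct along a branch — but never a legal observation at a tip).

Two processes act on ranges:

* **Anagenesis** (along branches).  Area $k \notin R$ is gained at rate
  $d \sum_{a \in R} m_{ak}$, where $d$ is the dispersal rate (events per
  lineage-My) and $m_{ak}$ is a dispersal multiplier; each occupied area is
  lost independently at the extirpation rate $e$.  The null range is
  absorbing.
* **Cladogenesis** (at nodes).  The ancestral range is partitioned between
  the two daughters according to one of three classical event menus:
  **DEC** (narrow sympatry, subset sympatry, vicariance with one single-area
  daughter), **DIVALIKE** (narrow sympatry, any vicariant bipartition),
  **BAYAREALIKE** (narrow sympatry and exact range copying only).  The
  founder-event extension (**+J**) adds jump events in which one daughter
  colonizes a single unoccupied area, with weight $j \in [0, 3]$; all other
  event weights are fixed at 1 and per-ancestor probabilities are the
  normalized weights.  With $j = 0$ the +J table is identical to the base
  table, so each +J model strictly nests its base model — a property the
  test suite asserts.

**Time stratification.**  Earth history enters through dispersal-multiplier
matrices that are piecewise constant over strata of geological time.
Branches are cut at stratum boundaries and each segment propagated with its
own transition matrix $\exp(Q_s \Delta t)$.  Ages are measured in My before
present; strata are half-open $[\mathrm{lower}, \mathrm{upper})$ in age, so
a boundary age belongs to the stratum whose lower bound it is — an
unambiguous convention the branch slicer and the multiplier lookup share.

The likelihood is computed by Felsenstein pruning with the cladogenetic
event table applied at every internal node and the root summed over a prior
that is uniform over non-null ranges (configurable; uniformity is the
documented default so results are reproducible without hidden settings).
Conditional-likelihood vectors are renormalized at every node with
accumulated log factors: with 56 states and trees tens of My deep, raw
products underflow double precision.  Data with probability zero under a
parameter set yield `-Inf` rather than an error, because the optimizer must
be able to traverse such regions.

## Fitting and model comparison

`fit_biogeo()` maximizes the likelihood over $d, e$ (and $j$) with bounded
`L-BFGS-B` on $\log_{10}$-transformed parameters from three deterministic
starts ($d = e \in \{10^{-3}, 10^{-2}, 10^{-1}\}$, $j \in \{10^{-4}, 0.5,
2\}$), with bounds $d, e \in [10^{-12}, 5]$ and $j \in [10^{-5}, 3]$.  The
log scale conditions the problem (rates span orders of magnitude); the
deterministic multi-start makes fits bit-reproducible without random seeds.
Because the $j$ search bound is strictly positive, +J fits additionally
profile the $j = 0$ boundary (a 2-parameter optimization from the same
starts) and report $j = 0$ when it wins, so a +J model can never score
below its base model.
Models are compared by the small-sample Akaike criterion
$\mathrm{AICc} = -2\ln L + 2k + 2k(k+1)/(n-k-1)$ with $n$ the number of
tips (AICc is undefined without a sample-size convention; tips are the
convention of the biogeographic literature this package follows), and by
Akaike weights $w_i \propto \exp(-\Delta_i/2)$.  `run_model_grid()` crosses
the four shipped dispersal scenarios with the six models (24 fits),
records per-model failures without aborting the grid, and ranks by AICc.

Marginal ancestral ranges (`ancestral_ranges()`, or `predict()` on a fit)
combine the tipward pass with a rootward pass so that every internal node
gets the probability of each range immediately before cladogenesis,
normalized per node.  On instances small enough for exhaustive enumeration
over all internal-node states and events (up to 4 tips and 3 areas) both
the likelihood and the marginals agree with the brute-force sum to $10^{-8}$.

## The shipped scenarios

Four scenarios over five strata (0–3, 3–20, 20–30, 30–40, 40–120 Ma)
encode hypotheses about the assembly of the Americas:

| scenario | description |
|---|---|
| `null` | all multipliers 1 everywhere |
| `panama` | baseline multipliers (adjacent land 0.5, across water 0.25) in all strata; the Mesoamerica–Pacific gateway reduced to 0.01 before the Panama isthmus closure at 3 Ma |
| `closing_americas` | gateway 0.5 during 3–20 Ma (narrowing seaway) and 0.01 before 20 Ma |
| `gaarlandia` | as `closing_americas`, plus Caribbean routes elevated during 30–40 Ma (the hypothesized Greater Antilles–Aves Ridge connection) |

Numerical choices that the sources leave open, fixed here and exposed as
arguments: non-adjacent land pairs receive the across-water multiplier
0.25 (only two tiers are defined; inventing a third would be a new
assumption); the youngest stratum of `closing_americas`/`gaarlandia` uses
the post-closure baseline; the elevated GAARlandia multiplier defaults to
the adjacent-land value 0.5 (`gaarlandia_mult`), since only an "increase"
is specified.  The area connectivity itself
(`magnolia_connectivity()`) is shipped as an editable specification because
it derives from a map rather than a printed table.

## The worked example

The package ships a 39-taxon Magnoliaceae example: two genera
(*Liriodendron* outgroup, *Magnolia*), the three Neotropical sections
(*Macrophylla*, *Magnolia*, *Talauma*) plus Asian relatives, ten
operational areas (eight Neotropical, Nearctic, Asia), and ranges capped at
two areas (56 states).  The chronogram (`magnolia_chronogram()`) constrains
the 14 published crown ages (root 92.92 Ma, crown *Magnolia* 44.02 Ma,
crown section *Talauma* 35.97 Ma, ...); internal nodes without a published
age are placed by even division of the age interval between their closest
constrained ancestor and their oldest constrained descendant (tips at 0).
This interpolation — and the caterpillar resolution used within
subsections — is a deterministic, documented stand-in: the fixture is
illustrative, not a reproduction of the original posterior tree.  Tip
ranges (`magnolia_geography()`) are coded from collection localities and
native distributions via the gazetteer in `inst/extdata/`, which is
deliberately editable because published sources show the coding only
graphically.

```{r example, eval = FALSE}
tr  <- magnolia_chronogram()
geo <- magnolia_geography()
sc  <- build_scenario("closing_americas", magnolia_areas(),
                      magnolia_connectivity())
fit <- fit_biogeo(tr, geo, model = "DIVALIKE+J", scenario = sc)
fit
anc <- predict(fit)        # per-node range probabilities
plot(fit)                  # chronogram with node pies
```

## The simulator

`simulate_yule_tree()` draws pure-birth chronograms conditioned on the tip
count (epoch $k$ lasts $\mathrm{Exp}(\lambda k)$; expected root age
$\sum_{k=2}^{n} 1/(\lambda k)$, which the tests check against 500
replicates).  `simulate_ranges()` runs a Gillespie simulation of the
anagenetic process along every branch — switching generators at stratum
boundaries — and draws one cladogenetic event per node, logging every event
with its age so that replaying the log reproduces the tip data exactly
(asserted per replicate).  Lineages reaching the null range are extinct;
datasets with extinct tips are *rejected and resimulated* with an
incremented seed rather than conditioned on survival, because the inference
assumes observed tips are extant; the rejection count is reported so the
conditioning bias stays visible.  Jumps occur only at nodes, never along
branches, matching the founder-event definition.  All randomness flows
from one integer seed (replicate $i$ uses `seed + i`-style offsets, kept
below $2^{31}$), so whole datasets are bit-reproducible.

What the simulator does *not* emulate about real data: phylogenetic error
(the tree is known and fixed), sampling gaps, range-dependent
diversification (no GeoSSE-style feedback), fossil lineages, and
within-area heterogeneity.  Passing recovery tests therefore demonstrate
correctness of the machinery under the model's own assumptions, not
robustness to their violation.

## Problem sizes and tolerances used in the tests

The exhaustive-enumeration oracle runs on 4-tip, 2–3-area instances
(tolerance $10^{-8}$); cladogenesis-table normalization is checked
exhaustively up to 5 areas ($10^{-12}$); stratification-identity and
$j=0$-reduction identities at $10^{-10}$; the parameter-recovery study uses
20 replicates of 100-tip Yule trees over 6 areas with true
$d = 0.05, e = 0.02$ and requires the median relative error of $\hat d$ to
be at most 50% — sizes chosen so the full suite runs on one CPU in minutes
while still exercising deep-tree scaling, stratified branches and the
rejection sampler.  The acceptance script re-runs the 24-model grid on the
39-taxon example and a scaled-down recovery study (8 replicates, 60 tips).

## Known limitations

* Ranking reproduction: the original study's AICc table derives from a
  posterior chronogram and per-species codings not reproducible here, so
  the example exercises the machinery qualitatively; its numerical ranking
  is a property of the fixture, not a published value.
* The optimizer is local; the three deterministic starts guard against the
  common ridge between $d$ and $e$ but pathological surfaces can still trap
  it (non-convergence is flagged on the fit object, never hidden).
* Marginal ancestral ranges condition on the fitted point estimates;
  parameter uncertainty is not propagated.
* No distance-scaled dispersal (+x), area-specific extirpation, or
  biogeographic stochastic mapping.
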