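# decstrat

Time-stratified dispersal–extinction–cladogenesis (DEC-family) models for
historical biogeography in R.

`decstrat` is for phylogeneticists who have a time-calibrated tree and
per-species geographic ranges and want to ask *where* ancestral lineages
lived and *which* paleogeographic scenario best explains today's
distributions.  It implements maximum-likelihood inference of range
evolution under the three classical cladogenesis families — **DEC**,
**DIVALIKE** and **BAYAREALIKE** — each with an optional founder-event
(**+J**) parameter, over dispersal-multiplier matrices that change across
strata of geological time, with AICc/Akaike-weight model comparison and
marginal ancestral-range estimation at every node.  A forward simulator
(Yule chronograms plus exact Gillespie range evolution) makes every stage
testable against known truth, and supermatrix utilities cover the
concatenation bookkeeping upstream of tree inference.

## The model in brief

A range is a subset of discrete operational areas (at most `m` areas per
range; the empty range is reachable along branches — extinction — but never
observed at a tip).  Along a branch, area `k` is gained at rate
`d * Σ_{a∈R} m_ak` (with `m_ak` the dispersal multiplier of the current
time stratum) and each occupied area is lost at rate `e`; at a node the
ancestral range is partitioned between daughters by sympatry, subset
sympatry, vicariance or a founder jump (weight `j`), depending on the model
family.  The likelihood is computed by Felsenstein pruning with branch
segments cut at stratum boundaries, and models are ranked by
`AICc = -2lnL + 2k + 2k(k+1)/(n-k-1)` (`n` = tips) and
`AICc_wt ∝ exp(-ΔAICc/2)`.

## Worked example

The package ships a 39-taxon Magnoliaceae chronogram (two genera; the
Neotropical sections *Macrophylla*, *Magnolia* and *Talauma* plus Asian and
Nearctic relatives), ten operational areas with ranges capped at two areas
(56 states), and four dispersal scenarios over five time strata
(0–3, 3–20, 20–30, 30–40, 40–120 Ma):

```r
library(decstrat)

tr  <- magnolia_chronogram()     # 39 tips, root age 92.92 Ma
geo <- magnolia_geography()      # ranges over 10 areas
sc  <- build_scenario("closing_americas", magnolia_areas(),
                      magnolia_connectivity())

fit <- fit_biogeo(tr, geo, model = "DIVALIKE+J", scenario = sc)
fit
#> DEC-family biogeographic model fit
#>   model:   DIVALIKE+J   scenario: closing_americas
#>   tips:    39
#>   d = 0.001752, e = 3.329e-10, j = 0.0663
#>   lnL = -89.9844  (k = 3)  AICc = 186.6546
```

`d` and `e` are in events per lineage-million-years; `j` is the
dimensionless founder-event weight.  The tiny `e` says the tip data need
essentially no extirpation; the positive `j` says founder jumps improve the
fit of cladogenetic range inheritance.  From a fit you can extract
per-node range probabilities and draw them as pies on the tree:

```r
anc <- predict(fit)   # internal nodes x 56 states, rows sum to 1
plot(fit)             # chronogram with node pies
```

and the whole 4-scenario × 6-model grid (24 fits, ranked by AICc):

```r
grid <- run_model_grid(tr, geo, magnolia_connectivity())
grid          # scenario, model, d, e, j, lnL, k, AICc, delta_AICc, AICc_wt
```

The simulator closes the loop — generate data with known parameters and
check they are recovered:

```r
ss  <- build_state_space(LETTERS[1:6], 2)
rec <- recovery_experiment(20, n_tips = 100, d = 0.05, e = 0.02,
                           model = "DEC", space = ss, root_range = "A",
                           seed = 1)
attr(rec, "summary")   # median relative error of d-hat
```

## Package layout

* `fit_biogeo()` / `biogeo_loglik()` / `ancestral_ranges()` /
  `run_model_grid()` / `model_weights()` — inference.
* `build_state_space()`, `read_geography()` — range space and tip data.
* `build_scenario()`, `connectivity_spec()`, `slice_branch()` — time
  strata and dispersal multipliers.
* `simulate_yule_tree()`, `simulate_ranges()`, `recovery_experiment()` —
  synthetic data.
* `read_fasta_alignment()`, `concatenate_alignments()`,
  `write_partition_file()` — supermatrix utilities.
* `magnolia_*()` — the packaged worked example; plain-text copies in
  `inst/extdata/`, materialized anywhere with `write_fixture_files()`.
* `inst/cli/decstrat.R` — thin command-line wrapper (subcommands `concat`,
  `fit`, `grid`, `ancestral`, `simulate`, `fixtures`).

See the vignette (`vignettes/stratified-dec-models.Rmd`) for the model,
its assumptions, numerical choices and limitations.
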