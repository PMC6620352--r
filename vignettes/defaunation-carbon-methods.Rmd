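---
title: "Methods: simulating carbon loss from frugivore defaunation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating carbon loss from frugivore defaunation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defaunacarbon)
```

## The question

Large-bodied frugivores (LBF) — gibbons, macaques, hornbills and large
pigeons, and terrestrial mammals such as deer, elephants and bears — are
the primary seed dispersers of many tropical tree species, and they are the
primary targets of hunting. Tree species that depend on them tend to have
denser wood than species dispersed by small birds, wind or ballistic
mechanisms. If defaunation removes the dispersers, the trees that depend on
them are expected to fail to recruit and to be replaced, over community
turnover, by the remaining species. Because above-ground biomass scales
linearly with wood density at a given stem diameter, that replacement
carries a carbon cost. This package quantifies that cost for a stem-census
plot: it classifies species by disperser guild, computes each stem's
above-ground carbon, and simulates the community turnover as a stochastic
zero-sum removal–replacement process.

## Per-stem carbon

Above-ground biomass uses the standard moist-forest allometry in wood
specific gravity $\rho$ (g/cm³) and diameter at breast height $D$ (cm,
$\ge 5$):

$$AGB = \rho \, \exp\!\left(-1.499 + 2.148 \ln D + 0.207 (\ln D)^2 -
0.0281 (\ln D)^3\right) \quad \text{[kg]}$$

and above-ground carbon is taken as $AGC = AGB/2$. Two properties matter
for everything downstream: the model is *exactly linear in* $\rho$ (so a
density swap changes a stem's carbon by a known factor), and it is strictly
increasing in $D$ over the whole ecological range (5–300 cm). The cubic
coefficient is $-0.0281$; an order-of-magnitude larger value would make
biomass peak at ~6 cm dbh, which is physically meaningless and would
contradict any observed plot total. Per-stem values are in kg; totals are
reported in Mg (= metric tons) and Mg/ha.

Missing wood densities are imputed with the precedence *species-level
database value → field sample → genus median → family median*, medians
taken over species-level values in the reference database (a mean is
available behind `use_mean = TRUE`). Provenance is recorded per species in
`wsg_source`. A database species value outranks a field sample; field
samples outrank genus-level aggregation, since a direct measurement of the
species beats an aggregate of congeners.

## Classification

Disperser knowledge is encoded as a set of up to eight groups per species
(gibbon, macaque, hornbills/large pigeons, smaller birds, terrestrial
mammals, unknown animals, unclassified, wind). Two predicates drive the
simulation: `is_lbf()` (any of gibbon, macaque, hornbills/large pigeons,
terrestrial mammals — an explicit whitelist; "unknown" does not count) and
`is_primate_dispersed()` (gibbon or macaque). For the descriptive carbon
breakdown, species are assigned to exactly one of three categories with
priority P (primates) > TB (large terrestrial/birds) > O (others), so the
categories partition the species list; a stricter reading in which P
requires primates to be the *only* LBF dispersers is available via
`share_category(primates = "alone")`. The simulation target sets use the
predicates directly, never the exclusive categories.

## The zero-sum simulation

Stems with dbh ≥ 5 cm are stratified into four diameter classes — [5, 20),
[20, 40), [40, 80), [80, ∞) cm; half-open on the upper end so 20, 40 and 80
fall in the class above. Per replicate:

1. **Removal.** `round(intensity × N_target)` target stems are drawn
   uniformly without replacement across the whole plot (removal is per
   individual; `round` is R's round-half-even, which never matters at the
   canonical 20% intensity steps). Targets are LBF-dispersed stems
   (`all_lbf`), primate-dispersed stems (`primates_only`), or all stems
   (`control`, removing the *same count* as `all_lbf` at that intensity so
   it isolates procedural artefacts).
2. **Replacement.** Each removed stem is replaced from the *non-target*
   stems of its own size class, drawn uniformly with replacement, with the
   pool fixed at pre-removal composition. Under `wsg_swap` the stem keeps
   its tag and diameter and only takes the donor's wood density — the dbh
   multiset, hence total basal area, is conserved exactly. Under
   `full_replace` the donor is cloned wholesale (species, density,
   diameter), conserving per-class stem counts but not within-class
   diameters. In the control scenario every stem is a target, so the donor
   pool falls back to the non-removed stems of the class — the natural
   analogue of "replacement by the surviving community".
3. **Statistic.** $\Delta AGC\% = 100\,(AGC_{sim} - AGC_{obs})/AGC_{obs}$.

The total stem count and the per-class counts are invariant in every
replicate (zero-sum). 200 replicates are summarised by their mean, and a
95% percentile interval of 200 bootstrap resamples of the replicate vector
(statistic = mean) gives the confidence band. With a single-valued donor
pool the procedure is deterministic and has a closed form: for a two-species
community with $n_t$ target stems of density $w_l$ and $n_p$ pool stems of
$w_o$ at one diameter, complete defaunation under `wsg_swap` gives exactly
$100\, n_t (w_o - w_l) / (n_t w_l + n_p w_o)$ — the anchor for the
acceptance tests.

Reproducibility: one master seed; each replicate and each bootstrap uses a
deterministic substream derived by hashing (seed, scenario, intensity,
option, replicate index), so replicate $r$ is invariant to the number of
replicates requested and the full experiment is bit-reproducible.

## The synthetic census generator

Real plot censuses sit behind data-access agreements, so the package ships
a generator that emulates the statistical structure the analysis relies
on. Defaults describe a 30-ha seasonal-evergreen plot: 232 species, 33,844
stems ≥ 5 cm; a log-series species-abundance distribution with Fisher's
α solved from those two counts; stem diameters from a truncated power law
($\propto D^{-2}$ on [5, 150] cm); per-species disperser-group sets by
independent per-group inclusion (redrawn if empty), with inclusion
probabilities chosen so that after the redraw conditioning about one-third
of species are LBF-dispersed; and species-level wood density from
$\mathcal{N}(0.55 + \delta \cdot \mathrm{LBF},\ 0.12)$ truncated to
(0.1, 1.2) g/cm³, with $\delta = 0.06$ by default and $\delta = 0$ as the
null.

What it does *not* emulate: spatial structure (coordinates, if requested,
are uniform), realistic per-species diameter distributions (all species
share one size law, so systematic size differences between guilds are
absent), phylogenetic signal in wood density, and a calibrated size
distribution — the power-law tail holds more very large stems than a real
plot, so absolute Mg/ha totals run high. Passing tests on synthetic data
therefore demonstrate the *procedure* (conservation, calibration,
monotonicity, reproducibility), not agreement with any particular plot's
published totals.

## A statistical subtlety worth knowing

Because wood density is drawn once per *species*, any single generated
community carries a realized association between density and guild even at
$\delta = 0$: the few dominant species carry most of the carbon, so the
effective sample is small and the per-community offset of mean
$\Delta AGC\%$ has a standard deviation of roughly 3 percentage points.
Within one community the replicate mean converges to that realized offset,
not to zero, while the bootstrap SE of the mean shrinks toward the (much
smaller) Monte-Carlo error. Unbiasedness of the procedure is therefore an
*ensemble* property — the grand mean across independently generated null
communities is zero within its standard error — and that is how the test
suite asserts it. For the same reason the monotone-loss-in-intensity check
first verifies that the realized community actually satisfies its premise
(mean LBF wood density above the rest), taking the first seed in a fixed
sequence that does. The control scenario's small nonzero offset within one
community reflects the realized covariance between stem size and density
within classes; its sign is not reproducible and is not treated as one.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `min_dbh` | 5 cm | census filter, inclusive |
| class bounds | 5/20/40/80 cm | half-open diameter strata |
| `intensities` | 0.2–1.0 by 0.2 | fraction of target stems removed |
| `n_reps` | 200 | removal–replacement replicates |
| `n_boot` | 200 | bootstrap resamples of the replicate vector |
| `plot_area_ha` | 30 | converts plot totals to Mg/ha |
| `delta` | 0.06 g/cm³ | LBF wood-density shift in the generator |
| `sigma` | 0.12 g/cm³ | species-level wood-density spread |

Test problem sizes are the package's own choices: conservation checks use
50 communities of 800 stems (conservation is exact per replicate, so one
replicate per scenario–intensity–option cell suffices); calibration and
monotonicity use 20,000-stem communities; ensemble unbiasedness uses 40
communities of 4,000 stems.

## Known limitations

The model assumes community equilibrium: no transient dynamics, no
density-dependent mortality, no secondary dispersal compensation, no
spatial processes. The replacement pool is frozen at pre-removal
composition, which ignores that replacements themselves change the pool in
a multi-step turnover. Welch's t-test on species means ignores phylogeny
and abundance weighting. All of these are deliberate: the aim is the
first-order, trait-driven carbon consequence of losing a disperser guild,
under assumptions transparent enough to audit.
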